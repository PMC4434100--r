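---
title: "Sorted-dictionary k-mer indexing and exact short-query search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorted-dictionary k-mer indexing and exact short-query search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerdict)
```

## The model

`kmerdict` answers one question exactly: at which positions of a DNA
database does a short pattern occur? The database is indexed once; each
query of length $l \le k$ is then resolved from the index alone, without
rescanning the sequences.

### Encoding

Every window of $k$ consecutive bases is mapped to an integer by reading
its bases as digits of a *bijective* base-4 numeral,

$$f(W) \;=\; \sum_{i=1}^{k} m(w_i)\,4^{\,i-1},
\qquad m(\mathrm{A})=1,\; m(\mathrm{T})=2,\; m(\mathrm{G})=3,\; m(\mathrm{C})=4,$$

with the **leftmost** base least significant. Two properties carry the
whole method:

1. *No zero digit.* Were any base zero-mapped, words ending in different
   numbers of that base would collide (the value of `CAA` would equal that
   of `CAAAA`). With digits 1–4 the map is injective, and the $4^k$
   $k$-digit values exactly fill the integer interval
   $[(4^k-1)/3,\; 4(4^k-1)/3]$ — the all-A and all-C words — with no gaps.
2. *Colexicographic order.* Because the leftmost base is least
   significant, ascending key order sorts words by their **suffix**. All
   words sharing an $l$-suffix therefore occupy one contiguous key
   interval, which is what makes suffix search a single range scan.

The inverse (`decode_word()`) peels digits off with
$d = ((v-1) \bmod 4) + 1$, $v \leftarrow (v-d)/4$.

### Rolling indexing

Adjacent windows share $k-1$ bases, so the next key follows from the
previous one in four operations:

$$f(W_{j+1}) \;=\; \frac{f(W_j) - m(w_j)}{4} \;+\; m(w_{j+k})\,4^{\,k-1}.$$

Indexing $n$ bases thus costs $O(n)$ rather than $O(nk)$; `roll_key()`
exposes the recurrence with an operation counter so the constant
per-window cost is testable, and `build_index()` uses the same recurrence
internally after the first window of each clean run.

### The sorted dictionary

The index is constructed dynamically: a key exists only if its word occurs
in the database, so every entry points at least one posting $(i, p)$
(0-based sequence index and window start), and none of the
$4^k - \text{observed}$ redundant slots of a precomputed hash table are
kept. The realization here is a sorted key array with parallel posting
lists; the contract is only that of an ordered map — ascending iteration
from a binary-searched lower bound, stopping at the first key past the
upper bound (`range_scan()` reports how many keys it touched, which tests
hold to "keys in range + 1").

### Search

For a query $q$ of length $l \le k$ with value $f(q)$:

- **Suffix mechanism.** $q$ is the suffix of a $k$-word iff the word's key
  lies in
  $$\bigl[f(q)\,4^{k-l} + \tfrac{4^{k-l}-1}{3},\;\;
        f(q)\,4^{k-l} + 4\tfrac{4^{k-l}-1}{3}\bigr],$$
  the values of $q$ left-padded with A's (minimum) and C's (maximum).
  Each posting $p$ in the range is an occurrence starting at $p + (k-l)$.
- **Prefix mechanism.** $q$ is the prefix of a $k$-word iff the key lies
  between the right-padded values $f(q\mathrm{A\cdots A})$ and
  $f(q\mathrm{C\cdots C})$ **and** $(key - f(q)) \bmod 4^l = 0$. The range
  alone is not sufficient here; the congruence pins the low-order $l$
  digits. Each surviving posting is an occurrence starting at $p$.

Suffix lookup alone finds exactly the occurrences with start $\ge k-l$; an
occurrence in the first $k-l$ positions of a sequence is contained in no
indexed word as a suffix. That is precisely where promoter consensus
elements sit in short reads, so `search_all()` unions both mechanisms.
Interior occurrences are found by both (as prefix of the word at $p$ and
suffix of the word at $p-(k-l)$); the deduplication rule makes the suffix
result authoritative and restricts the prefix contribution to starts
$< k-l$, so the two mechanisms partition the output. `mode = "prefix_only"`
in `search_batch()` still reports all prefix-mechanism hits for
diagnostics.

```{r}
idx <- build_index(c(read = paste0("TACACAAC", generate_sequence(102, 1))),
                   k = 8)
search_all(idx, "TACACA")
```

## Parameters

- **`k`** (default 8, the setting used throughout the package's reference
  experiments): word length in bases. It bounds the longest searchable
  query, and the key space $4^k$ grows fourfold per unit — at $k = 8$
  there are 65,536 possible keys, comfortably dense for bacterial-genome
  scale. Any $k \le 26$ is accepted; beyond that exact integer arithmetic
  in doubles (2^53) would no longer be guaranteed, so it is refused.
- **Coordinates** are 0-based half-open internally and in default output;
  `write_hits(..., one_based = TRUE)` renders 1-based inclusive.
- **Keys** are R doubles holding exact integers; every operation in the
  codec (sums, the division by 4, the modulus) stays on integer values,
  so no rounding can occur.

## Degenerate inputs and numerical choices

- Windows containing non-ACGT characters (N, ambiguity codes) are
  skipped; the rolling recurrence restarts with a direct encode at the
  next clean window. This mirrors the standard practice of excluding
  ambiguity-code words from k-mer indexes.
- Sequences shorter than $k$ contribute no indexed word; their
  occurrences are undetectable by the method, and indexing them emits a
  warning rather than silence.
- A subtler boundary: in a sequence with $k \le n < 2k-l-1$, an interior
  occurrence can start too late to begin an indexed word ($s > n-k$) and
  too early to end one ($s < k-l$), and is then invisible to both
  mechanisms. The completeness statement is therefore: `search_all()`
  returns every occurrence in every sequence of length at least
  $2k-l-1$. The fixture generator enforces a minimum length of $2k$ so
  this edge never contaminates ground truth.
- Ties: hits are ordered by (query input order, sequence index, start);
  postings within a key by (sequence index, position).

## What the synthetic generator emulates

`make_benchmark_set()` draws i.i.d. uniform-composition sequences (20
sequences of 100–500 bases by default — a desk-scale stand-in for a
fragment collection) and plants, for each query, at least one occurrence
with start $< k-l$ (the class suffix-only search misses) and one interior
occurrence, without overlaps, under a stated Mersenne-Twister seed. Ground
truth is always *recounted* by the naive oracle (`naive_all_occurrences()`,
a direct substring comparison at every start) on the final sequences, so
incidental occurrences created by planting are included.

What it does **not** emulate: repeats, GC skew, real promoter grammar, or
chromosome-scale lengths. Passing tests therefore demonstrate exactness of
the index and search logic, not robustness to genomic repeat structure —
though exactness is composition-independent by construction, since every
claim is checked against the brute-force oracle.

Problem sizes used by the test suite: oracle-equivalence runs use 200
sequences of 50–2000 bases per word length $k \in \{4, 6, 8\}$ with every
query length $1..k$; range-exactness enumerates all $4^6$ words; the
rolling-equivalence check uses a $10^5$-base sequence. These sizes give
full coverage of the boundary classes while keeping the suite quick.

## Design choices

- The digit assignment and orientation are fixed by the six published
  conversion values the codec must reproduce (e.g. $f(\mathrm{TATAAT}) =
  2406$, $f(\mathrm{TACACAAC}) = 71814$); the test suite carries them as a
  regression set. Leftmost-most-significant admits no consistent digit
  assignment for those values.
- A sorted array (not a balanced tree) realizes the dictionary: R has no
  native ordered map, the index is append-only in practice, and binary
  search + linear walk meets the same scan contract with better locality.
  `add_sequence()` merges one record's postings rather than rebuilding.
- Persistence is a versioned plain-text format (header with magic,
  version, `k`, key count and sequence table; one `key → i:p,…` line per
  key, ascending). Transparent files make corruption detectable (the key
  count is validated, keys must ascend strictly) and diffs reviewable.
- FASTA parsing is delegated to `Biostrings::readDNAStringSet()`; the
  package's own writer emits LF-only, fixed-width FASTA so fixtures are
  byte-reproducible.

## Limitations

- No query longer than $k$ can be searched — a stated property of the
  method, not an implementation shortfall; choose $k$ no smaller than the
  longest query before indexing.
- Forward strand only; no reverse-complement, no mismatches, no seed
  extension.
- The whole index lives in memory; there is no disk-resident posting
  store, so databases are limited by RAM (at bacterial scale this is a
  few hundred MB).
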