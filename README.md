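# kmerdict

Exact short-pattern search over DNA sequence databases via a dynamically
built, sorted-dictionary k-mer index.

## The problem

Scanning a sequence database for every exact occurrence of short annotated
patterns — bacterial promoter consensus elements such as the −10 box
`TATAAT`, restriction sites, telomeric repeats — is a core step in
functional annotation. Hash-based indexers assign each k-base word an
integer key, but zero-mapping any base makes words that end in different
numbers of that base collide, and precomputing all 4^k keys wastes memory
on words the database never contains. Worse, looking up a query of length
l < k only as a *suffix* of indexed words silently misses every occurrence
in the first k − l positions of each sequence — exactly where a promoter
consensus sits in a short read.

`kmerdict` implements the remedy end to end:

- **Collision-free encoding.** Each k-word W = w₁w₂…w_k is mapped to

      f(W) = Σᵢ m(wᵢ) · 4^(i−1),   m(A)=1, m(T)=2, m(G)=3, m(C)=4,

  a bijective base-4 numeral with the leftmost base least significant.
  The k-digit values fill the interval [(4^k−1)/3, 4(4^k−1)/3] with no
  gaps and no collisions.
- **O(1) rolling update.** The key of each successive window follows from
  the previous one in four arithmetic operations,

      f(next) = (f(prev) − m(out)) / 4 + m(in) · 4^(k−1),

  so indexing a database of n bases costs O(n), not O(nk).
- **Dynamic sorted dictionary.** Only words actually observed get an
  entry (key → list of (sequence, position) postings), eliminating the
  4^k − observed redundant slots of a precomputed table; keys are kept
  sorted so a search touches only the keys of its range, plus one.
- **Complete search for l ≤ k.** A query q of length l occurs as the
  suffix of a k-word iff the word's key lies in
  [f(q)·4^(k−l) + (4^(k−l)−1)/3, f(q)·4^(k−l) + 4(4^(k−l)−1)/3]
  (one contiguous scan), and as the prefix iff the key lies between the
  right-padded values f(qA…A) and f(qC…C) *and* (key − f(q)) mod 4^l = 0.
  Suffix hits are reported at posting position p + (k − l), prefix hits at
  p; the prefix mechanism contributes the beginning-of-sequence starts
  (< k − l) that suffix-only lookup cannot see.

## Worked example

```r
library(kmerdict)

# a short chromosome read beginning with the thrL promoter -10 consensus
read <- paste0("TACACAAC", generate_sequence(102, seed = 1))
idx  <- build_index(c(read = read), k = 8)

encode_word("TACACAAC")
#> [1] 71814

search_suffix(idx, "TACACA")[, c("start", "mechanism")]
#> [1] start     mechanism     <- empty: no indexed word ENDS in TACACA
#> <0 rows> (or 0-length row.names)

search_all(idx, "TACACA")[, c("start", "end", "mechanism")]
#>   start end mechanism
#> 1     0   6    prefix
```

The suffix-only search reports nothing: the consensus sits at position 0,
and none of the words TACACAAC, ACACAACA, … contain it as a suffix. The
combined search recovers the hit through the key 71814 of the first indexed
word, which passes the prefix test: 71814 lies in [22662, 84102] and
(71814 − 2182)/4096 = 17 exactly, where 2182 = f(TACACA).

The toy database from the search section behaves the same way:

```r
idx <- build_index(c(S2 = "CTTAAC"), k = 4)
search_all(idx, "AA")
#>   query_id pattern seq_index seq_name start end mechanism
#> 1       AA      AA         0       S2     3   5    suffix
```

`AA` is found as the suffix of the second indexed word `TTAA` (posting
p = 1), reported at start p + (k − l) = 3.

## Command line

```sh
SCRIPT=$(Rscript -e 'cat(system.file("scripts/kmerdict", package="kmerdict"))')
Rscript $SCRIPT simulate --k 8 --seed 3 --out-fasta db.fa --out-truth truth.tsv
Rscript $SCRIPT index    --fasta db.fa --k 8 --out db.idx
Rscript $SCRIPT search   --index db.idx --queries queries.txt \
                         --out hits.tsv --summary summary.tsv
Rscript $SCRIPT stats    --index db.idx
```

`search --mode suffix_only` reproduces the incomplete suffix-only
behaviour; the summary TSV tabulates, per query, `hits_all`,
`hits_suffix_only` and `hits_unreported_by_suffix_only`.

## Limitations

- Queries longer than k cannot be searched (inherent to the method; pick
  k at least the longest query before indexing).
- Sequences shorter than k contain no indexed word and are invisible;
  sequences shorter than 2k − l − 1 can additionally hide interior
  occurrences of an l-base query. Both cases are warned about at index
  time and discussed in the vignette.
- Forward strand only; no reverse-complement or approximate matching.
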