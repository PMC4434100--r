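Package: kmerdict
Title: Sorted-Dictionary K-mer Indexing and Exact Short-Query Search for DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Indexes DNA sequence databases by mapping every overlapping
    k-base word to a unique integer under a bijective base-4 numeration
    (digits A=1, T=2, G=3, C=4, leftmost base least significant) and storing
    the resulting keys with their (sequence, position) postings in a sorted
    dictionary built dynamically from the data.  Successive window keys are
    derived by a constant-time rolling recurrence, so indexing is linear in
    the database size.  Exact occurrences of queries no longer than k are
    retrieved by a contiguous suffix key-range scan combined with a
    prefix range-plus-divisibility test; the prefix mechanism recovers the
    beginning-of-sequence hits that suffix-only lookup misses, so every
    exact occurrence is reported.  Includes a seeded synthetic-fixture
    generator with a naive brute-force oracle, plain-text index
    persistence, and a command-line interface for indexing, searching and
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
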