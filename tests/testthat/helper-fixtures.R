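# Shared fixtures and independent oracles for the suite.

# direct per-window encoding: sum of digit * 4^(i-1) over each window,
# computed without the rolling recurrence (oracle for rolling builds)
direct_window_keys <- function(seq, k) {
  d <- encode_base(strsplit(toupper(seq), "")[[1]])
  n <- length(d)
  if (n < k) return(numeric(0))
  keys <- numeric(n - k + 1)
  for (i in 1:k) keys <- keys + d[i:(n - k + i)] * 4^(i - 1)
  keys
}

# every k-word and its key, by decoding the full valid interval
all_words_table <- function(k) {
  b <- valid_key_bounds(k)
  keys <- b[1]:b[2]
  data.frame(key = keys, word = decode_word(keys, k),
             stringsAsFactors = FALSE)
}

# small random database as a named character vector
rand_db <- function(nseq, min_len, max_len, seed) {
  lens <- min_len + (seq_len(nseq) * 7919L) %% (max_len - min_len + 1L)
  seqs <- vapply(seq_len(nseq), function(j) {
    generate_sequence(lens[j], seed = seed + j)
  }, character(1))
  names(seqs) <- sprintf("r%03d", seq_len(nseq))
  seqs
}

expect_same_occurrences <- function(hits, truth) {
  got <- hits[order(hits$seq_index, hits$start), c("seq_index", "start")]
  want <- truth[order(truth$seq_index, truth$start), c("seq_index", "start")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
}
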