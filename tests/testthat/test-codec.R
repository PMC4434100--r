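# Bijective base-4 codec: base mapping, word encoding, rolling recurrence,
# search ranges.

test_that("base mapping is the fixed bijection with case folding", {
  expect_equal(encode_base(c("A", "T", "G", "C")), c(1, 2, 3, 4))
  expect_equal(encode_base(c("a", "t", "g", "c")), c(1, 2, 3, 4))
  expect_error(encode_base("N"), "invalid base")
  expect_error(encode_base("-"), "invalid base")
  expect_error(encode_base("AT"), "single characters")
})

test_that("encoder reproduces the printed promoter-consensus conversion values", {
  printed <- c(CCGATAT = 9860, TATAAT = 2406, TTGACA = 2170,
               CTGGTA = 1788, CTAAA = 348, TACACAAC = 71814)
  expect_equal(encode_word(names(printed)), unname(printed))
})

test_that("encode_word handles boundary words and rejects bad input", {
  expect_equal(encode_word("AACT"), 197)       # 1 + 1*4 + 4*16 + 2*64
  expect_equal(encode_word("AAAA"), (4^4 - 1) / 3)
  expect_equal(encode_word("CCCC"), 4 * (4^4 - 1) / 3)
  expect_equal(encode_word("tataat"), 2406)    # case folding
  expect_error(encode_word(""), "non-empty")
  expect_error(encode_word("ACGN"), "invalid base")
})

test_that("decode_word inverts encode_word over the whole key interval", {
  expect_equal(decode_word(2406, 6), "TATAAT")
  expect_equal(decode_word(85, 4), "AAAA")
  expect_equal(decode_word(177, 4), "ACTT")
  # exhaustive bijection at small k: every valid key round-trips
  for (k in c(2, 4, 6)) {
    tab <- all_words_table(k)
    expect_false(any(duplicated(tab$word)))
    expect_equal(encode_word(tab$word), tab$key)
  }
  # sampled at k = 8
  b <- valid_key_bounds(8)
  keys <- round(seq(b[1], b[2], length.out = 500))
  expect_equal(encode_word(decode_word(keys, 8)), keys)
  expect_error(decode_word(84, 4), "out of range")
  expect_error(decode_word(341, 4), "out of range")
})

test_that("valid key interval is the all-A / all-C closed form", {
  expect_equal(valid_key_bounds(1), c(1, 4))
  expect_equal(valid_key_bounds(4), c(85, 340))
  expect_equal(valid_key_bounds(8), c(21845, 87380))
  expect_equal(valid_key_bounds(16), c((4^16 - 1) / 3, 4 * (4^16 - 1) / 3))
  # keys stay exact integers well beyond k = 8
  b <- valid_key_bounds(16)
  expect_identical(b[2] - (b[2] - 1), 1)
  expect_error(valid_key_bounds(0), "positive integer")
})

test_that("rolling one window reproduces direct encoding", {
  expect_equal(roll_key(encode_word("AACT"), "A", "T", 4),
               encode_word("ACTT"))  # 197 -> 177
  expect_equal(roll_key(85, "A", "A", 4), 85)  # all-A fixed point
  expect_equal(roll_key(71814, "T", "A", 8), encode_word("ACACAACA"))
  expect_error(roll_key(encode_word("AACT"), "T", "A", 4),
               "inconsistent state")
})

test_that("rolling an entire sequence equals per-window direct encoding", {
  for (k in c(4, 6, 8)) {
    seq <- generate_sequence(3000, seed = 100 + k)
    direct <- direct_window_keys(seq, k)
    chars <- strsplit(seq, "")[[1]]
    rolled <- numeric(length(direct))
    rolled[1] <- encode_word(substr(seq, 1, k))
    for (j in 2:length(direct)) {
      rolled[j] <- roll_key(rolled[j - 1], chars[j - 1], chars[j + k - 1], k)
    }
    expect_equal(rolled, direct)
  }
})

test_that("rolling costs exactly four arithmetic operations per window", {
  seq <- generate_sequence(500, seed = 5)
  chars <- strsplit(seq, "")[[1]]
  k <- 8
  roll_op_reset()
  key <- encode_word(substr(seq, 1, k))
  for (j in 2:(nchar(seq) - k + 1)) {
    key <- roll_key(key, chars[j - 1], chars[j + k - 1], k)
  }
  expect_identical(roll_op_count(), 4 * (nchar(seq) - k))
})

test_that("suffix key range matches the A-pad / C-pad closed form", {
  r <- suffix_key_range(encode_word("AA"), 2, 4)
  expect_equal(c(r$low, r$high), c(85, 100))
  r <- suffix_key_range(encode_word("TACACA"), 6, 8)
  expect_equal(c(r$low, r$high), c(34917, 34932))
  # endpoints are the keys of the padded extensions themselves
  expect_equal(r$low, encode_word("AATACACA"))
  expect_equal(r$high, encode_word("CCTACACA"))
  # l = k collapses to the query's own key
  r <- suffix_key_range(2406, 6, 6)
  expect_equal(c(r$low, r$high), c(2406, 2406))
  expect_error(suffix_key_range(2406, 7, 6), "exceeds indexed word length")
})

test_that("suffix ranges of consecutive query values tile the key space", {
  k <- 6
  for (l in c(1, 3, 5)) {
    b <- valid_key_bounds(l)
    qkeys <- b[1]:b[2]
    rngs <- lapply(qkeys, suffix_key_range, l = l, k = k)
    lows <- vapply(rngs, `[[`, numeric(1), "low")
    highs <- vapply(rngs, `[[`, numeric(1), "high")
    expect_true(all(highs - lows == 4^(k - l) - 1))
    # adjacent and disjoint: next low is previous high + 1
    expect_equal(lows[-1], highs[-length(highs)] + 1)
    # together they cover exactly the valid k-key interval
    expect_equal(c(lows[1], highs[length(highs)]), valid_key_bounds(k))
  }
})

test_that("prefix range and divisibility test reproduce the worked key check", {
  p <- prefix_key_params(encode_word("TACACA"), 6, 8)
  expect_equal(c(p$low, p$high), c(22662, 84102))
  expect_equal(p$modulus, 4^6)
  expect_true(key_matches_prefix(71814, p))       # TACACAAC
  expect_equal((71814 - p$residue) / p$modulus, 17)
  expect_false(key_matches_prefix(71815, p))      # breaks divisibility
  # endpoints are the A-pad / C-pad right extensions
  expect_equal(p$low, encode_word("TACACAAA"))
  expect_equal(p$high, encode_word("TACACACC"))
  # l = k: only the query's own key passes
  p <- prefix_key_params(2406, 6, 6)
  cand <- valid_key_bounds(6)[1]:valid_key_bounds(6)[2]
  expect_equal(cand[key_matches_prefix(cand, p)], 2406)
  expect_error(prefix_key_params(2406, 9, 8), "exceeds indexed word length")
})

test_that("range and modulus tests select exactly the right words, exhaustively", {
  # brute force over all 4^6 words at k = 6, several query lengths
  k <- 6
  tab <- all_words_table(k)
  set.seed(61)
  for (l in 1:k) {
    qs <- if (l == 1) c("A", "C", "G", "T") else {
      unique(vapply(1:10, function(i) {
        paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
              collapse = "")
      }, character(1)))
    }
    for (q in qs) {
      qk <- encode_word(q)
      r <- suffix_key_range(qk, l, k)
      in_range <- tab$key >= r$low & tab$key <= r$high
      is_suffix <- substring(tab$word, k - l + 1, k) == q
      expect_identical(in_range, is_suffix)
      p <- prefix_key_params(qk, l, k)
      expect_identical(key_matches_prefix(tab$key, p),
                       startsWith(tab$word, q))
    }
  }
})
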