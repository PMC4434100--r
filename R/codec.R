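# Bijective base-4 k-mer codec.
#
# Every k-base DNA word is mapped to a unique integer by reading its bases as
# digits of a bijective base-4 numeral: A=1, T=2, G=3, C=4, with the LEFTMOST
# base as the least-significant digit.  Because no base maps to zero, words
# ending in different numbers of A's receive different values (the flaw in
# zero-mapping adenine that this numeration avoids), and because the digit
# set {1,2,3,4} tiles the integers, the k-digit values fill the interval
# [(4^k-1)/3, 4*(4^k-1)/3] with no gaps and no collisions.
#
# Keys are kept as R doubles holding exact integers; all arithmetic here is
# integer-valued, exact up to 2^53, i.e. for k up to 26.

# digit lookup: names are the alphabet, values the digits
.BASE_DIGITS <- c(A = 1, T = 2, G = 3, C = 4)
.DIGIT_BASES <- c("A", "T", "G", "C")

# powers of four, exact as doubles: .POW4[i] == 4^(i-1)
.POW4 <- 4^(0:31)

# arithmetic-operation counter for the rolling recurrence (see roll_key)
.roll_env <- new.env(parent = emptyenv())
.roll_env$ops <- 0

#' Map a nucleotide to its base-4 digit
#'
#' The base-mapping underlying the whole codec: A→1, T→2, G→3, C→4.
#' No base maps to zero, which makes the word encoding collision-free.
#'
#' @param symbol Character vector of single nucleotide letters (case
#'   insensitive).
#' @return Integer-valued numeric vector of digits in `{1, 2, 3, 4}`.
#' @examples
#' encode_base(c("A", "c", "G", "t"))
#' @export
encode_base <- function(symbol) {
  if (!is.character(symbol) || any(nchar(symbol) != 1)) {
    stop("`symbol` must be single characters", call. = FALSE)
  }
  d <- .BASE_DIGITS[toupper(symbol)]
  if (anyNA(d)) {
    bad <- unique(symbol[is.na(d)])
    stop("invalid base(s): ", paste(bad, collapse = ", "),
         " (only A, C, G, T are encodable)", call. = FALSE)
  }
  unname(d)
}

# word -> digit vector; NA for non-ACGT characters if allow_invalid
.word_digits <- function(word, allow_invalid = FALSE) {
  chars <- strsplit(toupper(word), "", fixed = TRUE)[[1]]
  d <- unname(.BASE_DIGITS[chars])
  if (!allow_invalid && anyNA(d)) {
    bad <- unique(chars[is.na(d)])
    stop("invalid base(s) in word: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' Encode a DNA word as its conversion value
#'
#' Computes `f(W) = sum_i digit(w_i) * 4^(i-1)` over the bases of the word,
#' leftmost base least significant.  The mapping is a bijection between the
#' 4^k words of length k and the integers in
#' `[(4^k-1)/3, 4*(4^k-1)/3]`, so equal values imply equal words.
#'
#' @param word Character vector of DNA strings (ACGT, case insensitive).
#' @return Numeric vector of exact integer conversion values.
#' @examples
#' encode_word("TATAAT")    # 2406
#' encode_word("TACACAAC")  # 71814
#' @seealso [decode_word()] for the inverse, [roll_key()] for the
#'   incremental update between overlapping words.
#' @export
encode_word <- function(word) {
  if (!is.character(word) || length(word) == 0 || any(!nzchar(word))) {
    stop("`word` must be one or more non-empty DNA strings", call. = FALSE)
  }
  vapply(word, function(w) {
    d <- .word_digits(w)
    sum(d * .POW4[seq_along(d)])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Decode a conversion value back to its DNA word
#'
#' Extracts bijective base-4 digits: `d = ((key - 1) %% 4) + 1`, then
#' `key <- (key - d) / 4`, repeated `k` times from the least-significant
#' (leftmost) base outward.  Exact inverse of [encode_word()].
#'
#' @param key Numeric vector of conversion values (exact integers).
#' @param k Word length in bases.
#' @return Character vector of DNA words of length `k`.
#' @examples
#' decode_word(2406, 6)  # "TATAAT"
#' @export
decode_word <- function(key, k) {
  bounds <- valid_key_bounds(k)
  if (any(key < bounds[1] | key > bounds[2])) {
    stop("key out of range [", bounds[1], ", ", bounds[2], "] for k = ", k,
         call. = FALSE)
  }
  vapply(key, function(v) {
    out <- character(k)
    for (i in seq_len(k)) {
      d <- ((v - 1) %% 4) + 1
      out[i] <- .DIGIT_BASES[d]
      v <- (v - d) / 4
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Roll a word key one position to the right
#'
#' Given the key of the window starting at position j, the key of the window
#' at j+1 is obtained in four arithmetic operations, independent of k:
#' subtract the digit of the outgoing (leftmost) base, divide by 4 to shift
#' the shared k-1 bases down one place, and add the incoming base's digit
#' scaled by `4^(k-1)`.  This makes indexing a sequence O(n) instead of
#' O(n*k).
#'
#' Each call adds its four operations to an internal counter readable via
#' [roll_op_count()], so the constant per-window cost is observable.
#'
#' @param prev_key Key of the current window (its first base is `outgoing`).
#' @param outgoing Base leaving the window on the left.
#' @param incoming Base entering the window on the right.
#' @param k Window length.
#' @return Key of the shifted window.
#' @examples
#' roll_key(encode_word("AACT"), "A", "T", 4) == encode_word("ACTT")
#' @export
roll_key <- function(prev_key, outgoing, incoming, k) {
  d_out <- encode_base(outgoing)
  d_in <- encode_base(incoming)
  t1 <- prev_key - d_out           # subtraction
  if (t1 %% 4 != 0) {
    stop("inconsistent state: `prev_key` does not start with base '",
         outgoing, "'", call. = FALSE)
  }
  t2 <- t1 / 4                     # division
  t3 <- d_in * .POW4[k]            # multiplication by 4^(k-1)
  key <- t2 + t3                   # addition
  .roll_env$ops <- .roll_env$ops + 4
  key
}

#' @rdname roll_key
#' @export
roll_op_count <- function() .roll_env$ops

#' @rdname roll_key
#' @export
roll_op_reset <- function() {
  .roll_env$ops <- 0
  invisible(NULL)
}

#' Key range of the k-words ending in a query
#'
#' A query q of length l <= k occurs as the suffix of a k-word exactly when
#' the word's key lies in a contiguous interval: the minimum is reached by
#' padding q with A's on the left, the maximum by padding with C's.  In
#' closed form, with `w = 4^(k-l)`:
#' `low = f(q)*w + (w-1)/3` and `high = f(q)*w + 4*(w-1)/3`.
#' Because leftmost-least-significant encoding sorts words colexicographically,
#' words sharing an l-suffix occupy exactly this interval, and intervals of
#' consecutive query values are adjacent and disjoint.
#'
#' @param query_key Conversion value of the query.
#' @param l Query length.
#' @param k Indexed word length.
#' @return A `key_range` list with `low`, `high` (`modulus`/`residue` are NA;
#'   they apply to prefix search only).
#' @examples
#' suffix_key_range(encode_word("AA"), 2, 4)  # [85, 100]: words ending in AA
#' @export
suffix_key_range <- function(query_key, l, k) {
  .check_l_k(l, k)
  w <- .POW4[k - l + 1]
  pad_min <- (w - 1) / 3
  structure(
    list(low = query_key * w + pad_min,
         high = query_key * w + 4 * pad_min,
         modulus = NA_real_, residue = NA_real_),
    class = "key_range"
  )
}

#' Key range and divisibility test of the k-words beginning with a query
#'
#' A query q of length l <= k is the prefix of a k-word exactly when the
#' word's key satisfies both conditions: it lies between the values of q
#' padded on the right with A's (minimum) and with C's (maximum), and the
#' difference `key - f(q)` is divisible by `4^l` (the low-order l digits are
#' exactly q).  Unlike the suffix case the range alone is not sufficient;
#' the congruence picks the matching words out of the interval.
#'
#' @inheritParams suffix_key_range
#' @return A `key_range` list with `low`, `high`, `modulus = 4^l`,
#'   `residue = f(q)`.
#' @seealso [key_matches_prefix()] to apply the test.
#' @examples
#' p <- prefix_key_params(encode_word("TACACA"), 6, 8)
#' key_matches_prefix(encode_word("TACACAAC"), p)  # TRUE
#' @export
prefix_key_params <- function(query_key, l, k) {
  .check_l_k(l, k)
  m <- .POW4[l + 1]                  # 4^l
  pad_min <- (.POW4[k - l + 1] - 1) / 3
  structure(
    list(low = query_key + m * pad_min,
         high = query_key + 4 * m * pad_min,
         modulus = m, residue = query_key),
    class = "key_range"
  )
}

#' @rdname prefix_key_params
#' @param key Numeric vector of candidate word keys.
#' @param params A `key_range` produced by [prefix_key_params()].
#' @export
key_matches_prefix <- function(key, params) {
  stopifnot(inherits(params, "key_range"), !is.na(params$modulus))
  key >= params$low & key <= params$high &
    (key - params$residue) %% params$modulus == 0
}

#' Valid key interval for word length k
#'
#' The smallest key is the all-A word, `(4^k-1)/3`; the largest the all-C
#' word, `4*(4^k-1)/3`.  Every integer in between is the key of exactly one
#' k-word.
#'
#' @param k Word length, at least 1.
#' @return Numeric `c(low, high)`.
#' @examples
#' valid_key_bounds(8)  # c(21845, 87380)
#' @export
valid_key_bounds <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  if (k > 26) {
    stop("`k` > 26 exceeds exact double-precision integer range", call. = FALSE)
  }
  lo <- (.POW4[k + 1] - 1) / 3
  c(lo, 4 * lo)
}

.check_l_k <- function(l, k) {
  if (l < 1) stop("query length must be at least 1", call. = FALSE)
  if (l > k) {
    stop("query of length ", l, " exceeds indexed word length k = ", k,
         call. = FALSE)
  }
  invisible(NULL)
}

#' @export
print.key_range <- function(x, ...) {
  cat("<key_range> [", format(x$low, scientific = FALSE), ", ",
      format(x$high, scientific = FALSE), "]", sep = "")
  if (!is.na(x$modulus)) {
    cat("  with (key - ", format(x$residue, scientific = FALSE),
        ") %% ", format(x$modulus, scientific = FALSE), " == 0", sep = "")
  }
  cat("\n")
  invisible(x)
}
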