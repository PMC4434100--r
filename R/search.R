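# Exact search of queries of length l <= k against the sorted index.
#
# A query shorter than the indexed word length occurs either as the suffix
# of some indexed word (interior occurrences, found by a contiguous key
# range) or as the prefix of one (occurrences in the first k-l positions of
# a sequence, found by a range plus a divisibility test).  Suffix-only
# lookup misses exactly the occurrences starting before position k-l, which
# is why the combined search is needed for completeness.

#' Construct a validated query pattern
#'
#' @param pattern DNA string (ACGT, case insensitive), length at least 1.
#' @param query_id Identifier used in hit tables; defaults to the pattern
#'   itself.
#' @return A `query_pattern` list with `query_id`, `pattern`, `l` (length)
#'   and `key` (the conversion value `f(q)`).
#' @examples
#' query_pattern("TATAAT")$key  # 2406
#' @export
query_pattern <- function(pattern, query_id = pattern) {
  if (!is.character(pattern) || length(pattern) != 1 || !nzchar(pattern)) {
    stop("`pattern` must be a single non-empty DNA string", call. = FALSE)
  }
  pattern <- toupper(pattern)
  if (!grepl("^[ACGT]+$", pattern)) {
    stop("query '", query_id, "' contains characters outside ACGT",
         call. = FALSE)
  }
  structure(
    list(query_id = as.character(query_id), pattern = pattern,
         l = nchar(pattern), key = encode_word(pattern)),
    class = "query_pattern"
  )
}

.as_query <- function(query) {
  if (inherits(query, "query_pattern")) query else query_pattern(query)
}

.check_query_fits <- function(query, index) {
  if (query$l > index$k) {
    stop("query '", query$query_id, "' (length ", query$l,
         ") is longer than the indexed word length k = ", index$k,
         "; the method cannot search it", call. = FALSE)
  }
}

.empty_hits <- function() {
  data.frame(query_id = character(0), pattern = character(0),
              seq_index = integer(0), seq_name = character(0),
              start = integer(0), end = integer(0),
              mechanism = character(0), stringsAsFactors = FALSE)
}

.make_hits <- function(query, index, seq_idx, start, mechanism) {
  if (length(seq_idx) == 0) return(.empty_hits())
  ord <- order(seq_idx, start)
  seq_idx <- seq_idx[ord]
  start <- start[ord]
  data.frame(query_id = query$query_id, pattern = query$pattern,
             seq_index = as.integer(seq_idx),
             seq_name = index$seq_names[seq_idx + 1L],
             start = as.integer(start),
             end = as.integer(start + query$l),
             mechanism = mechanism, stringsAsFactors = FALSE)
}

.flatten_postings <- function(postings) {
  if (length(postings) == 0) {
    return(cbind(i = integer(0), p = integer(0)))
  }
  do.call(rbind, postings)
}

#' Find occurrences of a short query as suffixes of indexed words
#'
#' Scans the contiguous key interval of all k-words ending in the query
#' (see [suffix_key_range()]) and reports each posting `(i, p)` as an
#' occurrence starting at `p + (k - l)`.  This finds exactly the
#' occurrences with 0-based start >= k - l; anything closer to a sequence
#' beginning is not the suffix of any indexed word and is invisible to this
#' mechanism.
#'
#' @param index A `kmer_index`.
#' @param query A `query_pattern` or a plain DNA string.
#' @return Hit data frame with columns `query_id`, `pattern`, `seq_index`,
#'   `seq_name`, `start`, `end` (0-based, half-open) and `mechanism`,
#'   sorted by `(seq_index, start)`.
#' @examples
#' idx <- build_index(c(S2 = "CTTAAC"), k = 4)
#' search_suffix(idx, "AA")  # one hit at start 3, via the word TTAA
#' @export
search_suffix <- function(index, query) {
  stopifnot(inherits(index, "kmer_index"))
  query <- .as_query(query)
  .check_query_fits(query, index)
  rng <- suffix_key_range(query$key, query$l, index$k)
  scan <- range_scan(index, rng$low, rng$high)
  posts <- .flatten_postings(scan$postings)
  hits <- .make_hits(query, index, posts[, "i"],
                     posts[, "p"] + (index$k - query$l), "suffix")
  attr(hits, "keys_examined") <- scan$keys_examined
  hits
}

#' Find occurrences of a short query as prefixes of indexed words
#'
#' Scans the key interval of [prefix_key_params()] and keeps the keys whose
#' difference from the query's conversion value is divisible by `4^l`
#' (low-order digits equal the query).  Each posting of a surviving key is
#' an occurrence starting at `p` itself.  Prefix hits exist at any position
#' where an indexed word starts; their diagnostic value is the range
#' `start < k - l`, the beginning-of-sequence occurrences suffix search
#' cannot see.
#'
#' @inheritParams search_suffix
#' @return Hit data frame as in [search_suffix()], `mechanism = "prefix"`.
#' @export
search_prefix <- function(index, query) {
  stopifnot(inherits(index, "kmer_index"))
  query <- .as_query(query)
  .check_query_fits(query, index)
  par <- prefix_key_params(query$key, query$l, index$k)
  scan <- range_scan(index, par$low, par$high)
  keep <- key_matches_prefix(scan$keys, par)
  posts <- .flatten_postings(scan$postings[keep])
  hits <- .make_hits(query, index, posts[, "i"], posts[, "p"], "prefix")
  attr(hits, "keys_examined") <- scan$keys_examined
  hits
}

#' Find all exact occurrences of a short query
#'
#' Union of both mechanisms: every suffix hit, plus the prefix hits with
#' start `< k - l` (interior occurrences are found by both mechanisms, so
#' the suffix result is authoritative there and the prefix contribution is
#' restricted to the starts suffix search cannot reach).  For sequences of
#' length at least `2k - l - 1` this is every occurrence; shorter sequences
#' may hide interior occurrences that neither begin nor end an indexed
#' word (and sequences shorter than `k` are invisible entirely).
#'
#' @inheritParams search_suffix
#' @return Hit data frame; `mechanism` records which search found each hit.
#' @examples
#' idx <- build_index(c(read = "TACACAACATAAT"), k = 8)
#' search_all(idx, "TACACA")  # start-0 hit found by the prefix mechanism
#' @export
search_all <- function(index, query) {
  stopifnot(inherits(index, "kmer_index"))
  query <- .as_query(query)
  .check_query_fits(query, index)
  sfx <- search_suffix(index, query)
  pfx <- search_prefix(index, query)
  pfx <- pfx[pfx$start < index$k - query$l, , drop = FALSE]
  out <- rbind(sfx, pfx)
  out <- out[order(out$seq_index, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Search a batch of queries and tabulate per-query hit counts
#'
#' Runs every query in the requested mode and always computes the
#' per-query summary comparing the combined search with suffix-only lookup:
#' `hits_all - hits_suffix_only` is the number of beginning-of-sequence
#' occurrences (starts `< k - l`) that suffix-only search leaves unreported.
#'
#' @param index A `kmer_index`.
#' @param queries List of `query_pattern`s or character vector of patterns.
#' @param mode `"all"` (default), `"suffix_only"` or `"prefix_only"`;
#'   selects which hits populate the hit table.
#' @return List with `hits` (hit data frame in query input order, then
#'   `(seq_index, start)`) and `summary` (data frame with `query_id`,
#'   `pattern`, `conversion_value`, `hits_all`, `hits_suffix_only`,
#'   `hits_unreported_by_suffix_only`).
#' @export
search_batch <- function(index, queries,
                         mode = c("all", "suffix_only", "prefix_only")) {
  stopifnot(inherits(index, "kmer_index"))
  mode <- match.arg(mode)
  if (is.character(queries)) queries <- lapply(queries, query_pattern)
  if (inherits(queries, "query_pattern")) queries <- list(queries)
  for (q in queries) .check_query_fits(.as_query(q), index)

  hit_list <- vector("list", length(queries))
  summ <- vector("list", length(queries))
  for (j in seq_along(queries)) {
    q <- .as_query(queries[[j]])
    all_hits <- search_all(index, q)
    n_all <- nrow(all_hits)
    n_sfx <- sum(all_hits$mechanism == "suffix")
    hit_list[[j]] <- switch(
      mode,
      all = all_hits,
      suffix_only = all_hits[all_hits$mechanism == "suffix", , drop = FALSE],
      prefix_only = search_prefix(index, q)
    )
    summ[[j]] <- data.frame(
      query_id = q$query_id, pattern = q$pattern, conversion_value = q$key,
      hits_all = n_all, hits_suffix_only = n_sfx,
      hits_unreported_by_suffix_only = n_all - n_sfx,
      stringsAsFactors = FALSE
    )
  }
  hits <- do.call(rbind, c(list(.empty_hits()), hit_list))
  rownames(hits) <- NULL
  list(hits = hits, summary = do.call(rbind, summ))
}

#' @export
print.query_pattern <- function(x, ...) {
  cat("<query_pattern>", x$query_id, ":", x$pattern,
      "(l =", paste0(x$l, ","), "f(q) =",
      format(x$key, scientific = FALSE), ")\n")
  invisible(x)
}
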