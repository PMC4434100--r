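# Seeded synthetic fixtures and the brute-force occurrence oracle.
#
# The oracle is a direct substring comparison at every possible start, with
# no k limit and no indexing; everything else in the package is tested
# against it, never the other way round.  Random generation uses R's
# Mersenne-Twister generator under an explicit seed, with the caller's RNG
# state restored afterwards, so fixtures are byte-reproducible.

# run code under a fixed seed without disturbing the global RNG state
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

#' Generate a random DNA sequence
#'
#' Draws `length` bases independently from `{A, C, G, T}` with the given
#' weights, deterministically for a fixed `(length, seed, base_weights)`.
#'
#' @param length Number of bases (>= 0).
#' @param seed Integer seed.
#' @param base_weights Proportions for A, C, G, T; must sum to 1.
#' @return A single DNA string.
#' @examples
#' generate_sequence(10, seed = 1)
#' @export
generate_sequence <- function(length, seed,
                              base_weights = c(0.25, 0.25, 0.25, 0.25)) {
  if (!is.numeric(length) || length < 0 || length != round(length)) {
    stop("`length` must be a non-negative integer", call. = FALSE)
  }
  if (length(base_weights) != 4 || any(base_weights < 0) ||
      abs(sum(base_weights) - 1) > 1e-8) {
    stop("`base_weights` must be 4 non-negative proportions summing to 1",
         call. = FALSE)
  }
  if (length == 0) return("")
  .with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                 prob = base_weights), collapse = "")
  })
}

#' Brute-force enumeration of all exact occurrences
#'
#' The testing oracle: compares the pattern against the substring at every
#' start of every sequence.  Overlapping occurrences count separately and
#' there is no word-length limit.
#'
#' @param sequences Character vector of DNA strings (or anything accepted by
#'   [build_index()]).
#' @param pattern DNA string, non-empty.
#' @return Data frame with `seq_index` (0-based) and `start` (0-based),
#'   sorted.
#' @examples
#' naive_all_occurrences("CTTAAC", "AA")   # seq 0, start 3
#' naive_all_occurrences("AAAAA", "AAA")   # starts 0, 1, 2
#' @export
naive_all_occurrences <- function(sequences, pattern) {
  seqs <- .as_seq_vector(sequences)
  pattern <- toupper(pattern)
  l <- nchar(pattern)
  if (l == 0) stop("`pattern` must be non-empty", call. = FALSE)
  out <- lapply(seq_along(seqs), function(j) {
    n <- nchar(seqs[j])
    if (n < l) return(NULL)
    starts <- 1:(n - l + 1)
    hit <- substring(seqs[j], starts, starts + l - 1) == pattern
    if (!any(hit)) return(NULL)
    data.frame(seq_index = j - 1L, start = starts[hit] - 1L)
  })
  out <- do.call(rbind, c(list(data.frame(seq_index = integer(0),
                                          start = integer(0))), out))
  rownames(out) <- NULL
  out
}

#' Overwrite sequences with planted pattern occurrences
#'
#' Writes `pattern` into the given `(seq_index, start)` placements and
#' recomputes the ground truth with [naive_all_occurrences()], so the truth
#' includes both the planted occurrences and any incidental ones the
#' background (or the planting itself) created.
#'
#' @param sequences Character vector of DNA strings.
#' @param pattern DNA string to plant.
#' @param placements Data frame with columns `seq_index` (0-based) and
#'   `start` (0-based); placements must fit inside their sequence and must
#'   not overlap one another.
#' @return List with `sequences` (modified) and `truth` (occurrence data
#'   frame as from the oracle).
#' @export
plant_occurrences <- function(sequences, pattern, placements) {
  seqs <- .as_seq_vector(sequences)
  pattern <- toupper(pattern)
  l <- nchar(pattern)
  stopifnot(is.data.frame(placements),
            all(c("seq_index", "start") %in% names(placements)))
  for (r in seq_len(nrow(placements))) {
    i <- placements$seq_index[r]
    s <- placements$start[r]
    if (i < 0 || i >= length(seqs)) {
      stop("placement row ", r, ": no sequence with index ", i, call. = FALSE)
    }
    n <- nchar(seqs[i + 1])
    if (s < 0 || s + l > n) {
      stop("placement row ", r, ": start ", s, " does not fit a ", l,
           "-base pattern in a ", n, "-base sequence", call. = FALSE)
    }
    same <- placements$seq_index == i & seq_len(nrow(placements)) < r
    if (any(abs(placements$start[same] - s) < l)) {
      stop("placement row ", r, " overlaps an earlier placement",
           call. = FALSE)
    }
    substr(seqs[i + 1], s + 1, s + l) <- pattern
  }
  list(sequences = seqs, truth = naive_all_occurrences(seqs, pattern))
}

#' Generate a benchmark database with planted occurrences and ground truth
#'
#' Builds a seeded random database and, for every query, plants at least one
#' occurrence in the beginning-of-sequence zone (`start < k - l`, the class
#' suffix-only search misses — only possible when `l < k`) and one in the
#' interior (`start >= k - l`).  Placement positions are drawn by rejection
#' so plantings never overlap.  The truth table is recomputed by the naive
#' oracle on the final sequences, so incidental occurrences are included.
#'
#' @param k Indexed word length the fixture targets.
#' @param num_sequences Number of database sequences.
#' @param length_range Length 2 vector; sequence lengths drawn uniformly
#'   from this range.  The minimum must be at least `2k` so every planting
#'   zone exists.
#' @param queries Character vector of query patterns, all of length <= k.
#' @param seed Integer seed; fixes sequences, lengths and placements.
#' @param fasta,truth Optional paths; when given, the database is written as
#'   FASTA and the truth as a TSV with columns `pattern`, `seq_name`,
#'   `start`.
#' @return List with `sequences` (named character vector), `truth` (data
#'   frame `pattern`, `seq_index`, `seq_name`, `start`), and `k`.
#' @export
make_benchmark_set <- function(k, num_sequences, length_range, queries,
                               seed, fasta = NULL, truth = NULL) {
  stopifnot(length(length_range) == 2, length_range[1] <= length_range[2])
  queries <- toupper(queries)
  if (any(nchar(queries) > k)) {
    stop("all query lengths must be <= k = ", k, call. = FALSE)
  }
  if (length_range[1] < 2 * k) {
    stop("minimum sequence length must be at least 2k so both planting ",
         "zones exist", call. = FALSE)
  }
  res <- .with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], num_sequences,
                   replace = TRUE)
    seqs <- vapply(lens, function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- sprintf("synth_seq_%03d", seq_len(num_sequences) - 1L)

    # occupied[[i]]: starts (1-based) of bases already claimed by a planting
    occupied <- rep(list(integer(0)), num_sequences)
    claim_free <- function(i, s, l) {
      !any(occupied[[i + 1]] %in% (s + 1):(s + l))
    }
    plant_one <- function(pattern, zone) {
      l <- nchar(pattern)
      for (attempt in 1:1000) {
        i <- sample.int(num_sequences, 1) - 1L
        n <- nchar(seqs[i + 1])
        s <- if (zone == "begin") {
          sample.int(k - l, 1) - 1L           # start in [0, k-l-1]
        } else {
          (k - l) + sample.int(n - l + 1 - (k - l), 1) - 1L
        }
        if (claim_free(i, s, l)) {
          substr(seqs[i + 1], s + 1, s + l) <<- pattern
          occupied[[i + 1]] <<- c(occupied[[i + 1]], (s + 1):(s + l))
          return(invisible(NULL))
        }
      }
      stop("could not place pattern '", pattern, "' without overlap",
           call. = FALSE)
    }
    for (q in queries) {
      if (nchar(q) < k) plant_one(q, "begin")
      plant_one(q, "interior")
    }
    seqs
  })

  truth_df <- do.call(rbind, lapply(queries, function(q) {
    occ <- naive_all_occurrences(res, q)
    if (nrow(occ) == 0) {
      return(data.frame(pattern = character(0), seq_index = integer(0),
                        seq_name = character(0), start = integer(0)))
    }
    data.frame(pattern = q, seq_index = occ$seq_index,
               seq_name = names(res)[occ$seq_index + 1L], start = occ$start)
  }))
  rownames(truth_df) <- NULL

  if (!is.null(fasta)) write_fasta(res, fasta)
  if (!is.null(truth)) {
    utils::write.table(truth_df[c("pattern", "seq_name", "start")], truth,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(sequences = res, truth = truth_df, k = k)
}
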