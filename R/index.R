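# Sorted-dictionary index of overlapping k-words.
#
# The index is built dynamically: only words actually present in the database
# get a key, so no memory is spent on the 4^k - (distinct words) redundant
# entries a precomputed hash table would reserve.  Keys are held in a sorted
# array with parallel posting lists, which realizes the ordered-map contract
# the search phase relies on: ascending iteration from a binary-searched
# lower bound, stopping at the first key past the upper bound.

# Window keys of one sequence: 0-based start positions and their keys.
# Windows containing a non-ACGT character are skipped; the rolling recurrence
# restarts with a direct encode at the next clean window.  The first window
# of each clean run is encoded directly (k-1 multiply-adds); every later
# window uses the 4-operation rolling update.
.seq_window_keys <- function(residues, k) {
  d <- .word_digits(residues, allow_invalid = TRUE)
  n <- length(d)
  if (n < k) {
    return(list(pos = integer(0), keys = numeric(0)))
  }
  runs <- rle(!is.na(d))
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1
  pos_all <- vector("list", length(runs$lengths))
  key_all <- vector("list", length(runs$lengths))
  hi <- .POW4[k]  # 4^(k-1)
  for (r in seq_along(runs$lengths)) {
    if (!runs$values[r] || runs$lengths[r] < k) next
    s <- run_start[r]
    m <- runs$lengths[r] - k + 1
    dd <- d[s:(run_end[r])]
    keys <- numeric(m)
    key <- sum(dd[1:k] * .POW4[1:k])
    keys[1] <- key
    if (m > 1) {
      for (j in 2:m) {
        # rolling recurrence: drop leftmost digit, shift, append incoming
        key <- (key - dd[j - 1]) / 4 + dd[j + k - 1] * hi
        keys[j] <- key
      }
    }
    pos_all[[r]] <- (s - 1):(s - 1 + m - 1)  # 0-based
    key_all[[r]] <- keys
  }
  list(pos = as.integer(unlist(pos_all)), keys = as.numeric(unlist(key_all)))
}

# assemble the sorted structure from flat (key, i, p) triples
.assemble_index <- function(k, keys, seq_idx, pos, seq_names, seq_lengths) {
  if (length(keys) == 0) {
    return(structure(
      list(k = k, keys = numeric(0), postings = list(),
           seq_names = seq_names, seq_lengths = seq_lengths),
      class = "kmer_index"
    ))
  }
  ord <- order(keys, seq_idx, pos)
  keys <- keys[ord]
  seq_idx <- seq_idx[ord]
  pos <- pos[ord]
  first <- c(TRUE, keys[-1] != keys[-length(keys)])
  grp <- cumsum(first)
  postings <- lapply(
    split(seq_len(length(keys)), grp),
    function(ix) cbind(i = seq_idx[ix], p = pos[ix])
  )
  names(postings) <- NULL
  structure(
    list(k = k, keys = keys[first], postings = postings,
         seq_names = seq_names, seq_lengths = seq_lengths),
    class = "kmer_index"
  )
}

# normalize sequence input to a named character vector of upper-case strings
.as_seq_vector <- function(sequences) {
  if (inherits(sequences, "XStringSet")) {
    out <- toupper(as.character(sequences))
    if (is.null(names(out))) names(out) <- sprintf("seq%d", seq_along(out))
    return(out)
  }
  if (is.data.frame(sequences) && all(c("name", "residues") %in%
                                      names(sequences))) {
    out <- toupper(sequences$residues)
    names(out) <- sequences$name
    return(out)
  }
  if (is.character(sequences)) {
    out <- toupper(sequences)
    if (is.null(names(out))) names(out) <- sprintf("seq%d", seq_along(out))
    return(out)
  }
  stop("`sequences` must be a character vector, a DNAStringSet, or a ",
       "data frame with columns `name` and `residues`", call. = FALSE)
}

#' Build a sorted-dictionary k-word index
#'
#' Scans every sequence with a window of width `k` and records each valid
#' window's conversion value together with a posting `(i, p)`: the 0-based
#' index of the sequence and the 0-based start of the window.  After the
#' first window of each clean run, successive keys come from the
#' constant-time rolling recurrence (see [roll_key()]), so the scan is
#' linear in the database size.  Only observed words receive an entry, and
#' every stored key points at least one posting.
#'
#' Windows containing non-ACGT characters (N, IUPAC ambiguity codes) are
#' skipped and the recurrence restarts after them.  Sequences shorter than
#' `k` contribute no postings; a warning reports how many were skipped, since
#' occurrences inside them are invisible to the method.
#'
#' @param sequences Named character vector of DNA strings, a
#'   `Biostrings::DNAStringSet`, or a data frame from [read_fasta()].
#' @param k Word length in bases (the experiments motivating the method use
#'   `k = 8`).
#' @return A `kmer_index` object.
#' @examples
#' idx <- build_index(c(S2 = "CTTAAC"), k = 4)
#' key_count(idx)  # 3 distinct words: CTTA, TTAA, TAAC
#' @export
build_index <- function(sequences, k) {
  bounds <- valid_key_bounds(k)  # validates k
  seqs <- .as_seq_vector(sequences)
  short <- sum(nchar(seqs) < k)
  if (short > 0) {
    warning(short, " sequence(s) shorter than k = ", k,
            " contribute no indexed words; occurrences inside them cannot ",
            "be found", call. = FALSE)
  }
  per <- lapply(seqs, .seq_window_keys, k = k)
  counts <- vapply(per, function(x) length(x$pos), integer(1))
  .assemble_index(
    k,
    keys = unlist(lapply(per, `[[`, "keys"), use.names = FALSE),
    seq_idx = rep.int(seq_along(seqs) - 1L, counts),
    pos = unlist(lapply(per, `[[`, "pos"), use.names = FALSE),
    seq_names = names(seqs),
    seq_lengths = unname(nchar(seqs))
  )
}

#' Append one sequence to an existing index
#'
#' Re-scans only the new record and merges its postings, leaving an index
#' identical to one built from scratch with the record appended.  The new
#' sequence receives the next 0-based sequence index.
#'
#' @param index A `kmer_index`.
#' @param residues DNA string of the new record.
#' @param name Record name; defaults to `seq<i>` for the new index i.
#' @return The extended `kmer_index`.
#' @export
add_sequence <- function(index, residues, name = NULL) {
  stopifnot(inherits(index, "kmer_index"))
  i_new <- length(index$seq_names)
  if (is.null(name)) name <- paste0("seq", i_new)
  if (name %in% index$seq_names) {
    stop("a sequence named '", name, "' is already indexed", call. = FALSE)
  }
  residues <- toupper(residues)
  if (nchar(residues) < index$k && nzchar(residues)) {
    warning("sequence shorter than k = ", index$k,
            " contributes no indexed words", call. = FALSE)
  }
  new <- .seq_window_keys(residues, index$k)
  index$seq_names <- c(index$seq_names, name)
  index$seq_lengths <- c(index$seq_lengths, unname(nchar(residues)))
  if (length(new$pos) == 0) return(index)

  ord <- order(new$keys, new$pos)
  nk <- new$keys[ord]
  np <- new$pos[ord]
  first <- c(TRUE, nk[-1] != nk[-length(nk)])
  grp <- cumsum(first)
  new_keys <- nk[first]
  new_posts <- lapply(split(seq_along(nk), grp),
                      function(ix) cbind(i = rep.int(i_new, length(ix)),
                                         p = np[ix]))
  names(new_posts) <- NULL

  hit <- match(new_keys, index$keys)
  # existing keys: new postings append after old ones (larger seq index)
  for (j in which(!is.na(hit))) {
    at <- hit[j]
    index$postings[[at]] <- rbind(index$postings[[at]], new_posts[[j]])
  }
  fresh <- is.na(hit)
  if (any(fresh)) {
    all_keys <- c(index$keys, new_keys[fresh])
    all_posts <- c(index$postings, new_posts[fresh])
    ord2 <- order(all_keys)
    index$keys <- all_keys[ord2]
    index$postings <- all_posts[ord2]
  }
  index
}

#' Scan the stored keys of an interval in ascending order
#'
#' Binary-searches the lower bound of `low`, then walks forward until the
#' first key above `high`; no key outside the interval (beyond that
#' terminating one) is touched, so the cost is proportional to the number of
#' keys in range, not the index size.
#'
#' @param index A `kmer_index`.
#' @param low,high Inclusive key interval, `low <= high`.
#' @return List with `keys` (ascending numeric), `postings` (parallel list
#'   of `(i, p)` matrices), and `keys_examined` (keys touched during the
#'   walk, at most one more than the number returned).
#' @export
range_scan <- function(index, low, high) {
  stopifnot(inherits(index, "kmer_index"))
  if (low > high) stop("`low` must not exceed `high`", call. = FALSE)
  keys <- index$keys
  n <- length(keys)
  lb <- findInterval(low, keys, left.open = TRUE) + 1L  # first key >= low
  ub <- lb - 1L
  examined <- 0L
  while (ub + 1L <= n) {
    examined <- examined + 1L
    if (keys[ub + 1L] > high) break  # early termination
    ub <- ub + 1L
  }
  if (ub < lb) {
    return(list(keys = numeric(0), postings = list(),
                keys_examined = examined))
  }
  list(keys = keys[lb:ub], postings = index$postings[lb:ub],
       keys_examined = examined)
}

#' Index size statistics
#'
#' `key_count()` is the number of distinct indexed words (the size a
#' dynamically built dictionary actually needs); `posting_count()` the total
#' number of indexed windows; `redundant_key_count()` the `4^k - key_count`
#' entries a precomputed hash table would reserve for words absent from the
#' database.
#'
#' @param index A `kmer_index`.
#' @return A single number.
#' @export
key_count <- function(index) {
  stopifnot(inherits(index, "kmer_index"))
  length(index$keys)
}

#' @rdname key_count
#' @export
posting_count <- function(index) {
  stopifnot(inherits(index, "kmer_index"))
  if (length(index$postings) == 0) return(0)
  sum(vapply(index$postings, nrow, integer(1)))
}

#' @rdname key_count
#' @export
redundant_key_count <- function(index) {
  stopifnot(inherits(index, "kmer_index"))
  .POW4[index$k + 1] - key_count(index)
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index> k =", x$k, "\n")
  cat("  sequences:", length(x$seq_names),
      " total bases:", sum(x$seq_lengths), "\n")
  cat("  distinct keys:", key_count(x),
      " postings:", posting_count(x), "\n")
  invisible(x)
}

# ---- persistence: plain-text index format, version 1 ------------------------
#
#   #kmerdict-index<TAB>1
#   #k<TAB>8
#   #nkeys<TAB>3
#   #seq<TAB>0<TAB>S2<TAB>6
#   90<TAB>0:1
#   108<TAB>0:0
#   ...
#
# One body line per key, ascending; postings "i:p" comma-separated.

.INDEX_MAGIC <- "#kmerdict-index"
.INDEX_VERSION <- 1L

#' Save / load an index as versioned plain text
#'
#' The format is line-oriented and human-readable: a header with magic,
#' version, `k`, the key count, and the sequence table, followed by one line
#' per key in ascending order with its comma-separated `i:p` postings.
#' `load_index()` validates magic, version and key count, so truncated or
#' foreign files are rejected.
#'
#' @param index A `kmer_index`.
#' @param path File path.
#' @return `save_index()` returns `path` invisibly; `load_index()` returns
#'   the reconstructed `kmer_index`.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "kmer_index"))
  nm <- index$seq_names
  if (any(grepl("[\t\n]", nm))) {
    warning("tab/newline in sequence name(s) replaced by space in index file",
            call. = FALSE)
    nm <- gsub("[\t\n]", " ", nm)
  }
  header <- c(
    paste(.INDEX_MAGIC, .INDEX_VERSION, sep = "\t"),
    paste("#k", index$k, sep = "\t"),
    paste("#nkeys", length(index$keys), sep = "\t"),
    sprintf("#seq\t%d\t%s\t%d", seq_along(nm) - 1L, nm, index$seq_lengths)
  )
  body <- if (length(index$keys) == 0) character(0) else {
    posts <- vapply(index$postings, function(m) {
      paste(sprintf("%d:%d", m[, "i"], m[, "p"]), collapse = ",")
    }, character(1))
    sprintf("%s\t%s", format(index$keys, scientific = FALSE, trim = TRUE),
            posts)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], .INDEX_MAGIC)) {
    stop("not a kmerdict index file: ", path, call. = FALSE)
  }
  ver <- as.integer(strsplit(lines[1], "\t", fixed = TRUE)[[1]][2])
  if (is.na(ver) || ver != .INDEX_VERSION) {
    stop("unsupported index version: ", lines[1], call. = FALSE)
  }
  get_field <- function(tag) {
    ln <- lines[startsWith(lines, paste0("#", tag, "\t"))]
    if (length(ln) != 1) stop("malformed index header: missing #", tag,
                              call. = FALSE)
    strsplit(ln, "\t", fixed = TRUE)[[1]][-1]
  }
  k <- as.integer(get_field("k"))
  nkeys <- as.integer(get_field("nkeys"))
  seq_lines <- lines[startsWith(lines, "#seq\t")]
  seq_parts <- strsplit(seq_lines, "\t", fixed = TRUE)
  seq_names <- vapply(seq_parts, `[`, character(1), 3)
  seq_lengths <- as.integer(vapply(seq_parts, `[`, character(1), 4))
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) != nkeys) {
    stop("index file corrupt or truncated: expected ", nkeys,
         " key lines, found ", length(body), call. = FALSE)
  }
  if (nkeys == 0) {
    return(.assemble_index(k, numeric(0), integer(0), integer(0),
                           seq_names, seq_lengths))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  keys <- as.numeric(vapply(parts, `[`, character(1), 1))
  postings <- lapply(parts, function(pp) {
    ip <- strsplit(strsplit(pp[2], ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    cbind(i = as.integer(vapply(ip, `[`, character(1), 1)),
          p = as.integer(vapply(ip, `[`, character(1), 2)))
  })
  if (anyNA(keys) || is.unsorted(keys, strictly = TRUE)) {
    stop("index file corrupt: keys not strictly ascending", call. = FALSE)
  }
  structure(
    list(k = k, keys = keys, postings = postings,
         seq_names = seq_names, seq_lengths = seq_lengths),
    class = "kmer_index"
  )
}
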