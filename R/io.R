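# FASTA / query ingestion and hit-table output.

#' Read a multi-record DNA FASTA file
#'
#' Wrapped lines are concatenated, case is folded to upper, record order is
#' preserved and the full header line (minus `>`) is kept as the name.
#' Ambiguity codes such as N are accepted here; windows containing them are
#' skipped later, at indexing time.
#'
#' @param path FASTA file path.
#' @return Data frame with columns `seq_index` (0-based), `name`, `length`
#'   and `residues`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) {
      stop("cannot parse FASTA file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0) {
    stop("FASTA file '", path, "' contains no records", call. = FALSE)
  }
  res <- toupper(as.character(set))
  data.frame(seq_index = seq_along(res) - 1L,
             name = gsub("[\t\n]", " ", names(set)),
             length = unname(nchar(res)),
             residues = unname(res),
             stringsAsFactors = FALSE)
}

#' Write sequences as FASTA
#'
#' @param sequences Named character vector of DNA strings.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70) {
  seqs <- .as_seq_vector(sequences)
  con <- file(path, open = "wb")  # fixed LF endings => byte-reproducible
  on.exit(close(con))
  for (j in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[j]), con, sep = "\n")
    n <- nchar(seqs[j])
    starts <- seq(1, max(n, 1), by = width)
    if (n > 0) {
      writeLines(substring(seqs[j], starts, pmin(starts + width - 1, n)),
                 con, sep = "\n")
    }
  }
  invisible(path)
}

#' Read query patterns from plain text or FASTA
#'
#' A file whose first non-blank line starts with `>` is parsed as FASTA
#' (headers become query ids); otherwise one pattern per line, blank lines
#' ignored, with ids `L<line>` from the line number.  Every pattern is
#' validated as non-empty ACGT and gets its conversion value computed.
#'
#' @param path Query file path.
#' @return List of `query_pattern` objects.
#' @export
read_queries <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    stop("query file '", path, "' is empty", call. = FALSE)
  }
  if (startsWith(trimws(lines[nonblank[1]]), ">")) {
    fa <- read_fasta(path)
    return(lapply(seq_len(nrow(fa)), function(j) {
      query_pattern(fa$residues[j], query_id = fa$name[j])
    }))
  }
  lapply(nonblank, function(ln) {
    query_pattern(trimws(lines[ln]), query_id = paste0("L", ln))
  })
}

#' Write a hit table as TSV
#'
#' Columns `query_id`, `pattern`, `seq_name`, `start`, `end`.  Coordinates
#' are 0-based half-open by default; with `one_based = TRUE` they are
#' rendered 1-based inclusive (`start + 1`, same `end`).
#'
#' @param hits Hit data frame from the search functions.
#' @param path Output path.
#' @param one_based Render coordinates 1-based inclusive.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path, one_based = FALSE) {
  out <- hits[c("query_id", "pattern", "seq_name", "start", "end",
                "mechanism")]
  if (one_based) out$start <- out$start + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a per-query summary table as TSV
#'
#' @param summary Summary data frame from [search_batch()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
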