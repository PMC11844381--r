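zdna_parse_error <- function(msg) {
  structure(class = c("zdna_parse_error", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Read a FASTA file of DNA sequences
#'
#' Reads a multi-record FASTA file (plain or gzip-compressed, detected from
#' the file contents) into a data frame of records.  Multi-line sequences
#' are joined and blank lines tolerated.  Record identifiers are the header
#' text up to the first whitespace; duplicated identifiers are suffixed
#' deterministically (`make.unique` with `_`).  Sequences are normalized
#' with [normalize_sequence()]: uppercased, U mapped to T, non-IUPAC
#' characters retained with a warning.
#'
#' @param path Path to the FASTA file.
#'
#' @return A data frame with columns `record_id` and `sequence`, one row per
#'   record, in file order.  An empty file yields a zero-row data frame with
#'   a warning.
#'
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "GCGC", ">s2", "AT", "AT"), fa)
#' read_fasta(fa)
#'
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop(zdna_parse_error(paste0("FASTA file not found: ", path)))

  # gzfile() reads plain text transparently as well
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- tryCatch(readLines(con, warn = FALSE),
                    error = function(e)
                      stop(zdna_parse_error(paste0("cannot read '", path,
                                                   "': ", conditionMessage(e)))))

  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warning("FASTA file '", path, "' contains no records", call. = FALSE)
    return(data.frame(record_id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop(zdna_parse_error(sprintf(
      "malformed FASTA '%s': sequence data before first header at line %d",
      path, nonblank[1L])))

  # Biostrings handles the actual parsing (wrapped lines, gzip, large files);
  # BStringSet is used rather than DNAStringSet so that stray characters are
  # retained and scored as mismatches instead of rejected.
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop(zdna_parse_error(paste0("malformed FASTA '", path,
                                                 "': ", conditionMessage(e)))))

  ids <- sub("\\s.*$", "", names(set))
  ids[!nzchar(ids)] <- "unnamed"
  if (anyDuplicated(ids))
    ids <- make.unique(ids, sep = "_")
  seqs <- vapply(as.character(set), normalize_sequence, "", USE.NAMES = FALSE)
  data.frame(record_id = ids, sequence = seqs, stringsAsFactors = FALSE)
}
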