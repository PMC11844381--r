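# Minimal decimal rendering of scores (45.5, 63.75, 63 -- no padding,
# no trailing zeros, no scientific notation).
format_score <- function(x) {
  vapply(x, function(s) format(s, scientific = FALSE, trim = TRUE,
                               drop0trailing = TRUE), "")
}

#' Write hits to CSV
#'
#' Writes a hit table in the standard output layout: a comment line stating
#' the coordinate convention, a header row
#' `Sequence_name,Start,End,Z-DNA_Score,Sequence`, and one row per hit.
#' Coordinates are 0-based with inclusive ends; scores are printed in
#' minimal decimal form.
#'
#' @param hits A hit data frame from [find_candidate_regions()] or
#'   [run_scan()].
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_hits_csv <- function(hits, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "# Coordinates are 0-based; Start and End are inclusive nucleotide positions.",
    "Sequence_name,Start,End,Z-DNA_Score,Sequence"
  ), con)
  if (nrow(hits) > 0L)
    writeLines(paste(hits$record_id, hits$start, hits$end,
                     format_score(hits$score), hits$subsequence, sep = ","),
               con)
  invisible(path)
}

#' Scan FASTA input for potential Z-DNA-forming sequences
#'
#' The end-to-end pipeline: read one or more FASTA files, score every record
#' with [score_steps()], extract candidate regions with
#' [find_candidate_regions()], and write a CSV of all hits (plus optional
#' summary plots).  Records are the unit of parallel work; results are
#' gathered and ordered (input order, then start coordinate) before writing,
#' so output bytes are identical regardless of `workers`.
#'
#' @param fasta Character vector of FASTA paths (plain or gzip).
#' @param output Path of the CSV file to write, or `NULL` to skip writing.
#' @param params A [scoring_params()] object.
#' @param report_best Per record, report the single best region even when it
#'   is below the threshold.  Default `FALSE`.
#' @param workers Number of parallel workers (forked processes; values > 1
#'   fall back to serial on platforms without fork).  Default 1.
#' @param plots Also write a score-vs-length scatter plot and a score
#'   boxplot next to the CSV.  Default `FALSE`.
#' @param plot_prefix File-name prefix for plots; defaults to `output`
#'   without its extension.
#' @param verbose Log progress and a run summary to standard error.
#'
#' @return Invisibly, a list with `hits` (the combined hit data frame),
#'   `n_records`, `n_failed`, and `output`.
#'
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">mutant", "GCGCGTGCATATGCGTG"), fa)
#' res <- run_scan(fa, output = tempfile(fileext = ".csv"), verbose = FALSE)
#' res$hits
#'
#' @export
run_scan <- function(fasta, output, params = scoring_params(),
                     report_best = FALSE, workers = 1L, plots = FALSE,
                     plot_prefix = NULL, verbose = TRUE) {
  stopifnot(inherits(params, "zdna_params"))
  workers <- max(1L, as.integer(workers))
  t0 <- Sys.time()
  log_msg <- function(...) if (verbose) message(...)

  records <- do.call(rbind, lapply(fasta, read_fasta))
  n_records <- if (is.null(records)) 0L else nrow(records)
  log_msg("run_scan: ", n_records, " record(s) from ",
          length(fasta), " file(s)")

  scan_one <- function(i) {
    tryCatch({
      st <- score_steps(records[i, ], params)
      if (length(st$scores) == 0L)
        log_msg("record '", records$record_id[i],
                "': fewer than 2 bases, no steps to score")
      find_candidate_regions(st, params, report_best = report_best)
    }, error = function(e) e)
  }

  idx <- seq_len(n_records)
  results <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, scan_one, mc.cores = workers)
  } else {
    lapply(idx, scan_one)
  }

  failed <- vapply(results, inherits, TRUE, what = "error")
  for (i in which(failed))
    log_msg("record '", records$record_id[i], "' failed to score: ",
            conditionMessage(results[[i]]), " -- skipped")

  hit_list <- results[!failed]
  hits <- if (length(hit_list)) do.call(rbind, hit_list) else empty_hits()
  rownames(hits) <- NULL

  if (!is.null(output)) {
    write_hits_csv(hits, output)
    log_msg("run_scan: wrote ", nrow(hits), " hit(s) to ", output)
  }
  if (isTRUE(plots)) {
    if (is.null(plot_prefix))
      plot_prefix <- if (is.null(output)) "zdnascan" else
        sub("\\.[^.]*$", "", output)
    plot_summary(hits, plot_prefix)
  }
  if (nrow(hits) == 0L)
    log_msg("run_scan: no regions at or above threshold ",
            format(params$threshold))

  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  log_msg(sprintf(
    "run_scan: %d record(s) scanned, %d hit(s), %d failure(s), %.2f s",
    n_records, nrow(hits), sum(failed), elapsed))

  invisible(list(hits = hits, n_records = n_records,
                 n_failed = sum(failed), output = output))
}

#' Summary plots for a set of hits
#'
#' Writes two PNG files: `<prefix>_scatter.png`, a scatter plot of Z-DNA
#' score against region length, and `<prefix>_boxplot.png`, the score
#' distribution.  An empty hit table produces labelled empty plots.  A
#' failing graphics backend degrades to a warning; scan results are never
#' affected.
#'
#' @param hits A hit data frame.
#' @param prefix File-name prefix for the two files.
#'
#' @return Invisibly, the two file paths (or `NULL` on backend failure).
#' @export
plot_summary <- function(hits, prefix) {
  scatter <- paste0(prefix, "_scatter.png")
  box <- paste0(prefix, "_boxplot.png")
  ok <- tryCatch({
    grDevices::png(scatter, width = 800, height = 600)
    if (nrow(hits) > 0L) {
      len <- hits$end - hits$start + 1L
      graphics::plot(len, hits$score, xlab = "Region length (nt)",
                     ylab = "Z-DNA score",
                     main = "Z-DNA score vs region length", pch = 19,
                     col = "#2166ac")
    } else {
      graphics::plot.new()
      graphics::title(main = "Z-DNA score vs region length")
      graphics::text(0.5, 0.5, "no hits")
    }
    grDevices::dev.off()

    grDevices::png(box, width = 500, height = 600)
    if (nrow(hits) > 0L) {
      graphics::boxplot(hits$score, ylab = "Z-DNA score",
                        main = "Z-DNA score distribution")
    } else {
      graphics::plot.new()
      graphics::title(main = "Z-DNA score distribution")
      graphics::text(0.5, 0.5, "no hits")
    }
    grDevices::dev.off()
    TRUE
  }, error = function(e) {
    warning("plotting failed (", conditionMessage(e),
            "); scan results are unaffected", call. = FALSE)
    FALSE
  })
  invisible(if (ok) c(scatter = scatter, boxplot = box) else NULL)
}
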