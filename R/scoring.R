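# Dinucleotide step classes closed under reversal: GC = {GC, CG},
# GT = {GT, TG}, AC = {AC, CA}, AT = {AT, TA}.  Everything else
# (purine-purine, pyrimidine-pyrimidine, or any non-ACGT character)
# is a MISMATCH: it breaks the syn/anti alternation Z-DNA requires.
.step_class_table <- c(
  GC = "GC", CG = "GC",
  GT = "GT", TG = "GT",
  AC = "AC", CA = "AC",
  AT = "AT", TA = "AT"
)

#' Classify a dinucleotide step
#'
#' Assigns each ordered base pair to one of five step classes: `GC`
#' (covering GC and CG), `GT` (GT/TG), `AC` (AC/CA), `AT` (AT/TA), or
#' `MISMATCH` for every non-alternating step (purine followed by purine,
#' pyrimidine followed by pyrimidine, or any step touching a non-ACGT
#' character such as N or another IUPAC ambiguity code).
#'
#' @param base_a,base_b Character vectors of single bases (recycled to a
#'   common length).  Case-insensitive.
#'
#' @return Character vector of step class labels.
#'
#' @examples
#' classify_step("G", "C")   # "GC"
#' classify_step("T", "G")   # "GT"
#' classify_step("G", "A")   # "MISMATCH" (purine -> purine)
#' classify_step(c("A", "N"), c("T", "G"))
#'
#' @export
classify_step <- function(base_a, base_b) {
  key <- paste0(toupper(base_a), toupper(base_b))
  cls <- unname(.step_class_table[key])
  cls[is.na(cls)] <- "MISMATCH"
  cls
}

#' Penalty for the k-th step of a contiguous mismatch run
#'
#' Non-alternating steps are penalized with escalating severity so that
#' long interruptions extinguish a candidate region.  In linear mode the
#' k-th consecutive mismatch contributes `-(start + (k - 1) * delta)`;
#' in exponential mode `-(start * delta^(k - 1))`.
#'
#' @param k Integer vector of 1-based positions within a contiguous
#'   mismatch run; all values must be >= 1.
#' @param params A [scoring_params()] object.
#'
#' @return Numeric vector of (non-positive) score contributions.
#'
#' @examples
#' mismatch_penalty(1:3)  # -3 -6 -9 with the defaults
#'
#' @export
mismatch_penalty <- function(k, params = scoring_params()) {
  if (!is.numeric(k) || length(k) < 1L || any(!is.finite(k)) || any(k < 1))
    stop("`k` must contain positions >= 1 within a mismatch run", call. = FALSE)
  k <- as.numeric(k)
  if (params$mismatch_penalty_type == "linear") {
    -(params$mismatch_penalty_start + (k - 1) * params$mismatch_penalty_delta)
  } else {
    -(params$mismatch_penalty_start * params$mismatch_penalty_delta^(k - 1))
  }
}

#' Adjustment for the k-th step of a contiguous AT/TA run
#'
#' Looks up the consecutive-AT adjustment array: element `k` for the k-th
#' AT/TA step of a run, with the last element applied to every later step.
#' The value is *added* to `at_weight`, so with the defaults the first
#' three AT/TA steps of a run each score 0.5 + 0.5 = 1.0, the next two
#' 0.5, and from the seventh step onward 0.5 - 100.
#'
#' @param k Integer vector of 1-based positions within a contiguous AT/TA
#'   run.
#' @param params A [scoring_params()] object.
#'
#' @return Numeric vector of adjustments (same length as `k`).
#'
#' @examples
#' at_run_adjustment(c(1, 6, 7, 12))  # 0.5 -5 -100 -100
#'
#' @export
at_run_adjustment <- function(k, params = scoring_params()) {
  if (!is.numeric(k) || length(k) < 1L || any(!is.finite(k)) || any(k < 1))
    stop("`k` must contain positions >= 1 within an AT/TA run", call. = FALSE)
  adj <- params$consecutive_at_adjustments
  adj[pmin(as.integer(k), length(adj))]
}

# Coerce a character string or a list/data.frame row with fields
# `record_id` and `sequence` into a normalized record (uppercase, U -> T).
as_sequence_record <- function(record) {
  if (is.character(record) && length(record) == 1L && is.null(names(record))) {
    rec <- list(record_id = "seq", sequence = record)
  } else if ((is.list(record) || is.data.frame(record)) &&
             all(c("record_id", "sequence") %in% names(record))) {
    rec <- list(record_id = as.character(record$record_id)[1L],
                sequence = as.character(record$sequence)[1L])
  } else {
    stop("`record` must be a single DNA string or a list/data.frame with ",
         "`record_id` and `sequence` fields", call. = FALSE)
  }
  rec$sequence <- normalize_sequence(rec$sequence)
  rec
}

#' Normalize a DNA sequence string
#'
#' Uppercases the sequence and maps U to T.  Characters outside the IUPAC
#' nucleotide alphabet trigger a warning but are retained; any step that
#' touches them is scored as a mismatch.
#'
#' @param sequence A single character string.
#' @param warn Emit a warning for non-IUPAC characters (default `TRUE`).
#'
#' @return The normalized sequence string.
#' @export
normalize_sequence <- function(sequence, warn = TRUE) {
  s <- toupper(as.character(sequence))
  s <- gsub("U", "T", s, fixed = TRUE)
  if (warn && grepl("[^ACGTRYSWKMBDHVN]", s))
    warning("sequence contains characters outside the IUPAC alphabet; ",
            "they are retained and scored as mismatches", call. = FALSE)
  s
}

#' Score every dinucleotide step of a sequence
#'
#' Computes the per-step score array for one sequence: `gc_weight` for each
#' GC-class step, `gt_weight`/`ac_weight` for GT-/AC-class steps,
#' `at_weight + at_run_adjustment(k)` for the k-th AT-class step of a
#' contiguous AT/TA run, and `mismatch_penalty(k)` for the k-th step of a
#' contiguous mismatch run.  Both run counters reset whenever a step of any
#' other class occurs.  The array has one entry per adjacent base pair,
#' i.e. length `nchar(sequence) - 1`; sequences shorter than two bases
#' yield an empty array.
#'
#' @param record A DNA string, or a list/data.frame with `record_id` and
#'   `sequence` (e.g. one row of [read_fasta()] output).
#' @param params A [scoring_params()] object.
#'
#' @return An object of class `"zdna_steps"`: a list with `record_id`,
#'   `sequence` (normalized) and `scores` (numeric vector of step scores).
#'
#' @examples
#' st <- score_steps("GCGC")
#' st$scores            # 7 7 7
#' sum(score_steps("GCGCGTGACTATGCGTG")$scores)  # 45.5
#'
#' @seealso [max_scoring_subarray()], [find_candidate_regions()]
#' @export
score_steps <- function(record, params = scoring_params()) {
  stopifnot(inherits(params, "zdna_params"))
  rec <- as_sequence_record(record)
  s <- rec$sequence
  n <- nchar(s)
  if (n < 2L) {
    return(structure(list(record_id = rec$record_id, sequence = s,
                          scores = numeric(0)),
                     class = "zdna_steps"))
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  cls <- classify_step(chars[-n], chars[-1L])

  weights <- c(GC = params$gc_weight, GT = params$gt_weight,
               AC = params$ac_weight, AT = params$at_weight,
               MISMATCH = 0)
  scores <- unname(weights[cls])

  # position of each step within its run of equal classes
  runs <- rle(cls)
  k <- sequence(runs$lengths)

  is_at <- cls == "AT"
  if (any(is_at))
    scores[is_at] <- params$at_weight + at_run_adjustment(k[is_at], params)
  is_mm <- cls == "MISMATCH"
  if (any(is_mm))
    scores[is_mm] <- mismatch_penalty(k[is_mm], params)

  structure(list(record_id = rec$record_id, sequence = s, scores = scores),
            class = "zdna_steps")
}

#' @export
print.zdna_steps <- function(x, ...) {
  cat(sprintf("Step scores for '%s' (%d nt, %d steps), total %s\n",
              x$record_id, nchar(x$sequence), length(x$scores),
              format(sum(x$scores))))
  invisible(x)
}
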