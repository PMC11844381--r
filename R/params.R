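#' Scoring parameters for Z-DNA detection
#'
#' Bundles every tunable knob of the dinucleotide-transition scoring scheme.
#' The defaults are the recommended settings for Z-DNA searching: they are
#' anchored on the observation that a (GC)4 repeat (7 GC/CG steps) and a
#' (GT)25 repeat (49 GT/TG steps) are both near the minimum tract length for
#' Z-DNA formation, which fixes the GC step weight at 7 and places the
#' detection threshold at 50.
#'
#' @param threshold Minimum score for a region to be reported as a potential
#'   Z-DNA-forming sequence (inclusive comparison, `score >= threshold`).
#'   Default 50.  May be lowered, including to 0 or below.
#' @param gc_weight Weight for GC and CG steps.  Default 7.
#' @param gt_weight Weight for GT and TG steps.  Default 1.25.
#' @param ac_weight Weight for AC and CA steps.  Default 1.25.
#' @param at_weight Base weight for AT and TA steps.  Default 0.5.
#' @param consecutive_at_adjustments Numeric vector of adjustments *added* to
#'   `at_weight` for the 1st, 2nd, ... AT/TA step within a contiguous run of
#'   AT/TA steps; the last element applies to every later step in the run.
#'   Default `c(0.5, 0.5, 0.5, 0, 0, -5, -100)`: runs longer than about four
#'   AT/TA repeat units favour hairpin/cruciform structures over Z-DNA, so
#'   extension is made strongly unprofitable.
#' @param mismatch_penalty_start Penalty magnitude for the first
#'   non-alternating (purine-purine or pyrimidine-pyrimidine) step of a
#'   contiguous mismatch run; applied as a negative contribution.  Default 3.
#' @param mismatch_penalty_delta Escalation rate of the mismatch penalty for
#'   each subsequent step of the run.  Default 3.
#' @param mismatch_penalty_type `"linear"` (penalty `start + (k-1)*delta` for
#'   the k-th consecutive mismatch) or `"exponential"`
#'   (`start * delta^(k-1)`; requires `delta > 1`).  Default `"linear"`.
#'
#' @return An object of class `"zdna_params"`: a validated list with the
#'   fields above.
#'
#' @examples
#' p <- scoring_params()
#' p$gc_weight
#' scoring_params(threshold = 40, gt_weight = 1)
#'
#' @export
scoring_params <- function(threshold = 50,
                           gc_weight = 7,
                           gt_weight = 1.25,
                           ac_weight = 1.25,
                           at_weight = 0.5,
                           consecutive_at_adjustments = c(0.5, 0.5, 0.5, 0, 0, -5, -100),
                           mismatch_penalty_start = 3,
                           mismatch_penalty_delta = 3,
                           mismatch_penalty_type = c("linear", "exponential")) {
  mismatch_penalty_type <- match.arg(mismatch_penalty_type)

  num1 <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("`", name, "` must be a single finite number", call. = FALSE)
    as.numeric(x)
  }
  threshold <- num1(threshold, "threshold")
  gc_weight <- num1(gc_weight, "gc_weight")
  gt_weight <- num1(gt_weight, "gt_weight")
  ac_weight <- num1(ac_weight, "ac_weight")
  at_weight <- num1(at_weight, "at_weight")
  mismatch_penalty_start <- num1(mismatch_penalty_start, "mismatch_penalty_start")
  mismatch_penalty_delta <- num1(mismatch_penalty_delta, "mismatch_penalty_delta")

  if (!is.numeric(consecutive_at_adjustments) ||
      length(consecutive_at_adjustments) < 1L ||
      any(!is.finite(consecutive_at_adjustments)))
    stop("`consecutive_at_adjustments` must be a non-empty finite numeric vector",
         call. = FALSE)
  if (mismatch_penalty_start < 0)
    stop("`mismatch_penalty_start` must be >= 0", call. = FALSE)
  if (mismatch_penalty_delta < 0)
    stop("`mismatch_penalty_delta` must be >= 0", call. = FALSE)
  if (mismatch_penalty_type == "exponential" && mismatch_penalty_delta <= 1)
    stop("exponential mismatch penalties require `mismatch_penalty_delta` > 1",
         call. = FALSE)

  structure(
    list(threshold = threshold,
         gc_weight = gc_weight,
         gt_weight = gt_weight,
         ac_weight = ac_weight,
         at_weight = at_weight,
         consecutive_at_adjustments = as.numeric(consecutive_at_adjustments),
         mismatch_penalty_start = mismatch_penalty_start,
         mismatch_penalty_delta = mismatch_penalty_delta,
         mismatch_penalty_type = mismatch_penalty_type),
    class = "zdna_params"
  )
}

#' @export
print.zdna_params <- function(x, ...) {
  cat("Z-DNA scoring parameters\n")
  cat(sprintf("  threshold: %s\n", format(x$threshold)))
  cat(sprintf("  step weights: GC/CG %s, GT/TG %s, AC/CA %s, AT/TA %s\n",
              format(x$gc_weight), format(x$gt_weight),
              format(x$ac_weight), format(x$at_weight)))
  cat(sprintf("  consecutive-AT adjustments: %s\n",
              paste(format(x$consecutive_at_adjustments), collapse = ", ")))
  cat(sprintf("  mismatch penalty: start %s, delta %s, type %s\n",
              format(x$mismatch_penalty_start),
              format(x$mismatch_penalty_delta),
              x$mismatch_penalty_type))
  invisible(x)
}
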