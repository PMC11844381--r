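#' Maximum-scoring contiguous subarray (Kadane's algorithm)
#'
#' Finds the contiguous span of a step-score array with the largest sum, in
#' linear time.  Ties on the sum are broken by leftmost start, then by
#' longest span.  If the array is empty or its maximum subarray sum is not
#' positive, `NULL` is returned: an all-negative array contains no
#' candidate region.
#'
#' @param scores A `"zdna_steps"` object or a plain numeric vector.
#'
#' @return `NULL`, or a list with `step_start`, `step_end` (1-based indices
#'   into the score array, inclusive) and `score` (the subarray sum).
#'
#' @examples
#' max_scoring_subarray(c(1, -2, 3, 4, -1))   # steps 3..4, score 7
#' max_scoring_subarray(c(-1, -2, -3))        # NULL
#'
#' @export
max_scoring_subarray <- function(scores) {
  x <- if (inherits(scores, "zdna_steps")) scores$scores else as.numeric(scores)
  n <- length(x)
  if (n == 0L) return(NULL)

  best_sum <- 0
  best_start <- 0L
  best_end <- 0L
  found <- FALSE
  cur_sum <- 0
  cur_start <- 1L

  for (i in seq_len(n)) {
    if (cur_sum < 0) {          # extension can never help: restart here
      cur_sum <- 0
      cur_start <- i
    }
    cur_sum <- cur_sum + x[i]
    if (cur_sum > 0 &&
        (!found || cur_sum > best_sum ||
         (cur_sum == best_sum &&
          (cur_start < best_start ||
           (cur_start == best_start && i > best_end))))) {
      best_sum <- cur_sum
      best_start <- cur_start
      best_end <- i
      found <- TRUE
    }
  }
  if (!found) return(NULL)
  list(step_start = best_start, step_end = best_end, score = best_sum)
}

#' Convert a step span to nucleotide coordinates
#'
#' A step `i` (1-based index into the score array) covers nucleotides
#' `i - 1` and `i` in 0-based coordinates, so a step span `[step_start,
#' step_end]` covers nucleotides `[step_start - 1, step_end]`, both 0-based
#' and inclusive.  This is the coordinate convention used in all reported
#' hits and CSV output.
#'
#' @param step_start,step_end 1-based step indices, `step_start <= step_end`.
#'
#' @return Integer vector `c(start, end)`: 0-based inclusive nucleotide
#'   indices.
#'
#' @examples
#' steps_to_nucleotides(1, 16)   # c(0, 16): a 17-nt region
#' steps_to_nucleotides(6, 6)    # c(5, 6): one step spans two nucleotides
#'
#' @export
steps_to_nucleotides <- function(step_start, step_end) {
  if (!is.numeric(step_start) || !is.numeric(step_end) ||
      length(step_start) != 1L || length(step_end) != 1L ||
      step_start < 1 || step_end < step_start)
    stop("invalid step span: need 1 <= step_start <= step_end", call. = FALSE)
  c(start = as.integer(step_start) - 1L, end = as.integer(step_end))
}

# Split a step array into the disjoint segments delimited by the points
# where Kadane's running sum restarts (running sum < 0 before the step).
# Returns a list of c(start, end) 1-based index pairs.
segment_steps <- function(x) {
  n <- length(x)
  if (n == 0L) return(list())
  segs <- list()
  cur <- 0
  start <- 1L
  for (i in seq_len(n)) {
    if (cur < 0) {
      if (i - 1L >= start) segs[[length(segs) + 1L]] <- c(start, i - 1L)
      cur <- 0
      start <- i
    }
    cur <- cur + x[i]
  }
  segs[[length(segs) + 1L]] <- c(start, n)
  segs
}

empty_hits <- function() {
  data.frame(record_id = character(0), start = integer(0), end = integer(0),
             score = numeric(0), subsequence = character(0),
             above_threshold = logical(0), stringsAsFactors = FALSE)
}

#' Find candidate Z-DNA regions in a scored sequence
#'
#' Partitions the step-score array into disjoint positive-sum segments
#' (splitting wherever the running maximum-subarray sum restarts), keeps
#' each segment's maximal-scoring subarray, and returns every region whose
#' score is at least `params$threshold`, sorted by start coordinate.  The
#' score of a region is the sum of the step scores it spans, taken from the
#' array computed once over the full sequence; boundary steps are not
#' re-contextualized.
#'
#' With `report_best = TRUE`, if no region reaches the threshold the single
#' best subarray of the whole array is returned anyway (flagged by
#' `above_threshold = FALSE`), so near-miss sequences can still be
#' inspected.
#'
#' @param steps A `"zdna_steps"` object from [score_steps()].
#' @param params A [scoring_params()] object (supplies the threshold).
#' @param report_best Return the single best region when nothing passes the
#'   threshold.  Default `FALSE`.
#'
#' @return A data frame with one row per hit and columns `record_id`,
#'   `start`, `end` (0-based inclusive nucleotide coordinates), `score`,
#'   `subsequence`, `above_threshold`.
#'
#' @examples
#' st <- score_steps("GCGCGTGCATATGCGTG")
#' find_candidate_regions(st)           # one hit, score 59.5
#' st2 <- score_steps("GCGCGTGACTATGCGTG")
#' find_candidate_regions(st2)          # none: 45.5 < 50
#' find_candidate_regions(st2, report_best = TRUE)
#'
#' @export
find_candidate_regions <- function(steps, params = scoring_params(),
                                   report_best = FALSE) {
  stopifnot(inherits(steps, "zdna_steps"), inherits(params, "zdna_params"))
  x <- steps$scores
  if (length(x) == 0L) return(empty_hits())

  spans <- list()
  for (seg in segment_steps(x)) {
    local <- max_scoring_subarray(x[seg[1L]:seg[2L]])
    if (is.null(local)) next
    spans[[length(spans) + 1L]] <- list(
      step_start = local$step_start + seg[1L] - 1L,
      step_end = local$step_end + seg[1L] - 1L,
      score = local$score
    )
  }

  passing <- Filter(function(sp) sp$score >= params$threshold, spans)
  if (length(passing) == 0L && report_best) {
    best <- max_scoring_subarray(x)
    passing <- if (is.null(best)) list() else list(best)
  }
  if (length(passing) == 0L) return(empty_hits())

  rows <- lapply(passing, function(sp) {
    nt <- steps_to_nucleotides(sp$step_start, sp$step_end)
    data.frame(record_id = steps$record_id,
               start = nt[["start"]], end = nt[["end"]],
               score = sp$score,
               subsequence = substr(steps$sequence, nt[["start"]] + 1L,
                                    nt[["end"]] + 1L),
               above_threshold = sp$score >= params$threshold,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
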