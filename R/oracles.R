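# Independent brute-force oracles.  Deliberately written as plain
# character-by-character / exhaustive-enumeration code sharing nothing with
# the vectorized implementations in scoring.R and detection.R, so that
# agreement between the two routes is meaningful evidence of correctness.

#' Total Z-DNA score by independent re-derivation
#'
#' A character-by-character state machine that walks the sequence once,
#' tracking the current AT-run and mismatch-run lengths explicitly, and
#' accumulates the total score.  It shares no code with [score_steps()] and
#' serves as the reference in dual-implementation tests:
#' `oracle_score(s, p)` must equal `sum(score_steps(s, p)$scores)`.
#'
#' @param sequence A DNA string (ACGT; uppercased internally).
#' @param params A [scoring_params()] object.
#'
#' @return The total score, a single number.
#'
#' @examples
#' oracle_score("GCGCGCGC")           # 49
#' oracle_score("GCGCGTGACTATGCGTG")  # 45.5
#'
#' @export
oracle_score <- function(sequence, params = scoring_params()) {
  s <- toupper(sequence)
  n <- nchar(s)
  total <- 0
  at_run <- 0L
  mm_run <- 0L
  adj <- params$consecutive_at_adjustments
  if (n < 2L) return(0)
  for (i in 1:(n - 1L)) {
    pair <- substr(s, i, i + 1L)
    if (pair == "GC" || pair == "CG") {
      total <- total + params$gc_weight
      at_run <- 0L; mm_run <- 0L
    } else if (pair == "GT" || pair == "TG") {
      total <- total + params$gt_weight
      at_run <- 0L; mm_run <- 0L
    } else if (pair == "AC" || pair == "CA") {
      total <- total + params$ac_weight
      at_run <- 0L; mm_run <- 0L
    } else if (pair == "AT" || pair == "TA") {
      at_run <- at_run + 1L
      mm_run <- 0L
      total <- total + params$at_weight +
        (if (at_run <= length(adj)) adj[at_run] else adj[length(adj)])
    } else {
      mm_run <- mm_run + 1L
      at_run <- 0L
      pen <- if (params$mismatch_penalty_type == "linear")
        params$mismatch_penalty_start +
          (mm_run - 1L) * params$mismatch_penalty_delta
      else
        params$mismatch_penalty_start *
          params$mismatch_penalty_delta^(mm_run - 1L)
      total <- total - pen
    }
  }
  total
}

#' Best subarray by exhaustive enumeration
#'
#' Enumerates every contiguous span of the score array (quadratic cost, so
#' intended for arrays up to a few hundred entries) and returns the best
#' positive-sum span under the same tie rule as [max_scoring_subarray()]:
#' largest sum, then leftmost start, then longest span.  Returns `NULL`
#' when no span has a positive sum.
#'
#' @param scores Numeric vector of step scores.
#'
#' @return `NULL`, or a list with `step_start`, `step_end` (1-based,
#'   inclusive) and `score`.
#'
#' @examples
#' oracle_best_subarray(c(7, 7, 7))          # steps 1..3, score 21
#' oracle_best_subarray(c(-1, -2))           # NULL
#'
#' @export
oracle_best_subarray <- function(scores) {
  x <- as.numeric(scores)
  n <- length(x)
  best <- NULL
  for (i in seq_len(n)) {
    s <- 0
    for (j in i:n) {
      s <- s + x[j]
      if (s > 0 &&
          (is.null(best) || s > best$score ||
           (s == best$score &&
            (i < best$step_start ||
             (i == best$step_start && j > best$step_end))))) {
        best <- list(step_start = i, step_end = j, score = s)
      }
    }
  }
  best
}
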