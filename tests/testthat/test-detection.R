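test_that("max_scoring_subarray handles basic and degenerate cases", {
  expect_equal(max_scoring_subarray(c(1, -2, 3, 4, -1)),
               list(step_start = 3L, step_end = 4L, score = 7))
  expect_null(max_scoring_subarray(c(-1, -2, -3)))
  expect_null(max_scoring_subarray(numeric(0)))
  expect_null(max_scoring_subarray(c(0, 0)))  # non-positive maximum
  expect_equal(max_scoring_subarray(c(7, 7, 7)),
               list(step_start = 1L, step_end = 3L, score = 21))
})

test_that("max_scoring_subarray ties break leftmost-start then longest-span", {
  # equal best sums at two starts: leftmost wins
  expect_equal(max_scoring_subarray(c(2, -5, 2))[c("step_start", "step_end")],
               list(step_start = 1L, step_end = 1L))
  # zero-sum bridge: same start, longer span preferred
  expect_equal(max_scoring_subarray(c(5, -5, 5)),
               list(step_start = 1L, step_end = 3L, score = 5))
  expect_equal(max_scoring_subarray(c(-1, 3, -3, 3)),
               list(step_start = 2L, step_end = 4L, score = 3))
})

test_that("the 26-nt model sequence yields the documented best subarray", {
  st <- score_steps(seq_model)
  best <- max_scoring_subarray(st)
  expect_equal(best$score, 63.75)
  nt <- steps_to_nucleotides(best$step_start, best$step_end)
  expect_equal(unname(nt), c(1L, 24L))
  expect_equal(substr(seq_model, nt[["start"]] + 1L, nt[["end"]] + 1L),
               "ACGCGGGGCGCGTGCATATGCGTG")
  # the interior G-run escalates -3, -6, -9 (required for the 63.75 total);
  # the flanking G->A and trailing G->G steps each restart at -3
  expect_equal(sort(st$scores[st$scores < 0]), c(-9, -6, -3, -3, -3))
})

test_that("steps_to_nucleotides bridges step and nucleotide coordinates", {
  expect_equal(unname(steps_to_nucleotides(1, 16)), c(0L, 16L))
  expect_equal(unname(steps_to_nucleotides(2, 24)), c(1L, 24L))
  expect_equal(unname(steps_to_nucleotides(6, 6)), c(5L, 6L))
  expect_error(steps_to_nucleotides(5, 3), "step span")
  expect_error(steps_to_nucleotides(0, 3), "step span")
})

test_that("find_candidate_regions applies the threshold inclusively", {
  p <- scoring_params()
  hits <- find_candidate_regions(score_steps(seq_mutant), p)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 0L)
  expect_equal(hits$end, 16L)
  expect_equal(hits$score, 59.5)
  expect_equal(hits$subsequence, seq_mutant)
  expect_true(hits$above_threshold)

  # 45.5 < 50: nothing reported by default
  expect_equal(nrow(find_candidate_regions(score_steps(seq_native), p)), 0L)

  # inclusive comparison: a threshold of exactly the score still matches
  p455 <- scoring_params(threshold = 45.5)
  expect_equal(nrow(find_candidate_regions(score_steps(seq_native), p455)), 1L)
})

test_that("report_best returns the single best region below threshold", {
  p <- scoring_params()
  hits <- find_candidate_regions(score_steps(seq_native), p,
                                 report_best = TRUE)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$score, 45.5)
  expect_equal(c(hits$start, hits$end), c(0L, 16L))
  expect_false(hits$above_threshold)

  # an all-negative array stays empty even with report_best
  hits2 <- find_candidate_regions(score_steps("NNNNNNNN"), p,
                                  report_best = TRUE)
  expect_equal(nrow(hits2), 0L)
})

test_that("widely separated repeat blocks are reported as disjoint hits", {
  # Two (GC)5 blocks separated by 30 A's.  The escalating penalties of the
  # A run force a split into two regions.  Oracle-verified expectation: the
  # leading block picks up its trailing C->A step (AC-class, +1.25) and
  # scores 64.25 over nt 0..10; the trailing block, with no right flank,
  # scores exactly 9 x 7 = 63 over nt 40..49.
  s <- paste0(strrep("GC", 5), strrep("A", 30), strrep("GC", 5))
  st <- score_steps(s)
  hits <- find_candidate_regions(st, scoring_params())
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$score, c(64.25, 63))
  expect_equal(hits$start, c(0L, 40L))
  expect_equal(hits$end, c(10L, 49L))
  expect_equal(hits$subsequence, c("GCGCGCGCGCA", "GCGCGCGCGC"))

  # each reported span's score is its subarray sum in the precomputed array
  for (i in seq_len(nrow(hits)))
    expect_equal(hits$score[i],
                 sum(st$scores[(hits$start[i] + 1L):hits$end[i]]))
})

test_that("AT-repeat best subarray plateaus at 4.0 regardless of length", {
  # the -5/-100 tail of the adjustment array makes extension beyond five
  # AT/TA steps unprofitable: hairpin-prone runs never outscore threshold
  for (n in 3:30) {
    st <- score_steps(strrep("AT", n))
    expect_equal(max_scoring_subarray(st)$score, 4.0)
  }
})

test_that("raising the threshold never increases the number of hits", {
  withr::with_seed(424, {
    for (rep in 1:20) {
      s <- random_seq(sample(50:300, 1))
      st0 <- score_steps(s)
      counts <- vapply(c(-10, 0, 5, 20, 50, 80), function(thr) {
        nrow(find_candidate_regions(st0, scoring_params(threshold = thr)))
      }, integer(1))
      expect_true(all(diff(counts) <= 0))
    }
  })
})
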