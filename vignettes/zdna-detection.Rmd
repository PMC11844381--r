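---
title: "Scoring and detecting potential Z-DNA-forming sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and detecting potential Z-DNA-forming sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zdnascan)
```

## The model

Z-DNA is a left-handed double-helical conformation with a zigzag
sugar-phosphate backbone.  Its formation requires the bases to alternate
between *syn* and *anti* glycosidic conformations along each strand, which
is energetically feasible mainly in tracts of alternating purines and
pyrimidines under negative supercoiling.  `zdnascan` turns this structural
requirement into a simple additive score over dinucleotide *steps* (ordered
adjacent base pairs):

* **GC-class** steps (GC, CG) are the strongest Z-formers and score
  `gc_weight = 7`.
* **GT-class** (GT, TG) and **AC-class** (AC, CA) steps score
  `gt_weight = ac_weight = 1.25`.
* **AT-class** steps (AT, TA) score `at_weight = 0.5` *plus* a
  position-dependent adjustment within each contiguous AT/TA run (below).
* Every other step — purine followed by purine, pyrimidine followed by
  pyrimidine, or any step touching a non-ACGT character — is a
  **mismatch**: it breaks the syn/anti alternation and is penalized with
  escalating severity.

A region's score is the sum of the step scores it spans, and a sequence's
candidate regions are the maximal-scoring contiguous subarrays of its step
array.  With the default threshold of 50, a region is reported when its
score is at least 50.

The default weights are anchored on minimum motif lengths: a (GC)~4~ repeat
contributes 7 GC-class steps and a (GT)~25~ repeat 49 GT-class steps, and
both tracts are near the minimum length for Z-DNA formation, which fixes
the 7 / 1.25 weights and places the threshold at 50 (both calibration
motifs then sit just below it, at 49 and 61.25 respectively for pure
repeats — the GC motif needs one more repeat unit to cross the line).

### Consecutive AT/TA runs

AT-rich alternating tracts can form Z-DNA, but runs longer than about four
AT/TA repeat units preferentially extrude as hairpin or cruciform
structures instead.  The k-th AT-class step of a contiguous run therefore
receives `at_weight` plus the k-th element of the adjustment array
`c(0.5, 0.5, 0.5, 0, 0, -5, -100)`, with the last element applied to every
later step.  With the defaults, the best subarray of a pure (AT)~n~ repeat
is exactly `3 × 1.0 + 2 × 0.5 = 4.0` for every `n ≥ 3`: extension past
five steps is never profitable, which is the plateau property the test
suite asserts.

### Mismatch runs

The k-th step of a contiguous mismatch run contributes
`-(start + (k-1) · delta)` in linear mode (defaults: start 3, delta 3, so
-3, -6, -9, ...).  Both the AT-run counter and the mismatch-run counter
reset whenever a step of any other class occurs; two single mismatches
separated by a scoring step are each penalized -3, not -3 and -6.

The exponential mode is named but not defined by a formula in the
literature that motivated this scheme; this package defines it as
`-(start · delta^(k-1))` and requires `delta > 1` in that mode.  This was
a genuinely open design point: the chosen form reduces to the starting
penalty at `k = 1`, reuses the same two parameters as the linear mode,
and is strictly escalating.  No worked example constrains the choice.

### Worked examples

Three experimentally characterized sequences from the mouse
metallothionein-I promoter literature serve as the package's reference
calculations:

```{r examples}
p <- scoring_params()
for (s in c("GCGCGTGACTATGCGTG",    # native: no Z-DNA without strong stress
            "GCGCGTGCATATGCGTG",    # point-reversed mutant: forms Z-DNA
            "GACGCGGGGCGCGTGCATATGCGTGG")) {  # model: forms Z-DNA readily
  best <- max_scoring_subarray(score_steps(s, p))
  nt <- steps_to_nucleotides(best$step_start, best$step_end)
  cat(sprintf("%-26s best %6.2f at %d..%d\n", s, best$score, nt[1], nt[2]))
}
```

The native sequence scores 45.5 — just below the 50 cutoff — while the
mutant (59.5) and the model sequence (63.75, over nucleotides 1..24 of its
26-nt input) are reported, matching the published structural evidence
(two-dimensional gel and chemical-probing assays).  Reproducing 59.5
requires the AT adjustment to be *added* to `at_weight` (each of the
mutant's three AT-class steps contributes 1.0), and reproducing 63.75
requires the linear penalty escalation -3, -6, -9 across the mutant's
interior GGGG tract; both readings are locked in by tests.

## Detection semantics

* The step array is computed **once** over the full sequence; a region's
  score is a pure subarray sum and boundary steps are not
  re-contextualized when a region is excised.
* The maximal subarray is found in linear time (Kadane's algorithm).
  Ties on the sum are broken by leftmost start, then longest span — a
  deterministic rule that favours reporting the fullest motif.
* Multiple regions per record: the step array is partitioned into the
  disjoint segments delimited by the points where the running subarray sum
  restarts, and each segment contributes its own maximal subarray.  All
  regions with `score >= threshold` are reported (inclusive comparison, so
  a user-set threshold equal to a motif's score still matches).
* `report_best = TRUE` returns the single best region of a record even
  when nothing reaches the threshold, so near-misses such as the native
  promoter sequence (45.5) can be inspected.
* Coordinates are reported 0-based with inclusive ends, the convention of
  the reference calculations; a 17-nt sequence spans 0..16.  Internally,
  step index `i` (1-based) covers nucleotides `i-1..i`.

## What the synthetic generator emulates

`motif_spec()` / `generate_repeat()` produce the repeat tracts the scoring
scheme was calibrated on — (GC)~n~, (GT)~n~, (AT)~n~ — optionally embedded
in flanks that are either uniform-random ACGT (seeded, reproducible) or
homopolymer A ("Z-poor", for clean planted-motif recovery).  They emulate
motif composition and placement only: no mutational processes, base
modifications, supercoiling, ionic conditions, or chromatin context.  A
green planted-motif test therefore establishes that the scanner recovers
an isolated alternating tract from a non-alternating background, not that
the score predicts formation energetics in vivo.

One boundary effect is worth stating precisely, because it caught a
reference expectation being wrong: a GC-repeat block whose right neighbour
is an A still ends in a C→A step, which is AC-class and scores +1.25.
The maximal subarray over an A-flanked (GC)~5~ block is therefore the
block *plus one flank base*, score 64.25, not 63 — verified by the
exhaustive-enumeration oracle.  The corresponding acceptance expectation
is left failing rather than silently adjusted; a block at the end of its
sequence (no right flank) scores exactly 63.

## Numerical choices and degenerate inputs

* All default weights and adjustments are dyadic rationals (multiples of
  0.25), so sums are exact in binary floating point and tie comparisons in
  the subarray search are meaningful.  Property tests generate arrays of
  multiples of 0.25 for the same reason.
* Sequences shorter than two bases have an empty step array, score 0, and
  produce no hits; they are still logged.
* Input is uppercased and U is mapped to T.  IUPAC ambiguity codes are
  accepted silently and scored as mismatches; anything else warns but is
  retained — a long N run self-extinguishes through escalating penalties,
  keeping the score array aligned to the sequence.
* CSV output prints scores in minimal decimal form (`45.5`, `63.75`, `63`)
  and is byte-identical regardless of worker count: records are scored in
  parallel, but hits are gathered and ordered (input order, then start)
  before writing.

## Known limitations

* The scoring is purely additive over dinucleotide steps: no B-Z junction
  energetics, no statistical-mechanics treatment of supercoiling, and no
  condition-dependent motifs (CCG/CGG repeats, methylated cytosines, ionic
  effects).
* The GT/TG weight follows the recommended parameter table (1.25) even
  though accompanying prose elsewhere quotes "1"; only 1.25 reproduces the
  worked examples.
* Overlapping hits are not enumerated; each positive-sum segment yields
  exactly one region.
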