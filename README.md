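# zdnascan

Detection of potential Z-DNA-forming sequences in DNA by dinucleotide
transition scoring.

Z-DNA is a left-handed double-helical DNA conformation with a zigzag
backbone, adopted by alternating purine-pyrimidine tracts under negative
supercoiling and implicated in transcription regulation, recombination and
genome instability.  `zdnascan` is for anyone who needs to locate candidate
Z-DNA-forming regions in sequences at scale — from single promoter elements
to whole-genome FASTA — with a transparent, parameter-level view of why a
region scores the way it does.

## The scoring model

Every dinucleotide step (ordered adjacent base pair) of a sequence receives
a score:

| step class | members | default score |
|---|---|---|
| GC | GC, CG | 7 |
| GT | GT, TG | 1.25 |
| AC | AC, CA | 1.25 |
| AT | AT, TA | 0.5 + adjustment for the k-th step of an AT/TA run: `0.5, 0.5, 0.5, 0, 0, -5, -100` (last value repeats) |
| mismatch | purine→purine, pyrimidine→pyrimidine, non-ACGT | −(3 + 3(k−1)) for the k-th step of a mismatch run (linear mode) |

Both run counters reset on any step of another class.  A candidate region
is a maximal-scoring contiguous subarray of the step array (Kadane's
algorithm; ties broken leftmost-start, then longest-span), reported when
its score ≥ threshold (default 50).  Coordinates are 0-based with
inclusive ends.  The weights are anchored on minimum Z-forming tract
lengths: (GC)₄ has 7 GC steps, (GT)₂₅ has 49 GT steps.  Long AT/TA runs
are penalized because beyond ~4 repeat units they favour hairpin/cruciform
structures over Z-DNA.

## Worked example

```r
library(zdnascan)
p <- scoring_params()                       # all defaults
st <- score_steps("GCGCGTGCATATGCGTG", p)   # 16 step scores
find_candidate_regions(st, p)
#>   record_id start end score       subsequence above_threshold
#> 1       seq     0  16  59.5 GCGCGTGCATATGCGTG            TRUE
```

This 17-nt promoter mutant scores 59.5 ≥ 50, so its full span (nucleotides
0–16, 0-based inclusive) is reported as a potential Z-DNA-forming region.
The corresponding native sequence `GCGCGTGACTATGCGTG` — identical base
content, but with the central alternation interrupted — totals 45.5, just
below the cutoff, matching the experimental observation that only the
mutant forms Z-DNA without strong torsional stress:

```r
find_candidate_regions(score_steps("GCGCGTGACTATGCGTG", p), p,
                       report_best = TRUE)
#>   record_id start end score       subsequence above_threshold
#> 1       seq     0  16  45.5 GCGCGTGACTATGCGTG           FALSE
```

End-to-end, FASTA in / CSV out (parallel, byte-deterministic):

```r
run_scan("input.fa", output = "hits.csv", params = p, workers = 4,
         plots = TRUE)
```

or from a shell:

```sh
Rscript -e 'quit(status = zdnascan::zdna_main())' \
  --fasta input.fa --output hits.csv --threshold 50 --n-jobs 4
```

The CSV has columns `Sequence_name,Start,End,Z-DNA_Score,Sequence` after a
comment line stating the coordinate convention.  Exit codes: 0 success,
1 usage/config error, 2 input parse failure, 3 partial failure.

## Package tour

* `scoring_params()` — all tunable weights/penalties, validated.
* `classify_step()`, `score_steps()` — per-step classification and scoring.
* `max_scoring_subarray()`, `find_candidate_regions()`,
  `steps_to_nucleotides()` — region detection and coordinates.
* `read_fasta()`, `run_scan()`, `write_hits_csv()`, `plot_summary()`,
  `zdna_main()` — the FASTA→CSV pipeline and CLI.
* `motif_spec()`, `generate_repeat()`, `write_motif_fasta()` — seeded
  synthetic repeat fixtures; `oracle_score()`, `oracle_best_subarray()` —
  independent brute-force oracles used by the property tests.

See `vignettes/zdna-detection.Rmd` for the model, design decisions and
limitations.
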