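Package: zdnascan
Title: Detection of Potential Z-DNA-Forming Sequences by Dinucleotide
    Transition Scoring
Version: 0.1.0
Authors@R:
    person("zdnascan", "developers", email = "zdnascan@example.org",
           role = c("aut", "cre"))
Description: Scores DNA sequences for their potential to adopt the
    left-handed Z-DNA conformation.  Every dinucleotide step of a sequence
    receives an experimentally motivated weight (alternating
    purine-pyrimidine steps score positively, with GC/CG steps weighted
    most heavily) or penalty (non-alternating steps receive escalating
    penalties; long AT/TA runs are down-weighted because they favour
    hairpin formation over Z-DNA).  Maximal-scoring contiguous
    subsequences are extracted with a linear-time maximum-subarray search
    and reported above a configurable threshold, from FASTA input to CSV
    output, with optional summary plots and a command-line interface.
    Includes deterministic sequence generators and independent brute-force
    oracles for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    parallel,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
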