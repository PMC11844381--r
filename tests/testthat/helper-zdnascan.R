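# Shared helpers for the test suite.  Random inputs are always generated
# under an explicit seed so failures are reproducible.

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# step-score-like random arrays: multiples of 0.25 so sums are exact in
# binary floating point and tie comparisons are meaningful
random_score_array <- function(n) {
  sample(seq(-5, 7, by = 0.25), n, replace = TRUE)
}

reverse_string <- function(s) {
  paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
}

revcomp_string <- function(s) {
  reverse_string(chartr("ACGT", "TGCA", s))
}

# the three experimentally characterized promoter-derived sequences used
# as worked examples throughout the suite
seq_native <- "GCGCGTGACTATGCGTG"
seq_mutant <- "GCGCGTGCATATGCGTG"
seq_model  <- "GACGCGGGGCGCGTGCATATGCGTGG"

write_temp_fasta <- function(lines, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".fa.gz" else ".fa")
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  writeLines(lines, con)
  close(con)
  path
}
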