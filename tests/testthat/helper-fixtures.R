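# Shared fixtures and independent oracles. Oracles are deliberately written
# in the most naive way possible (character loops, exhaustive scans) so they
# stay independent of the package's vectorized implementations.

## naive Hamming distance between two equal-length strings
oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  sum(ca != cb)
}

## brute-force all-pairs minimum distance, O(k^2 L)
oracle_min_dist <- function(codes) {
  k <- length(codes)
  if (k < 2) return(nchar(codes[1]))
  best <- nchar(codes[1])
  for (i in 1:(k - 1)) for (j in (i + 1):k)
    best <- min(best, oracle_hamming(codes[i], codes[j]))
  best
}

## exhaustive poly(A)-suffix scoring: longest suffix >= min_run starting
## with A and holding at most max_mismatch non-A bases
oracle_polya_keep <- function(s, min_run = 6, max_mismatch = 1) {
  L <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  best <- 0
  for (n in seq_len(L)) {
    if (n < min_run) next
    suf <- ch[(L - n + 1):L]
    if (suf[1] == "A" && sum(suf != "A") <= max_mismatch) best <- n
  }
  L - best
}

fixture_sets <- function(k = 4) {
  a <- generate_barcode_set(k, seed = 11, name = "A")
  b <- generate_barcode_set(k, seed = 12, avoid = a, name = "B")
  list(a = a, b = b)
}

fixture_sheet <- function(sets, n = length(sets$a)) {
  sample_sheet(seq_len(n), seq_len(n), sprintf("S%02d", seq_len(n)),
               setA = sets$a, setB = sets$b)
}

## small error-free library shared by round-trip tests
fixture_library <- function(n_genes = 6, reads_per_sample = 300, eps = 0,
                            seed = 21, delta = 0, unique_umis = FALSE,
                            sets = fixture_sets(), sheet = NULL,
                            tx = NULL, ...) {
  if (is.null(sheet)) sheet <- fixture_sheet(sets)
  if (is.null(tx)) tx <- make_transcriptome(n_genes, seed = seed + 1)
  cfg <- sim_config(reads_per_sample = reads_per_sample,
                    substitution_error_rate = eps,
                    degradation_bias = delta,
                    unique_umis_per_gene = unique_umis,
                    seed = seed, ...)
  lib <- simulate_library(tx, sheet, sets$a, sets$b, cfg)
  list(sets = sets, sheet = sheet, tx = tx, cfg = cfg, lib = lib)
}

## truth table -> 1-based inclusive fragment intervals for coverage
truth_intervals <- function(truth) {
  truth$frag_lo <- truth$frag_start + 1L
  truth$frag_hi <- truth$frag_end
  truth
}

## expected mate-2 5' mapping coordinate from ground truth
truth_pos5 <- function(truth) {
  ifelse(truth$a_end == "left", truth$frag_end, truth$frag_start + 1L)
}
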