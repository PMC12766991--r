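# Simulator: templates, fragment statistics, error model, ground truth IO.

test_that("transcriptome generation is deterministic and species-aware", {
  tx1 <- make_transcriptome(20, seed = 5)
  tx2 <- make_transcriptome(20, seed = 5)
  p1 <- withr::local_tempfile(fileext = ".fa")
  p2 <- withr::local_tempfile(fileext = ".fa")
  write_transcriptome_fasta(tx1, p1)
  write_transcriptome_fasta(tx2, p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical FASTA
  expect_true(all(grepl("A{30}$", tx1$sequence)))  # poly(A) tail
  expect_true(all(tx1$body_length >= 1000))
  r <- read_transcriptome_fasta(p1)
  expect_identical(r$sequence, tx1$sequence)
  expect_identical(r$gene_id, tx1$gene_id)

  mix <- make_transcriptome(10, species_mix = c(6, 4), seed = 6)
  expect_identical(sum(startsWith(mix$gene_id, "HUMAN_")), 6L)
  expect_identical(sum(startsWith(mix$gene_id, "MOUSE_")), 4L)
})

test_that("error-free reads carry the exact truth tags at the stated positions", {
  fx <- fixture_library(reads_per_sample = 150, eps = 0)
  tags <- extract_tags(fx$lib$reads)
  truth <- fx$lib$truth
  expect_false(any(tags$fail_structure))
  expect_identical(tags$a_raw, fx$sets$a$barcodes[truth$a_index])
  expect_identical(tags$b_raw, fx$sets$b$barcodes[truth$b_index])
  expect_identical(tags$umi, truth$umi)
})

test_that("fragment lengths follow the truncated-normal model", {
  fx <- fixture_library(n_genes = 4, reads_per_sample = 1500, eps = 0,
                        seed = 31)
  len <- fx$lib$truth$frag_end - fx$lib$truth$frag_start
  expect_true(all(len >= 150 & len <= 800))
  se <- sd(len) / sqrt(length(len))
  expect_lt(abs(mean(len) - 400), 3 * se)
})

test_that("fragment starts are uniform along the template when delta = 0", {
  # one 2000-nt transcript, fixed fragment length so the valid start
  # window is the same for every fragment
  sets <- fixture_sets(1)
  sheet <- fixture_sheet(sets, 1)
  tx <- make_transcriptome(1, length_bounds = c(2000, 2000), seed = 41)
  cfg <- sim_config(reads_per_sample = 50000, substitution_error_rate = 0,
                    fragment_length_sd = 0, seed = 42)
  lib <- simulate_library(tx, sheet, sets$a, sets$b, cfg)
  W <- tx$length[1] - 400  # all starts lie in 0..W
  s <- lib$truth$frag_start
  expect_true(all(s >= 0 & s <= W))
  bins <- cut(s, breaks = seq(0, W + 1, length.out = 21),
              include.lowest = TRUE, right = FALSE)
  p <- stats::chisq.test(table(bins))$p.value
  expect_gt(p, 0.01)
})

test_that("the 3'-degradation tilt shifts fragment starts toward the 3' end", {
  sets <- fixture_sets(1)
  sheet <- fixture_sheet(sets, 1)
  tx <- make_transcriptome(1, length_bounds = c(2000, 2000), seed = 41)
  rel <- sapply(c(0, 2), function(delta) {
    cfg <- sim_config(reads_per_sample = 4000, substitution_error_rate = 0,
                      degradation_bias = delta, seed = 43)
    lib <- simulate_library(tx, sheet, sets$a, sets$b, cfg)
    mean(lib$truth$frag_start)
  })
  expect_gt(rel[2], rel[1] * 1.2)
})

test_that("observed substitution rate matches the configured rate", {
  # all content draws precede error injection, so an error-free twin with
  # the same seed reconstructs the pristine reads
  eps <- 0.01
  noisy <- fixture_library(n_genes = 4, reads_per_sample = 500, eps = eps,
                           seed = 51)
  clean <- fixture_library(n_genes = 4, reads_per_sample = 500, eps = 0,
                           seed = 51)
  mm <- function(x, y) {
    a <- strsplit(x, ""); b <- strsplit(y, "")
    sum(mapply(function(u, v) sum(u != v), a, b))
  }
  n_mm <- mm(noisy$lib$reads$r1_seq, clean$lib$reads$r1_seq) +
    mm(noisy$lib$reads$r2_seq, clean$lib$reads$r2_seq)
  n_bases <- sum(nchar(noisy$lib$reads$r1_seq)) +
    sum(nchar(noisy$lib$reads$r2_seq))
  se <- sqrt(eps * (1 - eps) / n_bases)
  expect_lt(abs(n_mm / n_bases - eps), 3 * se)
  # and the error positions are flagged at low quality
  expect_identical(sum(strsplit(paste(noisy$lib$reads$r1_qual, collapse = ""),
                                "")[[1]] == "/"),
                   mm(noisy$lib$reads$r1_seq, clean$lib$reads$r1_seq))
})

test_that("ground-truth tables round trip losslessly through TSV", {
  fx <- fixture_library(reads_per_sample = 250, eps = 0.002, seed = 61)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_truth(fx$lib$truth, p)
  r <- read_truth(p)
  expect_equal(r, fx$lib$truth, ignore_attr = TRUE)

  # empty table -> header-only file
  p0 <- withr::local_tempfile(fileext = ".tsv")
  write_truth(fx$lib$truth[0, ], p0)
  expect_identical(length(readLines(p0)), 1L)
  expect_identical(nrow(read_truth(p0)), 0L)

  # truncated row -> parse error naming the line
  bad <- readLines(p)
  bad[5] <- sub("\t[^\t]*$", "", bad[5])
  pb <- withr::local_tempfile(fileext = ".tsv")
  writeLines(bad, pb)
  expect_error(read_truth(pb), "line 5")
})

test_that("FASTQ export/import round trips and enforces mate pairing", {
  fx <- fixture_library(reads_per_sample = 40, eps = 0.002, seed = 71)
  r1 <- withr::local_tempfile(fileext = "_R1.fastq")
  r2 <- withr::local_tempfile(fileext = "_R2.fastq")
  write_fastq_pairs(fx$lib$reads, r1, r2)
  back <- read_fastq_pairs(r1, r2)
  expect_identical(back, fx$lib$reads)
  # mismatched mate files -> hard error
  r1b <- withr::local_tempfile(fileext = "_R1.fastq")
  r2b <- withr::local_tempfile(fileext = "_R2.fastq")
  write_fastq_pairs(fx$lib$reads[1:10, ], r1b, r2b)
  expect_error(read_fastq_pairs(r1, r2b), "mate")
})

test_that("configuration validation rejects impossible worlds", {
  expect_error(sim_config(substitution_error_rate = 0.3), "0.25")
  expect_error(sim_config(read_length = 30), "technical prefix")
  sets <- fixture_sets(1)
  tx <- make_transcriptome(1, length_bounds = c(1000, 1000), seed = 1)
  cfg <- sim_config(fragment_length_bounds = c(150, 1200))
  expect_error(simulate_library(tx, fixture_sheet(sets, 1),
                                sets$a, sets$b, cfg),
               "shortest template")
})
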