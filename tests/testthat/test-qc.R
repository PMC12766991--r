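# Gene-body coverage, bias index, barnyard calls, aggregate report.

test_that("interval projection spreads fragment mass over percentile bins", {
  tx <- data.frame(gene_id = "g1", transcript_id = "t1", species = "SYN",
                   biotype = "protein_coding", body_length = 1000L,
                   length = 1000L, sequence = strrep("A", 1000),
                   stringsAsFactors = FALSE)
  # one fragment covering exactly bins 1-10 (bases 1-100 of 1000)
  fr <- data.frame(transcript_id = "t1", frag_lo = 1L, frag_hi = 100L)
  p <- gene_body_coverage(fr, tx)
  expect_equal(p$profile[1:10], rep(0.1, 10))
  expect_equal(sum(p$profile[11:100]), 0)
  expect_error(gene_body_coverage(fr, tx, min_len = 2000), "eligible")
})

test_that("coverage profiles always normalize to unit mass", {
  set.seed(301)
  tx <- make_transcriptome(8, seed = 301)
  for (i in 1:5) {
    n <- 200
    tid <- sample(tx$transcript_id, n, TRUE)
    L <- tx$length[match(tid, tx$transcript_id)]
    lo <- pmax(1L, as.integer(runif(n) * (L - 120)))
    fr <- data.frame(transcript_id = tid, frag_lo = lo,
                     frag_hi = lo + sample(30:119, n, TRUE))
    expect_equal(sum(gene_body_coverage(fr, tx)$profile), 1,
                 tolerance = 1e-9)
  }
})

test_that("coverage is flat along the body interior when delta = 0", {
  fx <- fixture_library(n_genes = 6, reads_per_sample = 2500, eps = 0,
                        seed = 302)
  p <- gene_body_coverage(truth_intervals(fx$lib$truth), fx$tx)
  se <- sqrt(0.01 * 0.99 / p$n_fragments)
  # plateau bins (outside one fragment-length of either terminus)
  plateau <- p$profile[25:76]
  expect_lt(max(abs(plateau - mean(plateau))), 4 * se)
  # terminal bins are depleted: fragments need both adapter ends inside
  # the template, so coverage ramps over the first/last fragment length
  expect_lt(p$profile[1], 0.5 * mean(plateau))
  expect_lt(p$profile[100], 0.5 * mean(plateau))
})

test_that("the 3'/5' bias index is exact on constructed profiles", {
  flat <- structure(list(profile = rep(0.01, 100), n_bins = 100L,
                         n_transcripts = 1L, n_fragments = 1L),
                    class = "coverage_profile")
  expect_equal(coverage_bias_index(flat), 1)
  spike <- rep(0, 100); spike[100] <- 1
  expect_identical(coverage_bias_index(spike), Inf)
  ramp <- (1:100) / sum(1:100)  # closed form: mean(81:100)/mean(1:20)
  expect_equal(coverage_bias_index(ramp), mean(81:100) / mean(1:20))
})

test_that("the bias index increases strictly with the degradation tilt", {
  for (seed in c(311, 312, 313)) {
    idx <- sapply(c(0, 1, 2), function(delta) {
      fx <- fixture_library(n_genes = 4, reads_per_sample = 1200, eps = 0,
                            seed = seed, delta = delta)
      coverage_bias_index(
        gene_body_coverage(truth_intervals(fx$lib$truth), fx$tx))
    })
    expect_true(all(diff(idx) > 0),
                label = sprintf("seed %d: %s", seed,
                                paste(round(idx, 3), collapse = " < ")))
  }
})

test_that("barnyard calls follow the strict minor-fraction rule", {
  counts <- matrix(c(90, 10, 75, 25, 80, 20, 0, 0), nrow = 2,
                   dimnames = list(c("HUMAN_g1", "MOUSE_g1"),
                                   sprintf("S%d", 1:4)))
  calls <- barnyard_classify(counts)
  expect_identical(calls$call, c("HUMAN", "MIXED", "HUMAN", "UNDETERMINED"))
  expect_equal(calls$minor_fraction[1:3], c(0.10, 0.25, 0.20))
  # boundary: exactly 20% is NOT mixed ("more than 20%")
  expect_identical(calls$call[3], "HUMAN")
  # permuting the species labels swaps calls but preserves the MIXED set
  swapped <- barnyard_classify(counts, species = c("MOUSE", "HUMAN"))
  expect_identical(swapped$call[1], "MOUSE")
  expect_identical(swapped$call == "MIXED", calls$call == "MIXED")
})

test_that("simulated barnyard samples classify by their species", {
  sets <- fixture_sets(4)
  sheet <- fixture_sheet(sets, 4)
  tx <- make_transcriptome(10, species_mix = c(5, 5), seed = 321)
  species <- c(S01 = "HUMAN", S02 = "HUMAN", S03 = "MOUSE")  # S04 mixed
  cfg <- sim_config(reads_per_sample = 300, substitution_error_rate = 0,
                    seed = 322)
  lib <- simulate_library(tx, sheet, sets$a, sets$b, cfg,
                          sample_species = species)
  dm <- demultiplex(lib$reads, sets$a, sets$b, sheet)
  idx <- build_kmer_index(tx)
  asg <- quantify_records(dm$records, idx)
  em <- count_umis(asg[asg$status == "MAPPED", ], genes = tx$gene_id,
                   samples = sheet$entries$sample_id)
  calls <- barnyard_classify(em)
  expect_identical(calls$call[1:3], c("HUMAN", "HUMAN", "MOUSE"))
  expect_identical(calls$call[4], "MIXED")  # draws from both species
})

test_that("the QC report aggregates its constituents faithfully", {
  fx <- fixture_library(reads_per_sample = 150, eps = 0, seed = 331)
  dm <- demultiplex(fx$lib$reads, fx$sets$a, fx$sets$b, fx$sheet)
  idx <- build_kmer_index(fx$tx)
  asg <- quantify_records(dm$records, idx)
  em <- count_umis(asg[asg$status == "MAPPED", ])
  prof <- gene_body_coverage(asg[asg$status == "MAPPED", ], fx$tx)
  rep <- qc_report(dm$stats, em, prof)
  expect_identical(sort(names(rep)),
                   sort(c("demux", "expression", "coverage", "barnyard")))
  expect_identical(rep$demux$assigned_pairs, dm$stats$assigned_pairs)
  expect_identical(rep$expression$total_umis, as.integer(sum(em$counts)))
  expect_equal(rep$coverage$bias_index, coverage_bias_index(prof))
  expect_error(qc_report(NULL, em, prof), "missing section")
  p <- withr::local_tempfile(fileext = ".json")
  write_qc_report(rep, p)
  back <- read_qc_report(p)
  expect_equal(back$demux$assigned_pairs, rep$demux$assigned_pairs)
  expect_equal(back$coverage$profile, prof$profile)
  file.remove(p); writeLines('{"demux": {}}', p)
  expect_error(read_qc_report(p), "missing section")
})
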