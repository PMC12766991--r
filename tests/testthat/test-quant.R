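# k-mer index, transcript assignment, UMI counting, matrix IO.

mini_tx <- function(seqs, ids = sprintf("t%d", seq_along(seqs))) {
  data.frame(gene_id = sub("\\..*", "", ids), transcript_id = ids,
             species = "SYN", biotype = "protein_coding",
             body_length = nchar(seqs), length = nchar(seqs),
             sequence = seqs, stringsAsFactors = FALSE)
}

test_that("the k-mer index is complete and position-faithful", {
  set.seed(201)
  s <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  idx <- build_kmer_index(mini_tx(s), k = 21)
  expect_identical(sum(idx$strand == "+"), 80L)  # L - k + 1
  expect_identical(sum(idx$strand == "-"), 80L)
  # random spot-check against the sequence (and its reverse complement)
  rc <- revcomp(s)
  pick <- idx[sample(nrow(idx), 100), ]
  ref <- ifelse(pick$strand == "+", s, rc)
  expect_identical(substring(ref, pick$offset, pick$offset + 20), pick$kmer)
  expect_error(build_kmer_index(mini_tx(s), k = 200), "shortest")
  expect_error(build_kmer_index(mini_tx(c(s, s), ids = c("t1", "t1"))),
               "duplicate")
})

test_that("exact substrings map to their transcript and offset", {
  set.seed(202)
  seqs <- vapply(1:3, function(i)
    paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = ""),
    character(1))
  idx <- build_kmer_index(mini_tx(seqs))
  ins <- substring(seqs[2], 41, 140)  # 0-based offset 40
  got <- assign_transcripts(ins, idx, stride = 1)
  expect_identical(got$status, "MAPPED")
  expect_identical(got$transcript_id, "t2")
  expect_identical(got$strand, "+")
  expect_identical(got$start, 41L)
  expect_identical(got$pos5, 41L)
  # reverse-complement insert maps on the minus strand, same 5' base
  gotm <- assign_transcripts(revcomp(ins), idx, stride = 1)
  expect_identical(gotm$strand, "-")
  expect_identical(gotm$pos5, 140L)
  # an insert present in two identical transcripts is ambiguous
  idx2 <- build_kmer_index(mini_tx(c(seqs[1], seqs[1]),
                                   ids = c("t1", "t2")))
  expect_identical(assign_transcripts(substring(seqs[1], 1, 80),
                                      idx2)$status, "AMBIGUOUS")
  # too-short inserts are flagged
  expect_identical(assign_transcripts("ACGT", idx)$status, "TOO_SHORT")
})

test_that("error-free decoding maps every fragment to its true gene and end", {
  fx <- fixture_library(reads_per_sample = 300, eps = 0, seed = 203)
  dm <- demultiplex(fx$lib$reads, fx$sets$a, fx$sets$b, fx$sheet)
  idx <- build_kmer_index(fx$tx)
  asg <- quantify_records(dm$records, idx)
  expect_true(all(asg$status == "MAPPED"))
  m <- merge(asg, fx$lib$truth, by = "read_id")
  expect_identical(m$gene_id.x, m$gene_id.y)
  expect_identical(m$pos5, as.integer(truth_pos5(m)))
})

test_that("UMI deduplication policies collapse as specified", {
  a <- data.frame(sample_id = "S1", gene_id = "g1",
                  umi = c("AAAAAA", "AAAAAA", "AAAAAA"),
                  pos5 = c(100L, 100L, 100L), stringsAsFactors = FALSE)
  expect_identical(sum(count_umis(a)$counts), 1)  # PCR-duplicate collapse
  b <- a[1:2, ]; b$pos5 <- c(100L, 400L)
  expect_identical(sum(count_umis(b, policy = "umi_pos")$counts), 2)
  expect_identical(sum(count_umis(b, policy = "umi")$counts), 1)
})

test_that("quantification reproduces ground-truth fragment counts exactly", {
  # UMIs drawn without replacement per (sample, gene): no collisions, so
  # matrix counts must equal the truth table's per-(sample, gene) sizes
  fx <- fixture_library(reads_per_sample = 400, eps = 0, seed = 204,
                        unique_umis = TRUE)
  dm <- demultiplex(fx$lib$reads, fx$sets$a, fx$sets$b, fx$sheet)
  idx <- build_kmer_index(fx$tx)
  asg <- quantify_records(dm$records, idx)
  em <- count_umis(asg[asg$status == "MAPPED", ],
                   genes = fx$tx$gene_id,
                   samples = fx$sheet$entries$sample_id)
  expected <- table(factor(fx$lib$truth$gene_id, fx$tx$gene_id),
                    factor(fx$lib$truth$sample_id,
                           fx$sheet$entries$sample_id))
  expect_identical(unname(as.matrix(em$counts)),
                   unname(matrix(as.numeric(expected), nrow(expected))))
  expect_lte(sum(em$counts), dm$stats$assigned_pairs)
})

test_that("gene detection saturates monotonically with read depth", {
  fx <- fixture_library(n_genes = 12, reads_per_sample = 250, eps = 0,
                        seed = 205)
  dm <- demultiplex(fx$lib$reads, fx$sets$a, fx$sets$b, fx$sheet)
  idx <- build_kmer_index(fx$tx)
  asg <- quantify_records(dm$records, idx)
  mp <- asg[asg$status == "MAPPED", ]
  sat <- downsample_saturation(mp, fractions = seq(0.1, 1, 0.1), seed = 1)
  for (s in unique(sat$sample_id)) {
    g <- sat$genes_detected[sat$sample_id == s]
    expect_true(all(diff(g) >= 0))
    u <- sat$unique_umis[sat$sample_id == s]
    expect_true(all(diff(u) >= 0))
  }
  # fraction 1.0 reproduces the full matrix
  full <- count_umis(mp)
  top <- sat[sat$fraction == 1, ]
  expect_identical(top$unique_umis[match(full$samples, top$sample_id)],
                   as.integer(full$per_sample_totals))
})

test_that("expression matrices round trip through MTX and TSV", {
  set.seed(206)
  a <- data.frame(sample_id = sample(sprintf("S%02d", 1:16), 3000, TRUE),
                  gene_id = sample(sprintf("g%03d", 1:200), 3000, TRUE),
                  umi = random_umis <- vapply(1:3000, function(i)
                    paste(sample(c("A", "C", "G", "T"), 6, TRUE),
                          collapse = ""), character(1)),
                  pos5 = sample.int(2000, 3000, TRUE),
                  stringsAsFactors = FALSE)
  em <- count_umis(a, genes = sprintf("g%03d", 1:200),
                   samples = sprintf("S%02d", 1:16))
  d <- withr::local_tempdir()
  write_matrix(em, file.path(d, "mtx"), format = "mtx")
  expect_true(startsWith(readLines(file.path(d, "mtx", "matrix.mtx"),
                                   n = 1), "%%MatrixMarket"))
  back <- read_matrix(file.path(d, "mtx"), format = "mtx")
  expect_equal(as.matrix(back$counts), as.matrix(em$counts))
  tsv <- file.path(d, "dense.tsv")
  write_matrix(em, tsv, format = "tsv")
  back2 <- read_matrix(tsv, format = "tsv")
  expect_equal(as.matrix(back2$counts), as.matrix(em$counts))
  # label/dimension mismatch is an error
  writeLines("onlygene", file.path(d, "mtx", "genes.tsv"))
  expect_error(read_matrix(file.path(d, "mtx")), "dimensions")
})
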