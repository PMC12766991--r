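## End-to-end driver: simulate -> decode/demux -> quantify -> QC, with a
## JSON run configuration, one seed, and a checksum manifest.

#' Default pipeline configuration
#'
#' Returns the full default configuration as a named list; every key is
#' documented here and unknown keys in a user configuration are rejected.
#'
#' \describe{
#'   \item{seed}{master seed; all stage seeds derive from it.}
#'   \item{out_dir}{artifact directory.}
#'   \item{n_barcodes_a,n_barcodes_b}{whitelist sizes (10 + 10 address 100
#'     samples).}
#'   \item{barcode_length,min_dist}{8-nt codes at Hamming distance >= 3.}
#'   \item{n_samples}{samples drawn from the combinatorial space.}
#'   \item{n_genes}{transcriptome size.}
#'   \item{species_mix}{NULL, or c(n_human, n_mouse) for barnyard designs.}
#'   \item{reads_per_sample, fragment_length_mean, fragment_length_sd,
#'     fragment_length_bounds, read_length, substitution_error_rate,
#'     umi_length, degradation_bias, expression_dispersion}{see
#'     [sim_config()].}
#'   \item{k, min_votes, stride}{k-mer assigner parameters.}
#'   \item{policy}{UMI dedup policy.}
#'   \item{min_tag_q}{tag base-quality floor.}
#'   \item{barnyard_threshold}{minor-species doublet threshold.}
#' }
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(seed = 1L, out_dir = "combitag_run",
       n_barcodes_a = 10L, n_barcodes_b = 10L,
       barcode_length = 8L, min_dist = 3L,
       n_samples = 6L, n_genes = 20L, species_mix = NULL,
       reads_per_sample = 2000L,
       fragment_length_mean = 400, fragment_length_sd = 75,
       fragment_length_bounds = c(150L, 800L),
       read_length = 150L, substitution_error_rate = 0.002,
       umi_length = 6L, degradation_bias = 0, expression_dispersion = 1,
       k = 21L, min_votes = 3L, stride = 3L,
       policy = "umi_pos", min_tag_q = 10L, barnyard_threshold = 0.20)
}

load_run_config <- function(config) {
  base <- default_run_config()
  user <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else if (is.list(config)) config
  else stop("config must be a file path or a list")
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(base, user)
  for (key in c("seed", "out_dir")) {
    if (is.null(cfg[[key]])) stop("config key '", key, "' must not be NULL")
  }
  cfg
}

#' Run the full pipeline
#'
#' Generates whitelists and a sample sheet, simulates the library, writes
#' FASTQ and ground truth, demultiplexes, quantifies, computes QC, and
#' writes every artifact plus a `manifest.json` with md5 checksums. All
#' randomness derives from `config$seed`; a rerun with the same seed
#' produces byte-identical outputs.
#'
#' @param config a named list overriding [default_run_config()] keys, or a
#'   path to a JSON file of overrides. Unknown keys are rejected.
#' @return Invisibly, a list with the in-memory objects (`setA`, `setB`,
#'   `sheet`, `tx`, `lib`, `demux`, `assignments`, `matrix`, `profile`,
#'   `calls`, `report`) and `paths` to the written artifacts.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- load_run_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  setA <- generate_barcode_set(cfg$n_barcodes_a, length = cfg$barcode_length,
                               min_dist = cfg$min_dist, seed = cfg$seed,
                               name = "A")
  setB <- generate_barcode_set(cfg$n_barcodes_b, length = cfg$barcode_length,
                               min_dist = cfg$min_dist, seed = cfg$seed + 1L,
                               avoid = setA, name = "B")
  full <- full_sample_sheet(setA, setB)
  if (cfg$n_samples > nrow(full$entries))
    stop("n_samples exceeds the combinatorial capacity")
  ## spread samples across distinct A and B codes (diagonal-first order)
  ord <- order((full$entries$a_index + full$entries$b_index) %%
                 max(cfg$n_barcodes_b, 1L), full$entries$a_index)
  pick <- full$entries[ord[seq_len(cfg$n_samples)], ]
  sheet <- sample_sheet(pick$a_index, pick$b_index,
                        sprintf("S%02d", seq_len(cfg$n_samples)),
                        setA = setA, setB = setB)

  tx <- make_transcriptome(cfg$n_genes, species_mix = cfg$species_mix,
                           seed = cfg$seed + 2L)
  scfg <- sim_config(reads_per_sample = cfg$reads_per_sample,
                     fragment_length_mean = cfg$fragment_length_mean,
                     fragment_length_sd = cfg$fragment_length_sd,
                     fragment_length_bounds = cfg$fragment_length_bounds,
                     read_length = cfg$read_length,
                     substitution_error_rate = cfg$substitution_error_rate,
                     umi_length = cfg$umi_length,
                     degradation_bias = cfg$degradation_bias,
                     expression_dispersion = cfg$expression_dispersion,
                     seed = cfg$seed + 3L)
  lib <- simulate_library(tx, sheet, setA, setB, scfg)

  paths <- list(
    whitelist_a = file.path(out, "whitelist_A.txt"),
    whitelist_b = file.path(out, "whitelist_B.txt"),
    sample_sheet = file.path(out, "sample_sheet.csv"),
    transcriptome = file.path(out, "transcriptome.fasta"),
    r1 = file.path(out, "reads_R1.fastq"),
    r2 = file.path(out, "reads_R2.fastq"),
    truth = file.path(out, "truth.tsv"),
    demux_stats = file.path(out, "demux_stats.json"),
    composition = file.path(out, "per_base_composition.tsv"),
    matrix_dir = file.path(out, "matrix"),
    coverage = file.path(out, "coverage_profile.tsv"),
    qc = file.path(out, "qc_report.json"),
    manifest = file.path(out, "manifest.json"))

  write_whitelist(setA, paths$whitelist_a)
  write_whitelist(setB, paths$whitelist_b)
  write_sample_sheet(sheet, paths$sample_sheet)
  write_transcriptome_fasta(tx, paths$transcriptome)
  write_fastq_pairs(lib$reads, paths$r1, paths$r2)
  write_truth(lib$truth, paths$truth)

  dm <- demultiplex(lib$reads, setA, setB, sheet, min_tag_q = cfg$min_tag_q)
  write_demux_stats(dm$stats, paths$demux_stats)
  comp <- per_base_composition(lib$reads$r1_seq)
  write.table(data.frame(position = seq_len(nrow(comp)), comp),
              paths$composition, sep = "\t", quote = FALSE,
              row.names = FALSE)

  idx <- build_kmer_index(tx, k = cfg$k)
  asg <- quantify_records(dm$records, idx, min_votes = cfg$min_votes,
                          stride = cfg$stride)
  mapped <- asg[asg$status == "MAPPED", , drop = FALSE]
  em <- count_umis(mapped, policy = cfg$policy, genes = tx$gene_id,
                   samples = sheet$entries$sample_id)
  write_matrix(em, paths$matrix_dir, format = "mtx")

  key <- paste(mapped$sample_id, mapped$gene_id, mapped$umi,
               (mapped$pos5 - 1L) %/% 10L)
  dedup <- mapped[!duplicated(key), , drop = FALSE]
  profile <- gene_body_coverage(dedup, tx)
  write_coverage_profile(profile, paths$coverage)

  calls <- if (!is.null(cfg$species_mix))
    barnyard_classify(em, threshold = cfg$barnyard_threshold)
  report <- qc_report(dm$stats, em, profile, calls)
  write_qc_report(report, paths$qc)

  files <- setdiff(unlist(paths), c(paths$manifest, paths$matrix_dir))
  files <- c(files, file.path(paths$matrix_dir,
                              c("matrix.mtx", "genes.tsv", "samples.tsv")))
  manifest <- lapply(files, function(f)
    list(path = f, md5 = unname(tools::md5sum(f)), bytes = file.size(f)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(setA = setA, setB = setB, sheet = sheet, tx = tx, lib = lib,
                 demux = dm, assignments = asg, matrix = em,
                 profile = profile, calls = calls, report = report,
                 paths = paths))
}
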