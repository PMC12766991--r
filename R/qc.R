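## Quality metrics: gene-body coverage with a 3'/5' bias index, barnyard
## species-mixing classification, and the aggregate JSON report.

#' Gene-body coverage profile
#'
#' Projects each fragment interval onto 100 percentile bins (5' to 3') of
#' its transcript, spreading each fragment's unit mass proportionally to
#' bin overlap; each transcript's profile is normalized to unit mass before
#' averaging over transcripts. Only transcripts at least `min_len` nt long
#' (and with at least one fragment) contribute.
#'
#' @param frags data frame with `transcript_id`, `frag_lo`, `frag_hi`
#'   (1-based inclusive forward-strand interval bounds), e.g. mapped rows of
#'   [quantify_records()] (deduplicate first with the same key as
#'   [count_umis()] to avoid duplicate-driven spikes) or a ground-truth table
#'   with `frag_lo = frag_start + 1`, `frag_hi = frag_end`.
#' @param tx the transcriptome (for template lengths).
#' @param min_len minimum transcript length (default 500 nt).
#' @param n_bins number of percentile bins (100).
#' @return A `coverage_profile`: list with `profile` (length-`n_bins` mean
#'   normalized coverage, summing to 1), `n_transcripts`, `n_fragments`.
#' @export
gene_body_coverage <- function(frags, tx, min_len = 500L, n_bins = 100L) {
  len_of <- setNames(tx$length, tx$transcript_id)
  f <- frags[!is.na(frags$transcript_id), , drop = FALSE]
  f <- f[len_of[f$transcript_id] >= min_len, , drop = FALSE]
  if (nrow(f) == 0L) stop("no eligible transcripts for coverage")
  L <- as.numeric(len_of[f$transcript_id])
  lo <- pmax(as.numeric(f$frag_lo), 1)
  hi <- pmin(as.numeric(f$frag_hi), L)
  keep <- hi >= lo
  f <- f[keep, , drop = FALSE]; L <- L[keep]; lo <- lo[keep]; hi <- hi[keep]

  ## fractional bin span of each fragment: bins are [i*L/n, (i+1)*L/n)
  b_lo <- (lo - 1) * n_bins / L      # continuous bin coordinate of start
  b_hi <- hi * n_bins / L            # of end (exclusive)
  first <- pmin(floor(b_lo), n_bins - 1)
  last <- pmin(ceiling(b_hi) - 1, n_bins - 1)
  nb <- last - first + 1
  fi <- rep(seq_along(lo), nb)
  bin <- unlist(lapply(seq_along(lo), function(i) first[i]:last[i]),
                use.names = FALSE)
  ov <- pmin(bin + 1, b_hi[fi]) - pmax(bin, b_lo[fi])  # overlap in bin units
  w <- ov / (b_hi[fi] - b_lo[fi])                      # unit mass/fragment
  tid <- f$transcript_id[fi]

  dt <- data.table::data.table(tid = tid, bin = bin, w = w)
  per_tx <- dt[, .(mass = sum(w)), by = .(tid, bin)]
  per_tx[, mass := mass / sum(mass), by = tid]
  ntx <- length(unique(per_tx$tid))
  prof <- numeric(n_bins)
  agg <- per_tx[, .(m = sum(mass)), by = bin]
  prof[agg$bin + 1L] <- agg$m / ntx
  structure(list(profile = prof, n_bins = as.integer(n_bins),
                 n_transcripts = ntx, n_fragments = nrow(f)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage_profile: %d bins over %d transcripts (%d fragments), bias index %.3f\n",
              x$n_bins, x$n_transcripts, x$n_fragments,
              coverage_bias_index(x)))
  invisible(x)
}

#' 3'/5' coverage bias index
#'
#' Ratio of the mean mass of the 3'-most quintile of bins (81-100) to the
#' 5'-most quintile (1-20). 1.0 for a flat profile; grows with 3' bias,
#' e.g. with RNA degradation. Returns `Inf` when the 5' quintile carries no
#' mass.
#'
#' @param p a `coverage_profile` (or bare numeric profile vector).
#' @return Scalar bias index.
#' @export
coverage_bias_index <- function(p) {
  v <- if (inherits(p, "coverage_profile")) p$profile else as.numeric(p)
  n <- length(v)
  q <- n %/% 5L
  five <- mean(v[seq_len(q)])
  three <- mean(v[(n - q + 1L):n])
  if (five == 0) return(Inf)
  three / five
}

#' Write a coverage profile as TSV
#'
#' @param p a `coverage_profile`.
#' @param path TSV path (columns `bin`, `mean_coverage`).
#' @return `path`, invisibly.
#' @export
write_coverage_profile <- function(p, path) {
  write.table(data.frame(bin = seq_len(p$n_bins), mean_coverage = p$profile),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Barnyard species-mixing classification
#'
#' For each sample of a mixed-species (human/mouse) experiment, computes the
#' UMI counts attributed to each species and the minor-species fraction
#' `min(h, m) / (h + m)`. A sample is `MIXED` (doublet / cross-contaminated)
#' when the minor fraction is strictly greater than `threshold` (the "more
#' than 20%" rule); otherwise it is called for its major species. Samples
#' with zero total counts are `UNDETERMINED`.
#'
#' @param em an `expression_matrix` whose gene labels carry species
#'   prefixes, or any genes x samples matrix.
#' @param species optional character vector of per-gene species labels;
#'   by default parsed from the gene-id prefix before the first `_`.
#' @param threshold minor-fraction doublet threshold (default 0.20, strict
#'   inequality).
#' @return Data frame: `sample_id`, `human_count`, `mouse_count`,
#'   `minor_fraction`, `call` (`HUMAN`, `MOUSE`, `MIXED`, `UNDETERMINED`).
#' @export
barnyard_classify <- function(em, species = NULL, threshold = 0.20) {
  counts <- if (inherits(em, "expression_matrix")) em$counts else em
  genes <- rownames(counts)
  if (is.null(species)) species <- sub("_.*", "", genes)
  sp <- toupper(species)
  if (!all(sp %in% c("HUMAN", "MOUSE")))
    stop("every gene needs a HUMAN or MOUSE species label")
  h <- Matrix::colSums(counts[sp == "HUMAN", , drop = FALSE])
  m <- Matrix::colSums(counts[sp == "MOUSE", , drop = FALSE])
  tot <- h + m
  minor <- ifelse(tot > 0, pmin(h, m) / tot, NA_real_)
  call <- ifelse(tot == 0, "UNDETERMINED",
                 ifelse(minor > threshold, "MIXED",
                        ifelse(h >= m, "HUMAN", "MOUSE")))
  data.frame(sample_id = colnames(counts), human_count = as.numeric(h),
             mouse_count = as.numeric(m), minor_fraction = minor,
             call = call, stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate QC report
#'
#' Bundles demultiplexing statistics, expression-matrix summaries, the
#' coverage profile and (optionally) barnyard calls into one list, validated
#' for completeness, ready for JSON serialization.
#'
#' @param stats a `demux_stats` object.
#' @param em an `expression_matrix`.
#' @param profile a `coverage_profile`.
#' @param calls optional [barnyard_classify()] output.
#' @return A list of class `qc_report` with sections `demux`, `expression`,
#'   `coverage`, `barnyard` (NULL allowed only for `barnyard`).
#' @export
qc_report <- function(stats, em, profile, calls = NULL) {
  if (missing(stats) || is.null(stats)) stop("missing section: demux stats")
  if (missing(em) || is.null(em)) stop("missing section: expression matrix")
  if (missing(profile) || is.null(profile))
    stop("missing section: coverage profile")
  rep <- list(
    demux = list(total_pairs = stats$total_pairs,
                 assigned_pairs = stats$assigned_pairs,
                 barcode_filtration_rate = stats$barcode_filtration_rate,
                 whitelist_rate = stats$whitelist_rate,
                 unassigned_breakdown =
                   as.list(stats$unassigned_breakdown),
                 per_sample_counts =
                   as.list(setNames(stats$per_sample_counts,
                                    stats$sample_ids))),
    expression = list(n_genes = length(em$genes),
                      n_samples = length(em$samples),
                      policy = em$policy,
                      total_umis = as.integer(sum(em$counts)),
                      genes_detected_per_sample =
                        as.list(setNames(
                          as.integer(Matrix::colSums(em$counts > 0)),
                          em$samples))),
    coverage = list(n_bins = profile$n_bins,
                    n_transcripts = profile$n_transcripts,
                    n_fragments = profile$n_fragments,
                    bias_index = coverage_bias_index(profile),
                    profile = profile$profile),
    barnyard = if (!is.null(calls)) {
      lapply(seq_len(nrow(calls)), function(i) as.list(calls[i, ]))
    })
  class(rep) <- "qc_report"
  rep
}

#' Write / read a QC report (JSON)
#'
#' @param rep a `qc_report`.
#' @param path JSON path.
#' @return `write_qc_report()` returns `path` invisibly; `read_qc_report()`
#'   the report list (validated for the required sections).
#' @export
write_qc_report <- function(rep, path) {
  jsonlite::write_json(unclass(rep), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_qc_report
#' @export
read_qc_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("demux", "expression", "coverage")
  miss <- setdiff(need, names(rep))
  if (length(miss)) stop("missing section: ", paste(miss, collapse = ", "))
  rep
}
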