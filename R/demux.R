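## Combinatorial demultiplexing: restructure -> extract -> correct ->
## quality-filter -> assign, with conservation statistics.

#' Demultiplex a stream of read pairs
#'
#' Runs the full decoding cascade on a read table: tag extraction (with
#' structural checks), unique-nearest-neighbor barcode correction against
#' both whitelists, tag base-quality filtering, and sample-sheet lookup.
#' Every pair receives exactly one outcome:
#' `ASSIGNED`, `FAIL_STRUCTURE`, `BAD_A`, `BAD_B` (uncorrectable barcode),
#' `FAIL_QUALITY`, or `PAIR_NOT_IN_SHEET` (both barcodes whitelist-valid but
#' the combination is not an expected sample -- the cross-contamination
#' diagnostic class). Outcome counts always sum to the number of input pairs.
#'
#' @param reads data frame from [simulate_library()]/[read_fastq_pairs()]:
#'   `read_id`, `r1_seq`, `r1_qual`, `r2_seq`, `r2_qual`.
#' @param setA,setB the A and B [barcode_set()]s.
#' @param sheet a [sample_sheet()].
#' @param max_dist barcode correction radius (default Hamming 1).
#' @param min_tag_q minimum Phred quality over the 22 tag bases (default 10).
#' @param umi_length,me read-structure parameters.
#' @return List with:
#'   \describe{
#'     \item{records}{data frame, one row per pair: `read_id`, `status`,
#'       `a_index`, `b_index`, `a_dist`, `b_dist`, `umi`, `sample_id`,
#'       `insert_seq`, `insert_qual` (mate-2 insert after removal of the
#'       33-nt technical prefix; empty for structural failures).}
#'     \item{stats}{a `demux_stats` object (see Details).}
#'   }
#' @details `demux_stats` fields: `total_pairs`, `assigned_pairs`,
#'   `per_sample_counts`, `unassigned_breakdown` (named vector over the five
#'   failure reasons), `barcode_filtration_rate` (= assigned / total), and
#'   `whitelist_rate` (fraction of pairs with both barcodes whitelist-valid,
#'   regardless of sheet membership or tag quality).
#' @export
demultiplex <- function(reads, setA, setB, sheet, max_dist = 1L,
                        min_tag_q = 10L, umi_length = 6L, me = TN5_ME) {
  n <- nrow(reads)
  tags <- extract_tags(reads, umi_length = umi_length, me = me)
  corA <- correct_barcodes(tags$a_raw, setA, max_dist = max_dist)
  corB <- correct_barcodes(tags$b_raw, setB, max_dist = max_dist)
  qual_ok <- if (!is.null(tags$tag_qual))
    quality_filter_tags(tags$tag_qual, min_q = min_tag_q)
  else rep(TRUE, n)
  sample_id <- assign_sample(corA$index, corB$index, sheet)

  status <- rep("ASSIGNED", n)
  status[!is.na(corA$index) & !is.na(corB$index) & is.na(sample_id)] <-
    "PAIR_NOT_IN_SHEET"
  status[!qual_ok] <- "FAIL_QUALITY"
  status[is.na(corB$index)] <- "BAD_B"
  status[is.na(corA$index)] <- "BAD_A"
  status[tags$fail_structure] <- "FAIL_STRUCTURE"
  sample_id[status != "ASSIGNED"] <- NA_character_

  w <- r2_technical_width(umi_length = umi_length, me = me)
  insert_seq <- substring(reads$r2_seq, w + 1L)
  insert_qual <- substring(reads$r2_qual, w + 1L)
  insert_seq[tags$fail_structure] <- ""
  insert_qual[tags$fail_structure] <- ""

  records <- data.frame(read_id = reads$read_id, status = status,
                        a_index = corA$index, b_index = corB$index,
                        a_dist = corA$dist, b_dist = corB$dist,
                        umi = tags$umi, sample_id = sample_id,
                        insert_seq = insert_seq, insert_qual = insert_qual,
                        stringsAsFactors = FALSE)
  assigned <- sum(status == "ASSIGNED")
  per_sample <- table(factor(sample_id, levels = sheet$entries$sample_id))
  breakdown <- c(structure = sum(status == "FAIL_STRUCTURE"),
                 bad_a = sum(status == "BAD_A"),
                 bad_b = sum(status == "BAD_B"),
                 quality = sum(status == "FAIL_QUALITY"),
                 pair_not_in_sheet = sum(status == "PAIR_NOT_IN_SHEET"))
  stats <- structure(list(total_pairs = n, assigned_pairs = assigned,
                          per_sample_counts = as.integer(per_sample),
                          sample_ids = names(per_sample),
                          unassigned_breakdown = breakdown,
                          barcode_filtration_rate =
                            if (n > 0L) assigned / n else NA_real_,
                          whitelist_rate = if (n > 0L)
                            mean(!is.na(corA$index) & !is.na(corB$index))
                          else NA_real_),
                     class = "demux_stats")
  list(records = records, stats = stats)
}

#' @export
print.demux_stats <- function(x, ...) {
  cat(sprintf("demux: %d pairs, %d assigned (%.2f%%), whitelist-valid %.2f%%\n",
              x$total_pairs, x$assigned_pairs,
              100 * x$barcode_filtration_rate, 100 * x$whitelist_rate))
  bd <- x$unassigned_breakdown
  cat("  unassigned:", paste(sprintf("%s=%d", names(bd), bd),
                             collapse = " "), "\n")
  invisible(x)
}

#' Serialize demultiplexing statistics to JSON
#'
#' @param stats a `demux_stats` object from [demultiplex()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_demux_stats <- function(stats, path) {
  x <- unclass(stats)
  x$per_sample_counts <- as.list(setNames(x$per_sample_counts, x$sample_ids))
  x$sample_ids <- NULL
  x$unassigned_breakdown <- as.list(x$unassigned_breakdown)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Per-position base composition of a read stream
#'
#' Fraction of A/C/G/T/N at each of the first `n_positions` read positions.
#' Over the first 8 positions of raw reads this is the whitelist's positional
#' base usage weighted by sample abundance (the FastQC "per base sequence
#' content" signature of a barcoded library); downstream insert positions of
#' a random transcriptome tend to 25% per base.
#'
#' @param seqs character vector of reads.
#' @param n_positions number of leading positions to profile.
#' @return `n_positions` x 5 matrix of fractions (columns A, C, G, T, N);
#'   rows sum to 1 over reads long enough to contribute.
#' @export
per_base_composition <- function(seqs, n_positions = 30L) {
  if (length(seqs) == 0L) stop("no reads")
  n_positions <- min(n_positions, max(nchar(seqs)))
  out <- matrix(0, n_positions, 5L,
                dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  for (p in seq_len(n_positions)) {
    ch <- substr(seqs, p, p)
    ch <- ch[nzchar(ch)]
    ch[!ch %in% c("A", "C", "G", "T")] <- "N"
    tb <- table(factor(ch, levels = colnames(out)))
    out[p, ] <- as.numeric(tb) / length(ch)
  }
  out
}
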