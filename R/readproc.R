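## Read restructuring, tag extraction, whitelist error correction and
## technical-sequence trimming. All operations are vectorized over read
## tables; structurally deficient reads are flagged, never dropped silently.

#' Restructure read pairs
#'
#' Moves the barcode-B + UMI block (first 14 nt of mate 2) to the beginning
#' of mate 1 and deletes the full 33-nt technical prefix (barcode B + UMI +
#' mosaic end) from the 5' end of mate 2. Qualities are carried alongside.
#' The discarded window (bases 15-33 of mate 2) is the mosaic end, which is
#' constant and retained nowhere else.
#'
#' @param reads data frame with `r1_seq`, `r1_qual`, `r2_seq`, `r2_qual`
#'   (and any other columns, which are preserved).
#' @param umi_length,barcode_length,me read-structure parameters.
#' @return The data frame with restructured sequences/qualities and a logical
#'   column `fail_structure` (mate 2 shorter than the technical prefix, or
#'   mate 1 shorter than a barcode; such rows are left untouched).
#' @export
restructure_pairs <- function(reads, umi_length = 6L, barcode_length = 8L,
                              me = TN5_ME) {
  w <- r2_technical_width(barcode_length, umi_length, me)
  tag <- barcode_length + umi_length
  bad <- nchar(reads$r2_seq) < w | nchar(reads$r1_seq) < barcode_length
  ok <- !bad
  reads$r1_seq[ok] <- paste0(substr(reads$r2_seq[ok], 1L, tag),
                             reads$r1_seq[ok])
  reads$r1_qual[ok] <- paste0(substr(reads$r2_qual[ok], 1L, tag),
                              reads$r1_qual[ok])
  reads$r2_seq[ok] <- substring(reads$r2_seq[ok], w + 1L)
  reads$r2_qual[ok] <- substring(reads$r2_qual[ok], w + 1L)
  reads$fail_structure <- bad
  reads
}

#' Extract raw barcode and UMI tags
#'
#' Positional slicing of the raw (un-restructured) pair: barcode A is mate 1
#' positions 1-8, barcode B mate 2 positions 1-8, the UMI mate 2 positions
#' 9-14. Reads too short for the mate-2 technical prefix are flagged
#' `fail_structure` with empty tags.
#'
#' @param reads data frame with `r1_seq`, `r2_seq` (qualities optional; when
#'   present, tag qualities are extracted too).
#' @param umi_length,barcode_length,me read-structure parameters.
#' @return Data frame: `a_raw`, `b_raw`, `umi`, `fail_structure`, and (when
#'   qualities are present) `tag_qual` = concatenated qualities of the
#'   A + B + UMI bases.
#' @export
extract_tags <- function(reads, umi_length = 6L, barcode_length = 8L,
                         me = TN5_ME) {
  w <- r2_technical_width(barcode_length, umi_length, me)
  bad <- nchar(reads$r2_seq) < w | nchar(reads$r1_seq) < barcode_length
  a_raw <- substr(reads$r1_seq, 1L, barcode_length)
  b_raw <- substr(reads$r2_seq, 1L, barcode_length)
  umi <- substr(reads$r2_seq, barcode_length + 1L, barcode_length + umi_length)
  a_raw[bad] <- b_raw[bad] <- umi[bad] <- ""
  out <- data.frame(a_raw = a_raw, b_raw = b_raw, umi = umi,
                    fail_structure = bad, stringsAsFactors = FALSE)
  if (!is.null(reads$r1_qual) && !is.null(reads$r2_qual)) {
    tq <- paste0(substr(reads$r1_qual, 1L, barcode_length),
                 substr(reads$r2_qual, 1L, barcode_length + umi_length))
    tq[bad] <- ""
    out$tag_qual <- tq
  }
  out
}

#' Correct observed barcodes against a whitelist
#'
#' Unique-nearest-neighbor correction at Hamming distance `max_dist`
#' (default 1): an observed barcode maps to the single whitelist entry within
#' `max_dist`; ties at the minimum distance, no entry within range, or more
#' than `max_n` ambiguous `N` bases give `NA` (unassigned). `N` counts as a
#' mismatch to every letter. Exact matches always win at distance 0. With a
#' whitelist of minimum pairwise distance >= 3 this correction is sound: a
#' single substitution can never be attributed to the wrong barcode.
#'
#' @param observed character vector of observed barcodes (same width as the
#'   whitelist).
#' @param whitelist a [barcode_set()] or character vector.
#' @param max_dist maximum correction distance (default 1).
#' @param max_n observed barcodes with more than this many `N`s are
#'   unassigned outright (default 2).
#' @return Data frame `index` (1-based whitelist index or `NA`) and `dist`
#'   (Hamming distance to the chosen entry, `NA` when unassigned).
#' @export
correct_barcodes <- function(observed, whitelist, max_dist = 1L, max_n = 2L) {
  wl <- if (inherits(whitelist, "barcode_set")) whitelist$barcodes else whitelist
  L <- nchar(wl[1])
  n <- length(observed)
  idx <- rep(NA_integer_, n)
  dst <- rep(NA_integer_, n)
  if (n == 0L) return(data.frame(index = idx, dist = dst))
  usable <- nchar(observed) == L
  uo <- unique(observed[usable])
  if (length(uo)) {
    om <- str_to_mat(uo, L)
    nN <- rowSums(om == "N")
    D <- matrix(0L, length(uo), length(wl))
    for (j in seq_along(wl)) {
      wj <- strsplit(wl[j], "", fixed = TRUE)[[1]]
      D[, j] <- as.integer(rowSums(
        sweep(om, 2, wj, FUN = "!=") | (om == "N")))
    }
    dmin <- apply(D, 1L, min)
    nmin <- rowSums(D == dmin)
    jmin <- max.col(-D, ties.method = "first")
    hit <- dmin <= max_dist & nmin == 1L & nN <= max_n
    u_idx <- ifelse(hit, jmin, NA_integer_)
    u_dst <- ifelse(hit, dmin, NA_integer_)
    m <- match(observed, uo)
    idx[usable] <- u_idx[m[usable]]
    dst[usable] <- u_dst[m[usable]]
  }
  data.frame(index = idx, dist = dst)
}

#' Quality-filter tag bases
#'
#' A read fails when any base of its barcode/UMI tags has Phred quality below
#' `min_q` (default 10), mirroring low-quality barcode/UMI filtering.
#'
#' @param tag_qual character vector of concatenated tag quality strings
#'   (Phred+33), e.g. the `tag_qual` column of [extract_tags()].
#' @param min_q minimum acceptable Phred score.
#' @return Logical vector: `TRUE` = pass.
#' @export
quality_filter_tags <- function(tag_qual, min_q = 10L) {
  if (min_q <= 0L) return(rep(TRUE, length(tag_qual)))
  min_phred(tag_qual) >= min_q
}

#' Trim 3'-terminal poly(A)
#'
#' Removes the longest 3'-terminal suffix that is at least `min_run` long,
#' starts with an adenine, and contains at most `max_mismatch` non-A bases.
#' No-op when no suffix qualifies.
#'
#' @param seq,qual character vectors (qual may be `NULL`).
#' @param min_run minimum tail length to trim (default 6).
#' @param max_mismatch tolerated non-A bases inside the tail (default 1).
#' @return List of trimmed `seq` and `qual`.
#' @examples
#' trim_polya(paste0("ACGT", strrep("A", 20)))$seq  # "ACGT"
#' @export
trim_polya <- function(seq, qual = NULL, min_run = 6L, max_mismatch = 1L) {
  keep <- vapply(seq, function(s) {
    L <- nchar(s)
    if (L < min_run) return(L)
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    mm <- cumsum(ch != "A")
    ## candidate suffix lengths: >= min_run, <= max_mismatch non-A,
    ## first (5'-most) base of the suffix an A
    cand <- which(mm <= max_mismatch & seq_len(L) >= min_run & ch == "A")
    if (length(cand) == 0L) return(L)
    L - max(cand)
  }, integer(1), USE.NAMES = FALSE)
  out_seq <- substr(seq, 1L, keep)
  out_qual <- if (is.null(qual)) NULL else substr(qual, 1L, keep)
  list(seq = out_seq, qual = out_qual)
}

#' Trim adapter read-through at the mosaic end
#'
#' Fragments shorter than the read length read through into the opposite
#' adapter, whose first visible bases are the reverse complement of the
#' mosaic end. Truncates each read at the leftmost occurrence of
#' `revcomp(me)` allowing at most one mismatch; terminal partial matches of
#' at least `min_partial` nt (exact) are also trimmed.
#'
#' @param seq,qual character vectors (qual may be `NULL`).
#' @param me mosaic-end sequence.
#' @param max_mismatch mismatches tolerated in a full-length match.
#' @param min_partial minimum exact prefix of `revcomp(me)` recognized at the
#'   read's 3' terminus.
#' @return List of trimmed `seq` and `qual`.
#' @export
trim_me_readthrough <- function(seq, qual = NULL, me = TN5_ME,
                                max_mismatch = 1L, min_partial = 8L) {
  rme <- revcomp(me)
  Lme <- nchar(rme)
  n <- length(seq)
  if (n == 0L) return(list(seq = seq, qual = qual))
  L <- nchar(seq)
  cut <- L
  ## full-length matches (<= max_mismatch), vectorized over all reads
  long <- which(L >= Lme)
  if (length(long)) {
    hits <- Biostrings::vmatchPattern(rme, Biostrings::DNAStringSet(seq[long]),
                                      max.mismatch = max_mismatch)
    st <- vapply(Biostrings::startIndex(hits),
                 function(s) if (is.null(s)) NA_integer_ else min(s),
                 integer(1))
    found <- !is.na(st)
    cut[long[found]] <- st[found] - 1L
  }
  ## terminal partial matches: an exact >= min_partial prefix of rme at the
  ## read's 3' terminus (longest wins), only where no full match was found
  open <- which(cut == L & L >= min_partial)
  if (length(open)) {
    for (p in (Lme - 1L):min_partial) {
      cand <- open[L[open] >= p & cut[open] == L[open]]
      if (length(cand) == 0L) next
      hit <- substr(seq[cand], L[cand] - p + 1L, L[cand]) ==
        substr(rme, 1L, p)
      cut[cand[hit]] <- L[cand[hit]] - p
    }
  }
  list(seq = substr(seq, 1L, cut),
       qual = if (is.null(qual)) NULL else substr(qual, 1L, cut))
}
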