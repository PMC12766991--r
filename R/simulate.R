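## Read-level simulator for combinatorially barcoded tagmentation libraries.
##
## The physical picture mirrored here: pre-amplified full-length cDNA of each
## sample is tagmented by an A-type and a B-type transposome; only fragments
## carrying one A and one B adapter amplify in the indexing PCR, so every
## emitted pair is A--B. Mate 1 reads barcodeA + mosaic end + insert from the
## A-proximal fragment end; mate 2 reads barcodeB + UMI + mosaic end + insert
## from the B-proximal end on the opposite strand.

#' Simulation configuration
#'
#' Validated container of simulator parameters. Defaults are the package's
#' stated world: 150-nt paired reads; fragment lengths truncated
#' normal(400, 75) on [150, 800] nt, matching the ~300-500 bp tagmentation
#' product range of ~2 kb cDNA; 6-nt UMIs; per-base substitution error rate
#' 0.002 (a realistic Illumina error floor); log-normal(0, 1) per-sample
#' transcript abundances; no 3' degradation bias.
#'
#' @param reads_per_sample fragments (= read pairs) simulated per sample.
#' @param fragment_length_mean,fragment_length_sd,fragment_length_bounds
#'   truncated-normal insert-length model (nt).
#' @param read_length sequenced length of each mate (nt), must exceed the
#'   33-nt mate-2 technical prefix.
#' @param substitution_error_rate i.i.d. per-base substitution probability
#'   applied to every base of both mates; `0 <= rate < 0.25`.
#' @param umi_length UMI width (nt, default 6).
#' @param degradation_bias scalar `delta >= 0`. 0 = fragment start positions
#'   uniform over valid placements; `delta > 0` tilts starts toward the 3'
#'   end with weight proportional to `exp(delta * relative_position)`,
#'   emulating degraded (e.g. long-stored) RNA.
#' @param expression_dispersion log-normal sigma of per-sample transcript
#'   abundances.
#' @param unique_umis_per_gene draw UMIs without replacement within each
#'   (sample, gene): removes UMI collisions so truth and quantification agree
#'   exactly (used by round-trip tests).
#' @param me mosaic-end sequence (19 nt canonical Tn5).
#' @param seed integer seed; the whole library is deterministic given it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(reads_per_sample = 1000L,
                       fragment_length_mean = 400,
                       fragment_length_sd = 75,
                       fragment_length_bounds = c(150L, 800L),
                       read_length = 150L,
                       substitution_error_rate = 0.002,
                       umi_length = 6L,
                       degradation_bias = 0,
                       expression_dispersion = 1,
                       unique_umis_per_gene = FALSE,
                       me = TN5_ME,
                       seed = 1L) {
  eps <- substitution_error_rate
  if (eps < 0 || eps >= 0.25)
    stop("substitution_error_rate must be in [0, 0.25)")
  if (read_length <= r2_technical_width(umi_length = umi_length, me = me))
    stop("read_length must exceed the mate-2 technical prefix")
  if (fragment_length_bounds[1] > fragment_length_bounds[2])
    stop("fragment_length_bounds must be increasing")
  if (fragment_length_bounds[1] < 2L * umi_length)
    stop("fragment lower bound implausibly small")
  if (degradation_bias < 0) stop("degradation_bias must be >= 0")
  structure(list(reads_per_sample = as.integer(reads_per_sample),
                 fragment_length_mean = fragment_length_mean,
                 fragment_length_sd = fragment_length_sd,
                 fragment_length_bounds = as.integer(fragment_length_bounds),
                 read_length = as.integer(read_length),
                 substitution_error_rate = eps,
                 umi_length = as.integer(umi_length),
                 degradation_bias = degradation_bias,
                 expression_dispersion = expression_dispersion,
                 unique_umis_per_gene = isTRUE(unique_umis_per_gene),
                 me = me, seed = as.integer(seed)),
            class = "sim_config")
}

## Truncated-normal draws by vectorized rejection.
rtruncnorm_int <- function(n, mean, sd, bounds) {
  if (sd == 0) return(rep(as.integer(round(mean)), n))
  out <- integer(0)
  while (length(out) < n) {
    x <- round(rnorm(n - length(out) + 64L, mean, sd))
    x <- x[x >= bounds[1] & x <= bounds[2]]
    out <- c(out, as.integer(x))
  }
  out[seq_len(n)]
}

## Start positions on windows [0, W]: uniform when delta == 0, else tilted
## toward 3' with density proportional to exp(delta * x/W) (inverse-CDF of the
## continuous tilt, then rounded onto the integer window).
draw_starts <- function(W, delta) {
  u <- runif(length(W))
  if (delta == 0) return(as.integer(floor(u * (W + 1L))))
  x <- log1p(u * (exp(delta) - 1)) / delta  # in [0, 1]
  as.integer(pmin(W, round(x * W)))
}

## Apply i.i.d. substitution errors at rate eps to sequences `seqs`; quality
## strings get Q14 ('/') at error positions, Q37 ('F') elsewhere. Returns
## list(seq, qual). Binomial decomposition: per-read error counts are
## Binomial(L, eps), positions distinct-uniform within the read.
inject_errors <- function(seqs, eps, qual_hi = "F", qual_lo = "/") {
  L <- nchar(seqs[1])
  n <- length(seqs)
  qual <- rep(strrep(qual_hi, L), n)
  if (eps == 0 || n == 0L) return(list(seq = seqs, qual = qual))
  nerr <- rbinom(n, L, eps)
  ## single-error reads: fully vectorized
  i1 <- which(nerr == 1L)
  if (length(i1)) {
    pos <- sample.int(L, length(i1), replace = TRUE)
    old <- substr(seqs[i1], pos, pos)
    shift <- sample.int(3L, length(i1), replace = TRUE)
    new <- DNA_BASES[((match(old, DNA_BASES) - 1L + shift) %% 4L) + 1L]
    substr(seqs[i1], pos, pos) <- new
    substr(qual[i1], pos, pos) <- qual_lo
  }
  ## multi-error reads: rare, handled per read
  for (i in which(nerr >= 2L)) {
    pos <- sample.int(L, nerr[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      new <- sample(setdiff(DNA_BASES, old), 1L)
      substr(seqs[i], p, p) <- new
      substr(qual[i], p, p) <- qual_lo
    }
  }
  list(seq = seqs, qual = qual)
}

#' Simulate a combinatorially barcoded tagmentation library
#'
#' Draws per-sample transcript abundances, fragments templates with the
#' truncated-normal length model, places fragments uniformly (or 3'-tilted,
#' see [sim_config()]), assembles both mates base-by-base including
#' read-through into the opposite adapter on short fragments, applies
#' substitution errors, and records every fragment in a ground-truth table.
#'
#' All content draws happen before error injection, so two runs with the same
#' seed and different `substitution_error_rate` produce the same underlying
#' fragments -- the error-free twin of a noisy library is
#' `simulate_library(..., cfg with rate 0)`.
#'
#' @param tx a [make_transcriptome()] transcriptome.
#' @param sheet a [sample_sheet()].
#' @param setA,setB the A and B [barcode_set()]s.
#' @param cfg a [sim_config()].
#' @param sample_species optional named vector (`sample_id -> species`)
#'   restricting each sample's abundance to genes of that species (barnyard
#'   designs); names absent from it get the full transcriptome.
#' @return A list with `reads` (data frame: `read_id`, `r1_seq`, `r1_qual`,
#'   `r2_seq`, `r2_qual`) and `truth` (data frame: `read_id`, `sample_id`,
#'   `gene_id`, `transcript_id`, `frag_start`, `frag_end` (0-based half-open
#'   template coordinates), `umi`, `a_end` ("left" if adapter A sits at the
#'   5' template end of the fragment), `a_index`, `b_index`).
#' @examples
#' a <- generate_barcode_set(2, seed = 1); b <- generate_barcode_set(2, seed = 2,
#'   avoid = a, name = "B")
#' sh <- sample_sheet(c(1, 2), c(1, 2), c("S1", "S2"))
#' tx <- make_transcriptome(3, seed = 3)
#' lib <- simulate_library(tx, sh, a, b, sim_config(reads_per_sample = 50))
#' nrow(lib$reads)
#' @export
simulate_library <- function(tx, sheet, setA, setB, cfg = sim_config(),
                             sample_species = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(sheet, "sample_sheet"))
  if (max(sheet$entries$a_index) > length(setA) ||
      max(sheet$entries$b_index) > length(setB))
    stop("sample sheet references barcodes outside the whitelists")
  if (cfg$fragment_length_bounds[2] > min(tx$length))
    stop(sprintf(
      "fragment upper bound %d exceeds the shortest template (%d nt)",
      cfg$fragment_length_bounds[2], min(tx$length)))
  set.seed(cfg$seed)

  S <- nrow(sheet$entries)
  ntx <- nrow(tx)
  n_frag <- S * cfg$reads_per_sample
  sample_of <- rep(seq_len(S), each = cfg$reads_per_sample)

  ## per-sample transcript abundances (log-normal, renormalized), optionally
  ## restricted to one species for barnyard designs
  tx_of <- integer(n_frag)
  for (s in seq_len(S)) {
    ab <- rlnorm(ntx, 0, cfg$expression_dispersion)
    sid <- sheet$entries$sample_id[s]
    if (!is.null(sample_species) && sid %in% names(sample_species))
      ab[tx$species != sample_species[[sid]]] <- 0
    if (all(ab == 0)) stop("sample ", sid, " has no expressible genes")
    idx <- sample.int(ntx, cfg$reads_per_sample, replace = TRUE,
                      prob = ab / sum(ab))
    tx_of[sample_of == s] <- idx
  }

  len <- rtruncnorm_int(n_frag, cfg$fragment_length_mean,
                        cfg$fragment_length_sd, cfg$fragment_length_bounds)
  Tlen <- tx$length[tx_of]
  start <- draw_starts(Tlen - len, cfg$degradation_bias)
  end <- start + len

  ## UMIs: i.i.d. 6-mers, or distinct within (sample, gene) when requested
  if (cfg$unique_umis_per_gene) {
    umi <- character(n_frag)
    grp <- split(seq_len(n_frag), paste(sample_of, tx_of))
    for (g in grp) {
      if (length(g) > 4^cfg$umi_length)
        stop("more fragments than distinct UMIs in one (sample, gene)")
      umi[g] <- int_to_dna(sample.int(4^cfg$umi_length, length(g)) - 1L,
                           cfg$umi_length)
    }
  } else {
    umi <- random_dna(n_frag, cfg$umi_length)
  }

  a_left <- runif(n_frag) < 0.5
  insert_fwd <- substring(tx$sequence[tx_of], start + 1L, end)
  insert_A <- ifelse(a_left, insert_fwd, revcomp(insert_fwd))
  insert_B <- revcomp(insert_A)

  a_idx <- sheet$entries$a_index[sample_of]
  b_idx <- sheet$entries$b_index[sample_of]
  bcA <- setA$barcodes[a_idx]
  bcB <- setB$barcodes[b_idx]
  me <- cfg$me; rme <- revcomp(me)

  r1 <- paste0(bcA, me, insert_A, rme, revcomp(umi), revcomp(bcB),
               revcomp(READ2_SITE))
  r2 <- paste0(bcB, umi, me, insert_B, rme, revcomp(bcA),
               revcomp(READ1_SITE))
  pad <- function(x, L) {
    short <- nchar(x) < L
    if (any(short)) x[short] <- paste0(x[short],
                                       strrep("G", L - nchar(x[short])))
    substr(x, 1L, L)
  }
  r1 <- pad(r1, cfg$read_length)
  r2 <- pad(r2, cfg$read_length)

  e1 <- inject_errors(r1, cfg$substitution_error_rate)
  e2 <- inject_errors(r2, cfg$substitution_error_rate)

  read_id <- sprintf("frag%08d", seq_len(n_frag))
  list(reads = data.frame(read_id = read_id,
                          r1_seq = e1$seq, r1_qual = e1$qual,
                          r2_seq = e2$seq, r2_qual = e2$qual,
                          stringsAsFactors = FALSE),
       truth = data.frame(read_id = read_id,
                          sample_id = sheet$entries$sample_id[sample_of],
                          gene_id = tx$gene_id[tx_of],
                          transcript_id = tx$transcript_id[tx_of],
                          frag_start = start, frag_end = end,
                          umi = umi,
                          a_end = ifelse(a_left, "left", "right"),
                          a_index = a_idx, b_index = b_idx,
                          stringsAsFactors = FALSE))
}

TRUTH_COLS <- c("read_id", "sample_id", "gene_id", "transcript_id",
                "frag_start", "frag_end", "umi", "a_end",
                "a_index", "b_index")

#' Write / read a ground-truth table (TSV)
#'
#' Lossless round trip; malformed rows raise an error naming the offending
#' line.
#'
#' @param truth ground-truth data frame from [simulate_library()].
#' @param path TSV path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` the table.
#' @export
write_truth <- function(truth, path) {
  stopifnot(all(TRUTH_COLS %in% names(truth)))
  write.table(truth[, TRUTH_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  ln <- readLines(path)
  if (length(ln) == 0L) stop("empty truth file")
  fields <- strsplit(ln, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(TRUTH_COLS))
  if (length(bad))
    stop(sprintf("malformed truth row at line %d: %d fields (expected %d)",
                 bad[1], nf[bad[1]], length(TRUTH_COLS)))
  if (!identical(fields[[1]], TRUTH_COLS))
    stop("truth header mismatch at line 1")
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(frag_start = "integer",
                                  frag_end = "integer",
                                  a_index = "integer", b_index = "integer"))
  df
}

#' Write simulated reads as paired FASTQ
#'
#' Standard 4-line FASTQ, Phred+33; gzip-transparent when the path ends in
#' `.gz`.
#'
#' @param reads `reads` data frame from [simulate_library()].
#' @param r1_path,r2_path output paths.
#' @return Invisibly, `c(r1_path, r2_path)`.
#' @export
write_fastq_pairs <- function(reads, r1_path, r2_path) {
  wr <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals),
                                compress = endsWith(path, ".gz"))
  }
  wr(reads$r1_seq, reads$r1_qual, reads$read_id, r1_path)
  wr(reads$r2_seq, reads$r2_qual, reads$read_id, r2_path)
  invisible(c(r1_path, r2_path))
}

#' @rdname write_fastq_pairs
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  rd <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(id = sub(" .*", "", names(x)), seq = unname(as.character(x)),
         qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
  }
  a <- rd(r1_path); b <- rd(r2_path)
  if (length(a$id) != length(b$id) || !all(a$id == b$id))
    stop("mate mismatch between R1 and R2 files")
  data.frame(read_id = a$id, r1_seq = a$seq, r1_qual = a$qual,
             r2_seq = b$seq, r2_qual = b$qual, stringsAsFactors = FALSE)
}
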