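## Internal sequence helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Split equal-length strings into a character matrix (rows = strings).
str_to_mat <- function(x, width = NULL) {
  if (is.null(width)) width <- nchar(x[1])
  stopifnot(all(nchar(x) == width))
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = width, byrow = TRUE)
}

## Hamming distance between one string and each element of a vector of
## equal-length strings. 'N' (or any non-ACGT symbol) mismatches everything,
## including itself.
hamming_to_each <- function(x, ys) {
  xc <- strsplit(x, "", fixed = TRUE)[[1]]
  ym <- str_to_mat(ys, length(xc))
  valid <- xc %in% DNA_BASES
  rowSums(sweep(ym, 2, xc, FUN = "!=") | matrix(!valid, nrow(ym),
                                                ncol(ym), byrow = TRUE))
}

## All-pairs minimum Hamming distance of a set of equal-length strings.
## O(k^2 L); fine for whitelist-scale k.
min_pairwise_hamming <- function(x) {
  k <- length(x)
  if (k < 2L) return(nchar(x[1]))  # vacuous: defined as the word length
  m <- str_to_mat(x)
  best <- ncol(m)
  for (i in seq_len(k - 1L)) {
    d <- rowSums(sweep(m[(i + 1L):k, , drop = FALSE], 2, m[i, ], FUN = "!="))
    best <- min(best, d)
  }
  as.integer(best)
}

## Phred+33 qualities of a vector of quality strings -> list of int vectors.
phred_ints <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

## Minimum Phred score per quality string (vectorized, 0-length safe).
min_phred <- function(qual) {
  vapply(qual, function(q) {
    if (!nzchar(q)) return(Inf)
    min(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

## Random DNA strings: n strings of the given width.
random_dna <- function(n, width) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * width, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

## Longest homopolymer run length per string.
max_homopolymer_run <- function(x) {
  vapply(x, function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    max(r$lengths)
  }, integer(1), USE.NAMES = FALSE)
}

gc_fraction <- function(x) {
  (nchar(gsub("[^GC]", "", x))) / nchar(x)
}

## Encode integers 0..(4^w - 1) as DNA words of width w (base-4, A=0).
int_to_dna <- function(i, width) {
  out <- matrix("A", length(i), width)
  v <- i
  for (p in width:1) {
    out[, p] <- DNA_BASES[(v %% 4L) + 1L]
    v <- v %/% 4L
  }
  do.call(paste0, as.data.frame(out, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
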