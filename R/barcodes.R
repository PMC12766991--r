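## Orthogonal barcode whitelist design and validation.
##
## Both barcodes are sequenced in 8-cycle windows, so single-substitution
## correction is sound only when every pair of codes that could be confused
## sits at Hamming distance >= 3. The design floor here is therefore 3, and
## cross-set orthogonality (A vs B) can be enforced with `avoid=`.

#' Construct a barcode set
#'
#' A `barcode_set` is a named whitelist of fixed-length DNA barcodes with a
#' recorded minimum pairwise Hamming distance. Normally produced by
#' [generate_barcode_set()] or [read_whitelist()]; this constructor validates
#' an explicit list of sequences.
#'
#' @param barcodes character vector of A/C/G/T barcodes, all the same length.
#' @param name set label, conventionally `"A"` or `"B"`.
#' @param min_dist design floor for the pairwise Hamming distance; the stored
#'   set must meet it.
#' @return An object of class `barcode_set` with fields `name`, `barcodes`,
#'   `length` and `min_pairwise_dist`.
#' @seealso [generate_barcode_set()], [validate_barcode_set()]
#' @export
barcode_set <- function(barcodes, name = "A", min_dist = 3L) {
  barcodes <- toupper(as.character(barcodes))
  if (length(barcodes) < 1L) stop("barcode set must contain >= 1 barcode")
  if (length(unique(nchar(barcodes))) != 1L)
    stop("all barcodes must have the same length")
  if (any(grepl("[^ACGT]", barcodes)))
    stop("barcodes must be over the alphabet {A,C,G,T}")
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in set")
  d <- min_pairwise_hamming(barcodes)
  if (d < min_dist)
    stop(sprintf("minimum pairwise Hamming distance %d is below the floor %d",
                 d, min_dist))
  structure(list(name = name, barcodes = barcodes,
                 length = nchar(barcodes[1]),
                 min_pairwise_dist = as.integer(d)),
            class = "barcode_set")
}

#' @export
print.barcode_set <- function(x, ...) {
  cat(sprintf("barcode_set '%s': %d barcodes x %d nt, min pairwise Hamming %d\n",
              x$name, length(x$barcodes), x$length, x$min_pairwise_dist))
  invisible(x)
}

#' @export
length.barcode_set <- function(x) length(x$barcodes)

#' Generate an orthogonal barcode whitelist
#'
#' Greedy randomized search: candidate words are drawn uniformly, filtered for
#' GC content and homopolymer runs, and accepted when they keep the pairwise
#' Hamming distance of the growing set (and of `avoid`, for cross-set
#' orthogonality with the other adapter's whitelist) at or above `min_dist`.
#' Deterministic for a fixed `seed`; raises a "design infeasible" error when
#' the search cannot place a code within `max_attempts` candidate draws.
#'
#' @param k number of barcodes to generate.
#' @param length barcode width in nt (default 8).
#' @param min_dist minimum pairwise Hamming distance (design floor, default 3,
#'   the smallest distance at which Hamming-1 correction is unambiguous).
#' @param gc_range allowed GC fraction interval.
#' @param max_homopolymer longest allowed single-base run.
#' @param seed integer seed; the search is deterministic given it.
#' @param avoid optional `barcode_set` (or character vector) of codes the new
#'   set must also stay `min_dist` away from (e.g. generate B avoiding A).
#' @param name label for the resulting set.
#' @param max_attempts candidate draws allowed per placed code.
#' @return A [barcode_set()].
#' @examples
#' a <- generate_barcode_set(10, seed = 7)
#' b <- generate_barcode_set(10, seed = 8, avoid = a, name = "B")
#' combinatorial_capacity(a, b)  # 100
#' @export
generate_barcode_set <- function(k, length = 8L, min_dist = 3L,
                                 gc_range = c(0.25, 0.75),
                                 max_homopolymer = 3L, seed = 1L,
                                 avoid = NULL, name = "A",
                                 max_attempts = 1e5) {
  stopifnot(k >= 1L, min_dist <= length)
  if (4^length < k) stop("design infeasible: 4^length < k")
  if (inherits(avoid, "barcode_set")) avoid <- avoid$barcodes
  if (!is.null(avoid) && any(nchar(avoid) != length))
    stop("'avoid' barcodes must have the same length as the new set")
  set.seed(seed)
  accepted <- character(0)
  batch <- 512L
  for (i in seq_len(k)) {
    attempts <- 0L
    placed <- FALSE
    while (attempts < max_attempts) {
      cand <- unique(random_dna(batch, length))
      attempts <- attempts + batch
      gc <- gc_fraction(cand)
      ok <- gc >= gc_range[1] & gc <= gc_range[2] &
        max_homopolymer_run(cand) <= max_homopolymer
      cand <- cand[ok]
      for (cd in cand) {
        ref <- c(accepted, avoid)
        if (length(ref) == 0L || min(hamming_to_each(cd, ref)) >= min_dist) {
          accepted <- c(accepted, cd)
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed)
      stop(sprintf(
        "design infeasible: could not place barcode %d/%d (length %d, min_dist %d) within %g attempts",
        i, k, length, min_dist, max_attempts))
  }
  barcode_set(accepted, name = name, min_dist = min_dist)
}

#' Validate a barcode whitelist
#'
#' Independent re-check of a whitelist against design constraints. Unlike the
#' constructor this never raises: it returns a report with the brute-force
#' all-pairs minimum Hamming distance, GC statistics, the longest homopolymer
#' run, and an overall pass flag.
#'
#' @param set a [barcode_set()] or character vector of equal-length barcodes.
#' @param min_dist required distance floor.
#' @param gc_range,max_homopolymer synthesis constraints to check against.
#' @return A list of class `barcode_validation`: `n`, `length`,
#'   `min_distance`, `gc` (range observed), `max_homopolymer`, `duplicates`,
#'   `pass`, and `failures` (character vector of reasons, empty on pass).
#' @export
validate_barcode_set <- function(set, min_dist = 3L, gc_range = c(0.25, 0.75),
                                 max_homopolymer = 3L) {
  bc <- if (inherits(set, "barcode_set")) set$barcodes else as.character(set)
  if (length(bc) < 1L) stop("empty barcode set")
  fails <- character(0)
  widths <- unique(nchar(bc))
  if (length(widths) != 1L) fails <- c(fails, "unequal barcode lengths")
  if (any(grepl("[^ACGT]", bc))) fails <- c(fails, "non-ACGT characters")
  dup <- anyDuplicated(bc) > 0L
  if (dup) fails <- c(fails, "duplicate barcodes")
  d <- if (length(widths) == 1L) min_pairwise_hamming(bc) else NA_integer_
  if (!is.na(d) && d < min_dist)
    fails <- c(fails, sprintf("min pairwise distance %d < floor %d", d, min_dist))
  gc <- gc_fraction(bc)
  if (any(gc < gc_range[1] | gc > gc_range[2]))
    fails <- c(fails, "GC content outside range")
  hp <- max(max_homopolymer_run(bc))
  if (hp > max_homopolymer)
    fails <- c(fails, sprintf("homopolymer run %d > %d", hp, max_homopolymer))
  structure(list(n = length(bc), length = widths[1], min_distance = d,
                 gc = range(gc), max_homopolymer = hp, duplicates = dup,
                 pass = length(fails) == 0L, failures = fails),
            class = "barcode_validation")
}

#' @export
print.barcode_validation <- function(x, ...) {
  cat(sprintf("barcode validation: n=%d L=%d minDist=%d GC=[%.2f,%.2f] maxRun=%d -> %s\n",
              x$n, x$length, x$min_distance, x$gc[1], x$gc[2],
              x$max_homopolymer, if (x$pass) "PASS" else "FAIL"))
  if (!x$pass) cat("  ", paste(x$failures, collapse = "; "), "\n")
  invisible(x)
}

#' Cross-set minimum Hamming distance
#'
#' Both barcodes are read in 8-cycle windows, so a B barcode must never be
#' correctable to an A barcode: the union of the two whitelists used in one
#' experiment should itself keep the design-floor distance.
#'
#' @param setA,setB [barcode_set()] objects (or character vectors).
#' @return Integer: the minimum Hamming distance over the union of both sets.
#' @export
cross_set_min_distance <- function(setA, setB) {
  a <- if (inherits(setA, "barcode_set")) setA$barcodes else setA
  b <- if (inherits(setB, "barcode_set")) setB$barcodes else setB
  min_pairwise_hamming(c(a, b))
}

#' Combinatorial sample capacity
#'
#' The number of addressable samples of an A x B combinatorial design:
#' `|A| * |B|`. With 10 barcodes on each adapter, 20 transposome species
#' address 100 samples.
#'
#' @param setA,setB [barcode_set()] objects.
#' @return Integer capacity.
#' @export
combinatorial_capacity <- function(setA, setB) {
  length(setA) * length(setB)
}

#' Read and write whitelist files
#'
#' Plain-text whitelists: one barcode per line, `#` comments and blank lines
#' ignored.
#'
#' @param set a [barcode_set()].
#' @param path file path.
#' @param name,min_dist passed to [barcode_set()] on read.
#' @return `write_whitelist()` returns `path` invisibly; `read_whitelist()`
#'   returns a [barcode_set()].
#' @export
write_whitelist <- function(set, path) {
  bc <- if (inherits(set, "barcode_set")) set$barcodes else as.character(set)
  writeLines(c(sprintf("# %d barcodes, length %d", length(bc), nchar(bc[1])),
               bc), path)
  invisible(path)
}

#' @rdname write_whitelist
#' @export
read_whitelist <- function(path, name = "A", min_dist = 1L) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  barcode_set(ln, name = name, min_dist = min_dist)
}
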