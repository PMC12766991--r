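## The (A_m, B_n) -> sample map of a combinatorial experiment.

#' Construct a sample sheet
#'
#' Maps (A-barcode index, B-barcode index) pairs to sample identifiers.
#' Indices are 1-based positions into the respective whitelists.
#'
#' @param a_index,b_index integer vectors of whitelist indices (1-based).
#' @param sample_id character vector of unique sample labels.
#' @param setA,setB optional [barcode_set()]s; when given, indices are
#'   validated against them and `m`/`n` are taken from the set sizes.
#' @return A `sample_sheet` object: data frame `entries` plus `m`, `n`.
#' @examples
#' sample_sheet(c(1, 1), c(1, 2), c("S1", "S2"))
#' @export
sample_sheet <- function(a_index, b_index, sample_id,
                         setA = NULL, setB = NULL) {
  a_index <- as.integer(a_index); b_index <- as.integer(b_index)
  sample_id <- as.character(sample_id)
  stopifnot(length(a_index) == length(b_index),
            length(a_index) == length(sample_id))
  if (length(a_index) < 1L) stop("sample sheet must have >= 1 entry")
  if (any(a_index < 1L) || any(b_index < 1L)) stop("indices are 1-based")
  if (anyDuplicated(paste(a_index, b_index))) stop("duplicate (A,B) pairs")
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  m <- if (!is.null(setA)) length(setA) else max(a_index)
  n <- if (!is.null(setB)) length(setB) else max(b_index)
  if (any(a_index > m)) stop("a_index exceeds the A whitelist")
  if (any(b_index > n)) stop("b_index exceeds the B whitelist")
  stopifnot(length(a_index) <= m * n)
  structure(list(entries = data.frame(a_index = a_index, b_index = b_index,
                                      sample_id = sample_id,
                                      stringsAsFactors = FALSE),
                 m = as.integer(m), n = as.integer(n)),
            class = "sample_sheet")
}

#' @export
print.sample_sheet <- function(x, ...) {
  cat(sprintf("sample_sheet: %d samples over a %d x %d barcode space\n",
              nrow(x$entries), x$m, x$n))
  invisible(x)
}

#' Full combinatorial sample sheet
#'
#' One sample per (A, B) pair: `|A| * |B|` samples named
#' `S<a>_<b>` by default.
#'
#' @param setA,setB [barcode_set()]s.
#' @param prefix sample-name prefix.
#' @return A [sample_sheet()].
#' @export
full_sample_sheet <- function(setA, setB, prefix = "S") {
  g <- expand.grid(a = seq_len(length(setA)), b = seq_len(length(setB)))
  sample_sheet(g$a, g$b, sprintf("%s%02d_%02d", prefix, g$a, g$b),
               setA = setA, setB = setB)
}

#' Look up the sample of a corrected barcode pair
#'
#' Exact lookup of `(a_idx, b_idx)` in the sheet. Any `NA` component (an
#' uncorrectable barcode) and any pair absent from the sheet returns `NA`
#' ("pair not in sheet" -- the cross-contamination diagnostic class).
#'
#' @param a_idx,b_idx integer vectors of corrected whitelist indices
#'   (`NA` = unassigned barcode).
#' @param sheet a [sample_sheet()].
#' @return Character vector of sample ids, `NA` where unassigned.
#' @export
assign_sample <- function(a_idx, b_idx, sheet) {
  key <- paste(a_idx, b_idx, sep = ":")
  map <- setNames(sheet$entries$sample_id,
                  paste(sheet$entries$a_index, sheet$entries$b_index, sep = ":"))
  out <- unname(map[key])
  out[is.na(a_idx) | is.na(b_idx)] <- NA_character_
  out
}

#' Read and write sample sheets (CSV)
#'
#' Columns `a_index`, `b_index`, `sample_id`.
#'
#' @param sheet a [sample_sheet()].
#' @param path file path.
#' @return `write_sample_sheet()` returns `path` invisibly;
#'   `read_sample_sheet()` returns a [sample_sheet()].
#' @export
write_sample_sheet <- function(sheet, path) {
  write.csv(sheet$entries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("a_index", "b_index", "sample_id")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns a_index, b_index, sample_id")
  sample_sheet(df$a_index, df$b_index, df$sample_id)
}
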