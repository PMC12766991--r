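## Synthetic transcriptomes: the templates the simulator fragments and the
## references the k-mer quantifier indexes. Each record is a full-length
## cDNA template: random transcript body plus the poly(A) stretch an
## oligo-dT(30)-primed RT retains.

#' Generate a synthetic transcriptome
#'
#' Transcript bodies are i.i.d. random DNA with log-normal lengths; a poly(A)
#' tail of `polya_length` adenines is appended to every body, mirroring the
#' oligo-dT-captured tail of pre-amplified full-length cDNA. With
#' `species_mix`, gene ids carry `HUMAN_`/`MOUSE_` prefixes and a `species`
#' column for barnyard (species-mixing) tests. Deterministic under `seed`.
#'
#' @param n_genes number of genes (one transcript per gene).
#' @param length_meanlog,length_sdlog log-normal parameters of body length.
#' @param length_bounds body lengths are clamped into this range (nt).
#' @param polya_length appended 3' adenine stretch (nt); 30 matches an
#'   oligo-dT(30) primer footprint.
#' @param species_mix optional `c(n_human, n_mouse)` split summing to
#'   `n_genes`.
#' @param seed integer seed.
#' @return A `transcriptome`: data frame with `gene_id`, `transcript_id`,
#'   `species`, `biotype`, `body_length`, `length` (template length including
#'   tail) and `sequence`.
#' @examples
#' tx <- make_transcriptome(5, seed = 1)
#' tx$length - tx$body_length  # all 30
#' @export
make_transcriptome <- function(n_genes, length_meanlog = log(2000),
                               length_sdlog = 0.25,
                               length_bounds = c(1000, 4000),
                               polya_length = 30L,
                               species_mix = NULL, seed = 1L) {
  stopifnot(n_genes >= 1L, length_bounds[1] >= 200L)
  set.seed(seed)
  lens <- round(rlnorm(n_genes, length_meanlog, length_sdlog))
  lens <- pmin(pmax(lens, length_bounds[1]), length_bounds[2])
  if (!is.null(species_mix)) {
    stopifnot(length(species_mix) == 2L, sum(species_mix) == n_genes)
    species <- rep(c("HUMAN", "MOUSE"), species_mix)
    gene_id <- c(sprintf("HUMAN_g%04d", seq_len(species_mix[1])),
                 sprintf("MOUSE_g%04d", seq_len(species_mix[2])))
  } else {
    species <- rep("SYN", n_genes)
    gene_id <- sprintf("g%04d", seq_len(n_genes))
  }
  tail <- strrep("A", polya_length)
  seqs <- vapply(lens, function(L) paste0(random_dna(1L, L), tail),
                 character(1))
  biotype <- rep("protein_coding", n_genes)
  ## a sprinkle of lncRNA labels, as annotation carries both classes
  if (n_genes >= 10L) biotype[seq(10L, n_genes, by = 10L)] <- "lncRNA"
  structure(data.frame(gene_id = gene_id,
                       transcript_id = paste0(gene_id, ".t1"),
                       species = species, biotype = biotype,
                       body_length = as.integer(lens),
                       length = as.integer(lens + polya_length),
                       sequence = seqs, stringsAsFactors = FALSE),
            polya_length = as.integer(polya_length),
            class = c("transcriptome", "data.frame"))
}

#' Write / read a transcriptome as FASTA
#'
#' Headers are `transcript_id gene=<gene_id> species=<species>
#' biotype=<biotype>`; round trip preserves all fields.
#'
#' @param tx a `transcriptome` (or any data frame with the same columns).
#' @param path FASTA path.
#' @return `write_transcriptome_fasta()` returns `path` invisibly;
#'   `read_transcriptome_fasta()` returns a `transcriptome`.
#' @export
write_transcriptome_fasta <- function(tx, path) {
  ss <- Biostrings::DNAStringSet(tx$sequence)
  names(ss) <- sprintf("%s gene=%s species=%s biotype=%s",
                       tx$transcript_id, tx$gene_id, tx$species, tx$biotype)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_transcriptome_fasta
#' @export
read_transcriptome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  field <- function(key) sub(sprintf(".*%s=([^ ]+).*", key), "\\1", hdr)
  seqs <- as.character(ss)
  lens <- nchar(seqs)
  polya <- nchar(seqs) - nchar(sub("A*$", "", seqs))
  structure(data.frame(gene_id = field("gene"),
                       transcript_id = sub(" .*", "", hdr),
                       species = field("species"), biotype = field("biotype"),
                       body_length = as.integer(lens - polya),
                       length = as.integer(lens),
                       sequence = unname(seqs), stringsAsFactors = FALSE),
            class = c("transcriptome", "data.frame"))
}
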