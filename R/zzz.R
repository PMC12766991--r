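## data.table non-standard evaluation columns
utils::globalVariables(c(
  ".", ".N", ".SD", "rid", "pos", "gene_id", "votes", "v1", "v2",
  "offset", "transcript_id", "strand", "dvotes", "kmer", "tid", "bin",
  "mass", "w", "diag"))
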