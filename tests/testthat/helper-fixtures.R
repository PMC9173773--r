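# Shared fixtures: templates are cheap to build but used everywhere.

loop_tpl <- built_in_template("loop")
side_tpl <- built_in_template("side")
default_m <- default_similarity_matrix()

random_peptides <- function(n, k, alphabet = AA_NO_CYS) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, k, replace = TRUE), collapse = ""), character(1))
}

# Write a FASTQ of hand-controlled records (no simulator randomness).
# reads: list of list(id, bases, quals) with quals a single int or vector.
write_manual_fastq <- function(reads, path = tempfile(fileext = ".fastq")) {
  lines <- unlist(lapply(reads, function(r) {
    q <- r$quals
    if (length(q) == 1L) q <- rep(q, nchar(r$bases))
    c(paste0("@", r$id), r$bases, "+", intToUtf8(q + 33L))
  }))
  writeLines(lines, path)
  path
}

# Deterministic construct for a peptide (first-listed codons only).
perfect_read <- function(template, peptide, quals = 35L) {
  list(id = paste0("r_", peptide),
       bases = construct_dna(template, peptide),
       quals = quals)
}

# 1-based offset of the first variable-region base inside the construct.
var_region_offset <- function(template) {
  dna <- construct_dna(template, strrep("A", length(template$randomized_positions)))
  regexpr(template$dna_flank_5p, dna, fixed = TRUE)[1] +
    nchar(template$dna_flank_5p)
}
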