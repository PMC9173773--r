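# Scaffold library templates and codon designs.

#' Standard amino-acid alphabet without cysteine
#'
#' The 19 standard residues allowed at randomized positions of the built-in
#' libraries. Cysteine is excluded by design: a solvent-exposed cysteine can
#' promote dimerization and is usually regarded as a liability in displayed
#' scaffolds.
#' @export
AA_NO_CYS <- c("A", "D", "E", "F", "G", "H", "I", "K", "L", "M",
               "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# PCR primers bracketing the variable regions in the scaffold gene.
#' Default amplification primers for the scaffold gene
#'
#' Forward and reverse PCR primers located in the constant part of the
#' scaffold coding sequence, spanning both variable regions.
#' @export
DEFAULT_PRIMERS <- list(fwd = "GGCCATGGCCAAATCTCC",
                        rev = "CCAGTTCCTGGAACAGGTC")

#' Codon design for library construction
#'
#' A codon design maps each amino acid to the codon(s) permitted in the
#' synthesised library DNA. The default uses one common \emph{E. coli} codon
#' per amino acid, has no cysteine codon, excludes the ochre (TAA) and opal
#' (TGA) stop codons entirely, and keeps the amber stop codon TAG as an
#' additional glutamine codon: in the suppressor host used for phage
#' production (\emph{E. coli} Tg1) TAG is read as Gln.
#'
#' @param codons named list mapping single-letter amino acids to character
#'   vectors of codons. Defaults to a common-codon table.
#' @param amber_q logical; if \code{TRUE} (default) TAG is added as a second
#'   glutamine codon.
#' @return an object of class \code{codon_design} with elements
#'   \code{codons} (named list) and \code{stop_policy}.
#' @examples
#' cd <- codon_design()
#' cd$codons$Q   # "CAG" "TAG"
#' @export
codon_design <- function(codons = NULL, amber_q = TRUE) {
  if (is.null(codons)) {
    codons <- list(
      A = "GCG", R = "CGT", N = "AAC", D = "GAT", E = "GAA",
      Q = "CAG", G = "GGC", H = "CAT", I = "ATT", L = "CTG",
      K = "AAA", M = "ATG", F = "TTT", P = "CCG", S = "AGC",
      T = "ACC", W = "TGG", Y = "TAT", V = "GTG")
  }
  codons <- lapply(codons, toupper)
  if (amber_q)
    codons$Q <- unique(c(codons$Q, "TAG"))
  all_codons <- unlist(codons, use.names = FALSE)
  if ("C" %in% names(codons))
    stop("codon design must not contain a cysteine codon")
  if (any(c("TAA", "TGA") %in% all_codons))
    stop("codon design must not contain the TAA or TGA stop codons")
  if ("TAG" %in% all_codons && !"TAG" %in% codons$Q)
    stop("TAG, if present, must be a glutamine codon")
  structure(list(codons = codons,
                 stop_policy = "TAA/TGA excluded; TAG reassigned to Q"),
            class = "codon_design")
}

#' Reverse-translate a peptide under a codon design
#'
#' @param peptide amino-acid string.
#' @param design a \code{\link{codon_design}}.
#' @param sample if \code{TRUE}, draw uniformly among the permitted codons
#'   for each residue (uses the current RNG state); if \code{FALSE}
#'   (default) the first listed codon is used deterministically.
#' @return a nucleotide string of length \code{3 * nchar(peptide)}.
#' @export
reverse_translate <- function(peptide, design = codon_design(),
                              sample = FALSE) {
  aas <- strsplit(peptide, "")[[1]]
  missing <- setdiff(aas, names(design$codons))
  if (length(missing))
    stop("no codon available for residue(s): ",
         paste(unique(missing), collapse = ", "))
  paste(vapply(aas, function(a) {
    cs <- design$codons[[a]]
    if (sample && length(cs) > 1L) cs[sample.int(length(cs), 1L)] else cs[[1L]]
  }, character(1)), collapse = "")
}

#' Define a scaffold library template
#'
#' A template is the constant amino-acid context of a display library with
#' placeholder characters marking the randomized positions, together with
#' the alphabet allowed at those positions and two DNA flank markers used by
#' the read-QC stage for orientation and frame anchoring.
#'
#' @param name template identifier.
#' @param constant_sequence amino-acid string with \code{placeholder} at each
#'   randomized position.
#' @param alphabet allowed letters at randomized positions
#'   (default \code{\link{AA_NO_CYS}}).
#' @param placeholder single placeholder character, default \code{"X"}.
#' @param dna_flank_5p,dna_flank_3p nucleotide markers bracketing the
#'   variable region in the expected construct DNA. If \code{NULL} they are
#'   derived from \code{flank_residues} residues of constant sequence on
#'   either side of the variable span, reverse-translated with
#'   \code{design}.
#' @param design codon design used to derive flanks and the expected
#'   constant-region DNA.
#' @param flank_residues number of constant residues used per flank marker
#'   when deriving flanks (default 5).
#' @return an object of class \code{scaffold_template}.
#' @seealso \code{\link{built_in_template}} for the shipped "loop" and
#'   "side" libraries.
#' @export
scaffold_template <- function(name, constant_sequence,
                              alphabet = AA_NO_CYS,
                              placeholder = "X",
                              dna_flank_5p = NULL, dna_flank_3p = NULL,
                              design = codon_design(),
                              flank_residues = 5L) {
  stopifnot(nchar(placeholder) == 1L, length(alphabet) >= 1L)
  if (placeholder %in% alphabet)
    stop("alphabet must not contain the placeholder character")
  chars <- strsplit(constant_sequence, "")[[1]]
  rand_pos <- which(chars == placeholder)
  if (length(rand_pos) == 0L)
    stop("constant_sequence contains no placeholder position")
  if (is.null(dna_flank_5p) || is.null(dna_flank_3p)) {
    lo <- min(rand_pos); hi <- max(rand_pos)
    if (lo - flank_residues < 1L || hi + flank_residues > length(chars))
      stop("not enough constant context to derive ", flank_residues,
           "-residue DNA flanks")
    up <- paste(chars[(lo - flank_residues):(lo - 1L)], collapse = "")
    dn <- paste(chars[(hi + 1L):(hi + flank_residues)], collapse = "")
    dna_flank_5p <- reverse_translate(up, design)
    dna_flank_3p <- reverse_translate(dn, design)
  }
  obj <- structure(list(name = name,
                        constant_sequence = constant_sequence,
                        placeholder = placeholder,
                        randomized_positions = rand_pos,
                        alphabet = alphabet,
                        dna_flank_5p = toupper(dna_flank_5p),
                        dna_flank_3p = toupper(dna_flank_3p)),
                   class = "scaffold_template")
  validate_template(obj)
  obj
}

validate_template <- function(template) {
  stopifnot(inherits(template, "scaffold_template"))
  chars <- strsplit(template$constant_sequence, "")[[1]]
  pos <- template$randomized_positions
  if (any(pos < 1L | pos > length(chars)))
    stop("randomized position outside constant_sequence")
  if (!all(chars[pos] == template$placeholder))
    stop("randomized positions must hold the placeholder character")
  if (template$placeholder %in% template$alphabet)
    stop("alphabet contains the placeholder")
  invisible(template)
}

#' @export
print.scaffold_template <- function(x, ...) {
  cat(sprintf("scaffold_template '%s': %d residues, %d randomized, %d-letter alphabet\n",
              x$name, nchar(x$constant_sequence),
              length(x$randomized_positions), length(x$alphabet)))
  cat(" ", x$constant_sequence, "\n")
  invisible(x)
}

# Constant contexts of the two shipped libraries. The side library carries a
# six-residue randomized patch on the first EF-hand; the loop library a
# 13-residue insert (GGG + 7 randomized + GGG) between the two EF-hands.
.BUILTIN_TEMPLATES <- list(
  loop = paste0("MKSPEELKRIFEKYAAKEGDPDQLSKDELKLLIQAEFPSLLKGM",
                "GGGXXXXXXXGGG",
                "STLDDLFQELDKDGDGEVSFEEFQVLVKKISQ"),
  side = paste0("MKSPEELKRIFEKYAAKEGDPDQLS", "XX", "EL", "XX", "LI", "XX",
                "EFPSLLKGM",
                "STLDDLFQELDKDGDGEVSFEEFQVLVKKISQ"))

#' Built-in library templates
#'
#' Returns one of the two shipped scaffold templates: \code{"loop"} (a
#' seven-residue randomized loop, flanked by triple glycines, inserted
#' between the two EF-hands of the scaffold; 13-residue insert in total) or
#' \code{"side"} (three randomized residue pairs on the surface of the first
#' EF-hand, six randomized positions in total). Both use the 19-letter
#' alphabet excluding cysteine.
#'
#' @param name \code{"loop"} or \code{"side"}.
#' @param design codon design used to derive the DNA flank markers.
#' @return a \code{\link{scaffold_template}}.
#' @examples
#' theoretical_diversity(built_in_template("side"))  # 19^6
#' @export
built_in_template <- function(name = c("loop", "side"),
                              design = codon_design()) {
  name <- match.arg(name)
  scaffold_template(name, .BUILTIN_TEMPLATES[[name]], design = design)
}

#' Theoretical diversity of a library template
#'
#' The number of distinct variable-region peptides the template can encode:
#' \code{|alphabet| ^ n_randomized}. For the built-in side library this is
#' 19^6 (about 5e7) and for the loop library 19^7 (about 9e8).
#'
#' @param template a \code{\link{scaffold_template}}.
#' @return exact integer count (numeric if it exceeds integer range).
#' @export
theoretical_diversity <- function(template) {
  validate_template(template)
  n <- length(template$randomized_positions)
  k <- length(template$alphabet)
  d <- k^n
  if (d <= .Machine$integer.max) as.integer(d) else d
}

#' Reconstruct the full variant protein from a variable-region peptide
#'
#' Replaces the placeholder positions of the template, in N-to-C order, with
#' the letters of \code{variable_seq}. For the side library the variable
#' region is the six-letter concatenation of the randomized positions
#' (e.g. \code{"VIWIDD"} for the VI-WI-DD patch).
#'
#' @param template a \code{\link{scaffold_template}}.
#' @param variable_seq peptide of length equal to the number of randomized
#'   positions.
#' @param allow_extra extra letters tolerated beyond the template alphabet
#'   (e.g. \code{"Q"} shows up from amber TAG codons even if Q were excluded).
#' @return full amino-acid sequence of the variant protein.
#' @examples
#' tpl <- built_in_template("loop")
#' build_variant_protein(tpl, "YLTIRLM")
#' @export
build_variant_protein <- function(template, variable_seq,
                                  allow_extra = character(0)) {
  validate_template(template)
  pos <- template$randomized_positions
  letters_in <- strsplit(variable_seq, "")[[1]]
  if (length(letters_in) != length(pos))
    stop(sprintf("variable_seq has length %d but template '%s' has %d randomized positions",
                 length(letters_in), template$name, length(pos)))
  bad <- setdiff(letters_in, c(template$alphabet, allow_extra))
  if (length(bad))
    stop("letters not in template alphabet: ", paste(unique(bad), collapse = ", "))
  chars <- strsplit(template$constant_sequence, "")[[1]]
  chars[pos] <- letters_in
  paste(chars, collapse = "")
}

#' Extract the variable region from a full variant protein
#'
#' Inverse of \code{\link{build_variant_protein}}: reads the letters at the
#' template's randomized positions.
#' @param template a \code{\link{scaffold_template}}.
#' @param protein full-length variant protein sequence.
#' @return the variable-region peptide.
#' @export
extract_variable_region <- function(template, protein) {
  validate_template(template)
  if (nchar(protein) != nchar(template$constant_sequence))
    stop("protein length does not match template")
  paste(strsplit(protein, "")[[1]][template$randomized_positions],
        collapse = "")
}

#' Build construct DNA for a library variant
#'
#' Assembles synthetic amplifiable DNA for a variant: forward primer site,
#' the coding sequence of the full variant protein under the codon design,
#' then the reverse complement of the reverse primer. This is the construct
#' the read simulator sequences; real amplicons additionally contain vector
#' context, so only length differences between libraries are meaningful.
#'
#' The constant-region DNA is fixed (one deterministic codon per residue,
#' as in a synthesised library), while variable-region codons may be
#' sampled among those the design permits (\code{sample_codons = TRUE}),
#' which is how amber TAG codons enter reads at glutamine positions.
#'
#' @inheritParams build_variant_protein
#' @param design codon design.
#' @param primers list with \code{fwd} and \code{rev} primer sequences.
#' @param sample_codons sample variable-region codons uniformly among those
#'   permitted (uses the current RNG state); if \code{FALSE} the first
#'   listed codon is used.
#' @return nucleotide string.
#' @export
construct_dna <- function(template, variable_seq, design = codon_design(),
                          primers = DEFAULT_PRIMERS, sample_codons = FALSE,
                          allow_extra = character(0)) {
  protein <- build_variant_protein(template, variable_seq,
                                   allow_extra = allow_extra)
  chars <- strsplit(protein, "")[[1]]
  is_var <- seq_along(chars) %in% template$randomized_positions
  codons <- vapply(seq_along(chars), function(i) {
    reverse_translate(chars[i], design, sample = sample_codons && is_var[i])
  }, character(1))
  paste0(primers$fwd, paste(codons, collapse = ""), revcomp(primers$rev))
}

#' Locate an amplicon between two primers
#'
#' Finds the unique occurrence of the forward primer on the sense strand and
#' of the reverse complement of the reverse primer downstream of it, and
#' returns the inclusive primer-to-primer span.
#'
#' @param dna template nucleotide string.
#' @param fwd_primer,rev_primer primer sequences (reverse primer given in
#'   its own 5'-3' orientation, as ordered from a vendor).
#' @return list with \code{start}, \code{end} (1-based inclusive),
#'   \code{length} in bp and \code{sequence}.
#' @examples
#' amp <- find_amplicon(paste0("GGAA", DEFAULT_PRIMERS$fwd, "ACGT",
#'                             revcomp(DEFAULT_PRIMERS$rev), "TT"),
#'                      DEFAULT_PRIMERS$fwd, DEFAULT_PRIMERS$rev)
#' amp$length  # len(fwd) + 4 + len(rev)
#' @export
find_amplicon <- function(dna, fwd_primer = DEFAULT_PRIMERS$fwd,
                          rev_primer = DEFAULT_PRIMERS$rev) {
  dna <- toupper(dna)
  f_hits <- locate_all(dna, toupper(fwd_primer))
  if (length(f_hits) == 0L) stop("forward primer not found in sequence")
  if (length(f_hits) > 1L) stop("forward primer found at multiple sites")
  rc <- revcomp(rev_primer)
  r_hits <- locate_all(dna, rc)
  r_hits <- r_hits[r_hits > f_hits]
  if (length(r_hits) == 0L)
    stop("reverse primer site not found downstream of the forward primer")
  if (length(r_hits) > 1L) stop("reverse primer found at multiple sites")
  start <- f_hits
  end <- r_hits + nchar(rc) - 1L
  list(start = start, end = end, length = end - start + 1L,
       sequence = substr(dna, start, end))
}

# All start positions of `pattern` in `x` (non-overlapping not required).
locate_all <- function(x, pattern) {
  m <- gregexpr(pattern, x, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Reverse complement of a nucleotide string
#'
#' @param x nucleotide string (A/C/G/T/N, case-insensitive).
#' @return reverse complement, uppercase.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

#' Read scaffold templates from a JSON config
#'
#' The config is a JSON array of objects with fields \code{name},
#' \code{constant_sequence}, and optionally \code{placeholder},
#' \code{alphabet}, \code{dna_flank_5p}, \code{dna_flank_3p}. A copy of the
#' built-in definitions ships in
#' \code{system.file("extdata", "templates.json", package = "panscreen")}.
#'
#' @param path JSON file path.
#' @param design codon design used when flanks must be derived.
#' @return named list of \code{\link{scaffold_template}} objects.
#' @export
read_templates <- function(path, design = codon_design()) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  out <- lapply(cfg, function(tc) {
    scaffold_template(
      name = tc$name,
      constant_sequence = tc$constant_sequence,
      alphabet = if (is.null(tc$alphabet)) AA_NO_CYS else unlist(tc$alphabet),
      placeholder = if (is.null(tc$placeholder)) "X" else tc$placeholder,
      dna_flank_5p = tc$dna_flank_5p, dna_flank_3p = tc$dna_flank_3p,
      design = design)
  })
  setNames(out, vapply(out, `[[`, character(1), "name"))
}

#' Write variant proteins to FASTA
#'
#' @param proteins named character vector (names become FASTA headers).
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_variant_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
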