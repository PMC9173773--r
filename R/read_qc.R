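# FASTQ read QC: orientation, filtering, frame anchoring and translation.

#' Fate labels of the read-QC cascade
#' @export
QC_FATES <- c("passed", "contains_N", "low_quality", "in_frame_stop",
              "unoriented", "flank_mismatch", "constant_mismatch",
              "frame_error")

#' Construct a read record
#'
#' Minimal container for one sequencing read: identifier, bases, per-base
#' Phred scores, an orientation flag and a QC fate, set exactly once by the
#' filter cascade.
#'
#' @param read_id identifier.
#' @param bases nucleotide string (A/C/G/T/N).
#' @param quals integer Phred scores, one per base.
#' @return object of class \code{read_record}.
#' @export
read_record <- function(read_id, bases, quals) {
  bases <- toupper(bases)
  if (nchar(bases) != length(quals))
    stop("bases and quals lengths differ for read ", read_id)
  structure(list(read_id = read_id, bases = bases, quals = as.integer(quals),
                 orientation = "undetermined", fate = NA_character_),
            class = "read_record")
}

#' Orient a read to the sense strand
#'
#' Looks for the template's DNA flank markers on the read and on its reverse
#' complement. Antisense reads are reverse-complemented in silico (qualities
#' reversed); reads whose markers are found on neither strand, or
#' ambiguously on both, get fate \code{unoriented}.
#'
#' @param read a \code{\link{read_record}}.
#' @param template a \code{\link{scaffold_template}}.
#' @return the read, with \code{orientation} set (and bases/quals flipped
#'   for antisense reads), or with fate \code{unoriented}.
#' @export
orient_read <- function(read, template) {
  sense <- .has_marker(read$bases, template)
  rc <- revcomp(read$bases)
  anti <- .has_marker(rc, template)
  if (sense && !anti) {
    read$orientation <- "sense"
  } else if (anti && !sense) {
    read$bases <- rc
    read$quals <- rev(read$quals)
    read$orientation <- "antisense"
  } else {
    read$fate <- "unoriented"
  }
  read
}

.has_marker <- function(bases, template) {
  grepl(template$dna_flank_5p, bases, fixed = TRUE) ||
    grepl(template$dna_flank_3p, bases, fixed = TRUE)
}

#' Quality filter: undetermined bases and Phred threshold
#'
#' A read fails with \code{contains_N} if any base is N, otherwise with
#' \code{low_quality} if any base has a Phred score below \code{min_phred}.
#' The default threshold 21 corresponds to a per-base error probability
#' just under 1\%. The whole read is screened, not only the variable
#' region.
#'
#' @param read a \code{\link{read_record}}.
#' @param min_phred minimum acceptable Phred score (default 21).
#' @return the read with fate set to \code{passed}, \code{contains_N} or
#'   \code{low_quality}. A fate set by an earlier filter is kept.
#' @export
quality_filter <- function(read, min_phred = 21L) {
  if (min_phred < 0) stop("min_phred must be non-negative")
  if (!is.na(read$fate)) return(read)
  if (grepl("N", read$bases, fixed = TRUE)) {
    read$fate <- "contains_N"
  } else if (any(read$quals < min_phred)) {
    read$fate <- "low_quality"
  }
  read
}

# Genetic code with amber suppression: TAG is read as Gln in the E. coli
# Tg1 host used for library production; TAA/TGA remain stops.
amber_genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc[["TAG"]] <- "Q"
  gc
}

#' Translate a variable-region codon string
#'
#' Standard genetic code with the amber codon TAG reassigned to glutamine
#' (the library design keeps TAG as a Gln codon for the suppressor host).
#' TAA or TGA anywhere in frame fails the read with \code{in_frame_stop}.
#'
#' @param codons nucleotide string, length divisible by 3, A/C/G/T only.
#' @return list with \code{status} (\code{"passed"}, \code{"in_frame_stop"}
#'   or \code{"frame_error"}) and \code{peptide} (NA unless passed).
#' @examples
#' translate_variable_region("TATCTGACCATTCGTCTGATG")$peptide  # "YLTIRLM"
#' translate_variable_region("TAGCTGACCATTCGTCTGATG")$peptide  # "QLTIRLM"
#' @export
translate_variable_region <- function(codons) {
  codons <- toupper(codons)
  if (nchar(codons) %% 3L != 0L || grepl("[^ACGT]", codons))
    return(list(status = "frame_error", peptide = NA_character_))
  gc <- amber_genetic_code()
  triplets <- substring(codons, seq(1, nchar(codons), 3),
                        seq(3, nchar(codons), 3))
  aas <- gc[triplets]
  if (any(aas == "*"))
    return(list(status = "in_frame_stop", peptide = NA_character_))
  list(status = "passed", peptide = paste(aas, collapse = ""))
}

# Expected window of construct DNA around the variable region: constant
# codons spelled out, variable codons as "...". Window spans from the first
# flank residue through the last.
.template_window <- function(template, design) {
  chars <- strsplit(template$constant_sequence, "")[[1]]
  pos <- template$randomized_positions
  fl <- nchar(template$dna_flank_5p) / 3L
  lo <- min(pos) - fl
  hi <- max(pos) + fl
  idx <- lo:hi
  codons <- character(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    codons[k] <- if (i %in% pos) "..." else reverse_translate(chars[i], design)
  }
  list(dna = paste(codons, collapse = ""),
       residues = idx,
       var_offsets = which(idx %in% pos))  # codon slots of variable residues
}

#' Frame and constant-region check; variable-codon extraction
#'
#' Anchors the expected construct window on the read via the 5' DNA flank
#' and validates the constant context around the variable region. For a
#' template with one contiguous variable span (loop library) both flanks
#' must match exactly and bracket exactly \code{3 * n_randomized}
#' nucleotides; a mismatch or truncation fails the read with
#' \code{flank_mismatch}. For an interspersed design (side library) every
#' constant nucleotide of the anchored window must equal the expected
#' construct; a deviation fails the read with \code{constant_mismatch}.
#' Flank matching is exact by default (\code{max_flank_mismatch = 0}); the
#' screen's filter specified exact expected sequences.
#'
#' @param read oriented, quality-passed \code{\link{read_record}}.
#' @param template a \code{\link{scaffold_template}}.
#' @param design codon design giving the expected constant-region DNA.
#' @return list with the (possibly failed) \code{read} and \code{codons},
#'   the concatenated variable-region codon string (NA on failure):
#'   21 nt for the loop library, 18 nt (six codons) for the side library.
#' @export
frame_and_constant_check <- function(read, template,
                                     design = codon_design()) {
  if (!is.na(read$fate)) return(list(read = read, codons = NA_character_))
  pos <- template$randomized_positions
  contiguous <- (max(pos) - min(pos) + 1L) == length(pos)
  bases <- read$bases
  f5 <- locate_all(bases, template$dna_flank_5p)
  if (length(f5) == 0L) {
    read$fate <- "flank_mismatch"
    return(list(read = read, codons = NA_character_))
  }
  f5 <- f5[1]
  if (contiguous) {
    var_len <- 3L * length(pos)
    var_start <- f5 + nchar(template$dna_flank_5p)
    f3_expect <- var_start + var_len
    have_3p <- substr(bases, f3_expect,
                      f3_expect + nchar(template$dna_flank_3p) - 1L)
    if (nchar(have_3p) < nchar(template$dna_flank_3p) ||
        have_3p != template$dna_flank_3p) {
      read$fate <- "flank_mismatch"
      return(list(read = read, codons = NA_character_))
    }
    codons <- substr(bases, var_start, var_start + var_len - 1L)
    return(list(read = read, codons = codons))
  }
  # interspersed design: compare all constant nucleotides in the window
  win <- .template_window(template, design)
  win_start <- f5
  win_end <- win_start + nchar(win$dna) - 1L
  if (win_end > nchar(bases)) {
    read$fate <- "flank_mismatch"
    return(list(read = read, codons = NA_character_))
  }
  observed <- substr(bases, win_start, win_end)
  exp_chars <- strsplit(win$dna, "")[[1]]
  obs_chars <- strsplit(observed, "")[[1]]
  const_idx <- exp_chars != "."
  if (!all(obs_chars[const_idx] == exp_chars[const_idx])) {
    read$fate <- "constant_mismatch"
    return(list(read = read, codons = NA_character_))
  }
  codons <- paste(vapply(win$var_offsets, function(k) {
    substr(observed, 3L * (k - 1L) + 1L, 3L * k)
  }, character(1)), collapse = "")
  list(read = read, codons = codons)
}

# In-frame stop pre-check: scan codons in the frame anchored by the 5'
# flank (which starts on a codon boundary of the construct), from the
# first complete codon in that frame to the end of the read.
.has_inframe_stop <- function(bases, template) {
  f5 <- locate_all(bases, template$dna_flank_5p)
  if (length(f5) == 0L) return(NA)  # cannot anchor a frame
  start <- ((f5[1] - 1L) %% 3L) + 1L
  n_codon <- (nchar(bases) - start + 1L) %/% 3L
  if (n_codon < 1L) return(FALSE)
  s <- seq(start, by = 3L, length.out = n_codon)
  triplets <- substring(bases, s, s + 2L)
  any(triplets %in% c("TAA", "TGA"))
}

# Vectorized equivalent of .has_inframe_stop for reads that share lengths
# and frames: scans in-frame triplets column-wise across the batch.
.batch_stop_scan <- function(seqs, anchor) {
  res <- logical(length(seqs))
  frame <- (anchor - 1L) %% 3L
  L <- nchar(seqs)
  groups <- split(seq_along(seqs), paste(frame, L))
  for (g in groups) {
    fr <- frame[g[1]]; len <- L[g[1]]
    if (len - fr < 3L) next
    starts <- seq(fr + 1L, len - 2L, by = 3L)
    sub <- seqs[g]
    hit <- rep(FALSE, length(g))
    for (s in starts) {
      tri <- substr(sub, s, s + 2L)
      hit <- hit | tri == "TAA" | tri == "TGA"
    }
    res[g] <- hit
  }
  res
}

#' Run the full read-QC cascade on a FASTQ file
#'
#' Applies, in order: undetermined-base (N) and Phred-quality filters and
#' the in-frame-stop filter (frame anchored on the 5' flank of whichever
#' strand carries it), then orientation, then flank / constant-region
#' validation, then translation of the variable region with TAG read as
#' Gln. This order matches the screen's pipeline, in which the stop-codon
#' and quality criteria were applied first and removed the large majority
#' of discarded reads.
#'
#' @param fastq_path FASTQ file, plain or gzipped, Phred+33 qualities.
#' @param template a \code{\link{scaffold_template}}.
#' @param design codon design for the expected constant-region DNA.
#' @param min_phred Phred threshold (default 21).
#' @return list with \code{peptides}, a data.frame (read_id, peptide) of
#'   passed reads in input order, and \code{report}, a \code{qc_report}.
#' @export
run_qc <- function(fastq_path, template, design = codon_design(),
                   min_phred = 21L) {
  if (min_phred < 0) stop("min_phred must be non-negative")
  fq <- read_fastq(fastq_path)
  n <- length(fq$bases)
  ids <- fq$ids
  if (n == 0L)
    return(list(peptides = data.frame(read_id = character(0),
                                      peptide = character(0)),
                report = qc_report(character(0))))
  bases <- fq$bases
  fates <- rep(NA_character_, n)

  # N and Phred filters (whole read)
  fates[grepl("N", bases, fixed = TRUE)] <- "contains_N"
  minq <- vapply(fq$quals, min, numeric(1))
  fates[is.na(fates) & minq < min_phred] <- "low_quality"

  # batch reverse complements once; all flank searches are vectorized
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(bases)))
  f5 <- template$dna_flank_5p; f3 <- template$dna_flank_3p
  sense_hit <- regexpr(f5, bases, fixed = TRUE) > 0L |
    regexpr(f3, bases, fixed = TRUE) > 0L
  anti_hit <- regexpr(f5, rc, fixed = TRUE) > 0L |
    regexpr(f3, rc, fixed = TRUE) > 0L

  # in-frame stop pre-check, frame anchored on the 5' flank of whichever
  # strand carries it
  f5_sense <- regexpr(f5, bases, fixed = TRUE)
  f5_anti <- regexpr(f5, rc, fixed = TRUE)
  alive <- is.na(fates)
  use_sense <- alive & f5_sense > 0L
  use_anti <- alive & !use_sense & f5_anti > 0L
  stop_hit <- logical(n)
  if (any(use_sense))
    stop_hit[use_sense] <- .batch_stop_scan(bases[use_sense],
                                            f5_sense[use_sense])
  if (any(use_anti))
    stop_hit[use_anti] <- .batch_stop_scan(rc[use_anti], f5_anti[use_anti])
  fates[alive & stop_hit] <- "in_frame_stop"

  # orientation
  unor <- is.na(fates) & (sense_hit == anti_hit)  # neither or both strands
  fates[unor] <- "unoriented"
  flip <- is.na(fates) & anti_hit
  bases[flip] <- rc[flip]

  # flank / constant check and variable-codon extraction (vectorized: the
  # expected window doubles as a regex with "." at variable positions)
  codons <- rep(NA_character_, n)
  alive <- is.na(fates)
  pos <- template$randomized_positions
  contiguous <- (max(pos) - min(pos) + 1L) == length(pos)
  f5pos <- regexpr(f5, bases, fixed = TRUE)
  bad5 <- alive & f5pos < 0L
  fates[bad5] <- "flank_mismatch"
  alive <- is.na(fates)
  if (contiguous) {
    var_len <- 3L * length(pos)
    var_start <- f5pos + nchar(f5)
    got3 <- substr(bases, var_start + var_len,
                   var_start + var_len + nchar(f3) - 1L)
    ok3 <- alive & got3 == f3
    fates[alive & !ok3] <- "flank_mismatch"
    codons[ok3] <- substr(bases[ok3], var_start[ok3],
                          var_start[ok3] + var_len - 1L)
  } else {
    win <- .template_window(template, design)
    w_end <- f5pos + nchar(win$dna) - 1L
    trunc <- alive & w_end > nchar(bases)
    fates[trunc] <- "flank_mismatch"
    alive <- is.na(fates)
    observed <- substr(bases, f5pos, w_end)
    ok_win <- alive & grepl(paste0("^", win$dna, "$"), observed)
    fates[alive & !ok_win] <- "constant_mismatch"
    idx <- which(ok_win)
    if (length(idx)) {
      parts <- lapply(win$var_offsets, function(kk)
        substr(observed[idx], 3L * (kk - 1L) + 1L, 3L * kk))
      codons[idx] <- do.call(paste0, parts)
    }
  }

  # batched translation with amber TAG -> Q
  peptides <- rep(NA_character_, n)
  idx <- which(is.na(fates))
  if (length(idx)) {
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(codons[idx]),
      genetic.code = amber_genetic_code(), no.init.codon = TRUE))
    stopped <- grepl("*", aa, fixed = TRUE)
    fates[idx[stopped]] <- "in_frame_stop"
    fates[idx[!stopped]] <- "passed"
    peptides[idx[!stopped]] <- aa[!stopped]
  }
  keep <- fates == "passed"
  list(peptides = data.frame(read_id = ids[keep], peptide = peptides[keep],
                             stringsAsFactors = FALSE),
       report = qc_report(fates))
}

#' Summarise QC fates
#'
#' @param fates character vector of per-read fates.
#' @return object of class \code{qc_report}: counts per fate, total,
#'   retained, retention fraction.
#' @export
qc_report <- function(fates) {
  counts <- table(factor(fates, levels = QC_FATES))
  total <- length(fates)
  retained <- as.integer(counts[["passed"]])
  structure(list(counts = as.list(as.integer(counts)) |>
                   setNames(QC_FATES),
                 total = total, retained = retained,
                 retention = if (total > 0) retained / total else NA_real_),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d reads, %d retained (%.1f%%)\n", x$total,
              x$retained, 100 * x$retention))
  nz <- Filter(function(v) v > 0, x$counts)
  for (f in names(nz)) cat(sprintf("  %-18s %d\n", f, nz[[f]]))
  invisible(x)
}

#' Write a QC report as JSON
#' @param report a \code{qc_report}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Thin wrapper around Biostrings FASTQ input. Returns parallel vectors of
# ids, bases and integer quality lists.
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- tryCatch(
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
    error = function(e) stop("failed to read FASTQ '", path, "': ",
                             conditionMessage(e)))
  quals <- as(Biostrings::quality(x), "IntegerList")
  list(ids = sub("\\s.*$", "", names(x)),
       bases = as.character(x),
       quals = as.list(quals))
}
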