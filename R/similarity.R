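# Amino-acid similarity matrices for ungapped peptide alignment.

# Physicochemical groups used by the default matrix.
.AA_GROUPS <- list(
  aliphatic = c("I", "L", "V", "M"),
  aromatic  = c("F", "W", "Y"),
  polar     = c("S", "T", "N", "Q"),
  positive  = c("K", "R", "H"),
  negative  = c("D", "E"),
  small     = c("A", "G"),
  proline   = "P")

# Cross-group relationships scoring above zero.
.AA_RELATED <- list(c("aromatic", "aliphatic"),
                    c("polar", "positive"),
                    c("polar", "negative"))

#' Default amino-acid similarity matrix
#'
#' An integer similarity matrix over the 19-letter (no cysteine) alphabet
#' with scores between 0 (no resemblance) and 9 (identity): identity scores
#' 9; two different residues in the same physicochemical group (aliphatic
#' ILVM, aromatic FWY, polar STNQ, positive KRH, negative DE, small AG,
#' proline alone) score 6; residues in related groups (aromatic--aliphatic,
#' polar--charged) score 3; anything else 0. The matrix is a plain integer
#' matrix and fully replaceable via \code{\link{read_similarity_matrix}}.
#'
#' @param alphabet letters covered by the matrix.
#' @return symmetric integer matrix of class \code{c("similarity_matrix",
#'   "matrix")} with row/column names.
#' @examples
#' m <- default_similarity_matrix()
#' pairwise_score("YLTIRLM", "YLTIRLM", m)  # 63
#' @export
default_similarity_matrix <- function(alphabet = AA_NO_CYS) {
  grp <- rep(NA_character_, length(alphabet))
  names(grp) <- alphabet
  for (g in names(.AA_GROUPS))
    grp[intersect(.AA_GROUPS[[g]], alphabet)] <- g
  related <- matrix(FALSE, length(.AA_GROUPS), length(.AA_GROUPS),
                    dimnames = list(names(.AA_GROUPS), names(.AA_GROUPS)))
  for (pair in .AA_RELATED) {
    related[pair[1], pair[2]] <- TRUE
    related[pair[2], pair[1]] <- TRUE
  }
  n <- length(alphabet)
  m <- matrix(0L, n, n, dimnames = list(alphabet, alphabet))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- alphabet[i]; b <- alphabet[j]
    m[i, j] <- if (a == b) 9L
      else if (!is.na(grp[a]) && identical(grp[a], grp[b])) 6L
      else if (!is.na(grp[a]) && !is.na(grp[b]) && related[grp[a], grp[b]]) 3L
      else 0L
  }
  as_similarity_matrix(m)
}

as_similarity_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m),
            !is.null(rownames(m)), identical(rownames(m), colnames(m)))
  storage.mode(m) <- "integer"
  if (!isSymmetric(unname(m))) stop("similarity matrix must be symmetric")
  if (any(m < 0L) || any(m > 9L)) stop("similarity scores must lie in [0, 9]")
  class(m) <- c("similarity_matrix", class(matrix()))
  m
}

#' Read a similarity matrix from TSV
#'
#' Expected format: a header row of amino-acid letters, one row per letter
#' with the letter in the first column, integer cells. Symmetry and the
#' 0--9 score range are validated.
#'
#' @param path TSV file.
#' @return a \code{similarity_matrix}.
#' @export
read_similarity_matrix <- function(path) {
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  colnames(m) <- colnames(df)
  as_similarity_matrix(m)
}

#' Write a similarity matrix to TSV
#'
#' @param m a \code{similarity_matrix}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_similarity_matrix <- function(m, path) {
  df <- as.data.frame(unclass(m), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Checksum identifying a similarity matrix
#'
#' Cluster outputs record this checksum so results can be tied to the exact
#' matrix used.
#' @param m a \code{similarity_matrix}.
#' @return md5 string of the canonical TSV serialization.
#' @export
similarity_matrix_checksum <- function(m) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write_similarity_matrix(m, tmp)
  unname(tools::md5sum(tmp))
}
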