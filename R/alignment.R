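# Ungapped all-vs-all peptide scoring, cutoff clustering and logo matrices.

#' Ungapped pairwise alignment score
#'
#' Scores two equal-length peptides position by position with a similarity
#' matrix and returns the sum. No gaps or shifts are considered; the screen
#' compares variable regions of fixed length.
#'
#' @param a,b peptides of equal length.
#' @param m a \code{\link{default_similarity_matrix}}-style matrix.
#' @return integer score in \code{[0, 9 * nchar(a)]} for matrices in the
#'   standard 0--9 range.
#' @examples
#' pairwise_score("YLTIRLM", "YLTIRLM")  # 63: seven identities at 9 each
#' @export
pairwise_score <- function(a, b, m = default_similarity_matrix()) {
  if (nchar(a) != nchar(b))
    stop(sprintf("peptide lengths differ (%d vs %d)", nchar(a), nchar(b)))
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  unknown <- setdiff(c(ca, cb), rownames(m))
  if (length(unknown))
    stop("letters absent from similarity matrix: ",
         paste(unique(unknown), collapse = ", "))
  sum(m[cbind(ca, cb)])
}

#' All-vs-all scores for a ranked peptide list
#'
#' Scores every unordered pair among up to a few hundred peptides (the
#' screen aligns the top 500 of each selection against each other).
#'
#' @param peptides character vector of equal-length peptides.
#' @param m similarity matrix.
#' @return data.frame with columns \code{i}, \code{j} (1-based indices,
#'   \code{i < j}), \code{peptide_i}, \code{peptide_j}, \code{score};
#'   exactly \code{n (n - 1) / 2} rows.
#' @export
all_vs_all <- function(peptides, m = default_similarity_matrix()) {
  n <- length(peptides)
  lens <- nchar(peptides)
  if (n > 0L && length(unique(lens)) > 1L)
    stop("peptides must all have equal length")
  if (n < 2L)
    return(data.frame(i = integer(0), j = integer(0),
                      peptide_i = character(0), peptide_j = character(0),
                      score = integer(0)))
  # integer-encode once; score via matrix lookup on index pairs
  L <- lens[1]
  alpha <- rownames(m)
  enc <- matrix(match(unlist(strsplit(peptides, "")), alpha), nrow = L)
  if (anyNA(enc))
    stop("letters absent from similarity matrix")
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  scores <- integer(length(i))
  for (p in seq_len(L))
    scores <- scores + m[cbind(enc[p, i], enc[p, j])]
  data.frame(i = i, j = j,
             peptide_i = peptides[i], peptide_j = peptides[j],
             score = scores)
}

#' Seed-centric cutoff cluster
#'
#' Collects all peptides from a variant table whose ungapped score against a
#' chosen seed peptide reaches a cutoff (the screen used 30 for the
#' seven-residue loop library and 27 for the six-residue side library).
#' This is a star cluster around the seed, not single-linkage: membership is
#' defined only by similarity to the seed.
#'
#' @param seed the reference peptide (always a member of its own cluster).
#' @param table a \code{\link{count_variants}} table, or a data.frame with
#'   columns \code{peptide} and \code{read_count}.
#' @param m similarity matrix.
#' @param cutoff minimum score for membership.
#' @return object of class \code{cluster_result}: list with \code{seed},
#'   \code{cutoff}, \code{matrix_checksum} and \code{members}, a data.frame
#'   (peptide, score, read_count) sorted by score desc, then read_count
#'   desc, then peptide.
#' @export
cluster_by_cutoff <- function(seed, table, m = default_similarity_matrix(),
                              cutoff) {
  if (!all(c("peptide", "read_count") %in% names(table)))
    stop("table must have columns 'peptide' and 'read_count'")
  L <- nchar(seed)
  if (cutoff < 0 || cutoff > 9L * L)
    stop("cutoff outside [0, 9 * peptide length]")
  peps <- table$peptide
  if (any(nchar(peps) != L))
    stop("seed length does not match table peptides")
  if (!seed %in% peps) {
    table <- rbind(table[, c("peptide", "read_count")],
                   data.frame(peptide = seed, read_count = 0L))
    peps <- table$peptide
  }
  scores <- vapply(peps, pairwise_score, integer(1), b = seed, m = m)
  keep <- scores >= cutoff
  members <- data.frame(peptide = peps[keep],
                        score = unname(scores[keep]),
                        read_count = table$read_count[keep])
  ord <- order(-members$score, -members$read_count, members$peptide)
  members <- members[ord, , drop = FALSE]
  rownames(members) <- NULL
  structure(list(seed = seed, cutoff = cutoff,
                 matrix_checksum = similarity_matrix_checksum(m),
                 members = members),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster around %s (cutoff %d): %d members\n",
              x$seed, x$cutoff, nrow(x$members)))
  print(head(x$members, 10))
  invisible(x)
}

#' Frequency and information-content (bits) logo matrices
#'
#' Computes, from a set of equal-length peptides with non-negative weights,
#' the per-position letter frequency matrix and the corresponding bits
#' matrix in the WebLogo convention: the information content of position
#' \eqn{p} is \eqn{R_p = \log_2(A) - H_p}, where \eqn{A} is the alphabet
#' size and \eqn{H_p} the Shannon entropy (log2) of the letter frequencies
#' at that position; each letter's bar height is its frequency times
#' \eqn{R_p}. The alphabet size defaults to 19 because cysteine is excluded
#' from the randomized positions by library design.
#'
#' @param peptides equal-length peptides (e.g. cluster members).
#' @param weights non-negative weights, default 1 per peptide (each unique
#'   sequence counts once); pass read counts to weight by abundance.
#' @param alphabet_size alphabet size used for the information content
#'   (default 19; set 20 to include cysteine).
#' @param alphabet letters forming the matrix columns.
#' @return list with \code{frequency} and \code{bits} matrices (positions x
#'   alphabet), \code{information} (per-position bits, numeric vector) and
#'   \code{alphabet_size}.
#' @export
logo_matrices <- function(peptides, weights = NULL,
                          alphabet_size = 19L, alphabet = AA_NO_CYS) {
  n <- length(peptides)
  if (n == 0L) stop("no peptides supplied")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights must match peptides in length")
  if (any(weights < 0)) stop("weights must be non-negative")
  tot <- sum(weights)
  if (tot <= 0) stop("total weight is zero")
  lens <- unique(nchar(peptides))
  if (length(lens) != 1L) stop("peptides must all have equal length")
  L <- lens
  chars <- matrix(unlist(strsplit(peptides, "")), nrow = L)
  extra <- setdiff(unique(as.vector(chars)), alphabet)
  if (length(extra)) alphabet <- c(alphabet, sort(extra))
  freq <- matrix(0, L, length(alphabet),
                 dimnames = list(paste0("pos", seq_len(L)), alphabet))
  for (p in seq_len(L)) {
    w <- tapply(weights, factor(chars[p, ], levels = alphabet), sum)
    w[is.na(w)] <- 0
    freq[p, ] <- w / tot
  }
  entropy <- apply(freq, 1, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  info <- pmax(log2(alphabet_size) - entropy, 0)
  bits <- freq * info
  list(frequency = freq, bits = bits, information = unname(info),
       alphabet_size = alphabet_size)
}
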