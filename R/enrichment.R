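# Variant counting, ranking, summaries and cross-selection overlaps.

#' Count variable-region peptides for one selection
#'
#' Exact multiset count of the peptides retained by QC, ranked by read
#' count descending with ties broken lexicographically so output order is
#' fully deterministic. Frequencies use the retained (QC-passed) reads as
#' denominator.
#'
#' @param peptides character vector of peptides (one entry per read).
#' @param selection_id label for the selection.
#' @return object of class \code{variant_table}: a data.frame with columns
#'   \code{peptide}, \code{read_count}, \code{frequency}, plus attributes
#'   \code{selection_id} and \code{total_retained_reads}.
#' @examples
#' count_variants(c("AAA", "AAA", "AAA", "BBB"))
#' @export
count_variants <- function(peptides, selection_id = "selection") {
  if (length(peptides) == 0L) {
    tab <- data.frame(peptide = character(0), read_count = integer(0),
                      frequency = numeric(0))
    warning("empty peptide stream for selection '", selection_id, "'")
  } else {
    counts <- table(peptides)
    df <- data.frame(peptide = names(counts),
                     read_count = as.integer(counts),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$read_count, df$peptide), , drop = FALSE]
    df$frequency <- df$read_count / length(peptides)
    rownames(df) <- NULL
    tab <- df
  }
  attr(tab, "selection_id") <- selection_id
  attr(tab, "total_retained_reads") <- length(peptides)
  class(tab) <- c("variant_table", class(tab))
  tab
}

#' Per-selection summary: top frequency and number of abundant sequences
#'
#' The two headline statistics reported per selection: the frequency of the
#' most abundant sequence (in percent) and the number of distinct
#' sequences observed at least \code{min_reads} times (default 100).
#'
#' @param table a \code{\link{count_variants}} table.
#' @param min_reads abundance threshold (default 100).
#' @return list with \code{top_freq_percent}, \code{n_seq_min_reads},
#'   \code{threshold} and \code{selection_id}.
#' @export
selection_summary <- function(table, min_reads = 100L) {
  if (nrow(table) == 0L) stop("cannot summarise an empty variant table")
  list(selection_id = attr(table, "selection_id"),
       top_freq_percent = 100 * table$frequency[1],
       n_seq_min_reads = sum(table$read_count >= min_reads),
       threshold = as.integer(min_reads))
}

#' Top-ranked peptides of a selection
#'
#' @param table a \code{\link{count_variants}} table.
#' @param n how many (default 500, as used by the screen); if the table has
#'   fewer rows, all are returned.
#' @param min_reads optional additional abundance filter applied before
#'   taking the top \code{n} (e.g. 100 to mirror the at-least-100-reads
#'   lists).
#' @return character vector of peptides in rank order.
#' @export
top_n_peptides <- function(table, n = 500L, min_reads = 0L) {
  if (n < 1L) stop("n must be at least 1")
  peps <- table$peptide[table$read_count >= min_reads]
  head(peps, n)
}

#' Overlaps between 2--4 peptide sets
#'
#' Computes the count of peptides in every intersection region of the Venn
#' diagram over the given sets (exact string identity, no clustering).
#' Regions are exclusive, so their counts sum to the size of the union.
#'
#' @param sets named list of 2--4 character vectors (names are selection
#'   ids).
#' @return data.frame with one row per non-empty membership pattern:
#'   logical columns (one per set), \code{region} (e.g. \code{"A&B"}) and
#'   \code{count}.
#' @export
overlap_analysis <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 4L) stop("overlap_analysis supports 2 to 4 sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- LETTERS[seq_len(k)]
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  names(patterns) <- names(sets)
  patterns <- patterns[rowSums(patterns) > 0L, , drop = FALSE]
  counts <- apply(patterns, 1, function(p) {
    sum(apply(member, 1, function(row) all(row == p)))
  })
  region <- apply(patterns, 1, function(p)
    paste(names(sets)[as.logical(p)], collapse = "&"))
  out <- cbind(patterns, region = region, count = as.integer(counts))
  rownames(out) <- NULL
  out
}

#' Naive-library quality statistics
#'
#' For an unselected (naive) library, diversity and uniformity checks: the
#' fraction of reads whose peptide occurs exactly once, the fraction whose
#' peptide occurs at most twice, and the per-position amino-acid frequency
#' matrix at the randomized positions. A well-made naive library shows
#' about 80\% unique reads at typical sequencing depth, over 99.9\% of
#' reads seen at most twice, and near-uniform positional frequencies.
#'
#' @param table a \code{\link{count_variants}} table of uniform-length
#'   peptides.
#' @param alphabet columns of the frequency matrix (default
#'   \code{\link{AA_NO_CYS}}).
#' @return list with \code{unique_read_fraction},
#'   \code{fraction_reads_seen_at_most_twice} and \code{position_frequency}
#'   (positions x alphabet matrix, rows summing to 1; read-weighted).
#' @export
library_qc <- function(table, alphabet = AA_NO_CYS) {
  if (nrow(table) == 0L) stop("empty variant table")
  if (length(unique(nchar(table$peptide))) != 1L)
    stop("peptides of mixed length")
  total <- sum(table$read_count)
  uniq <- sum(table$read_count[table$read_count == 1L]) / total
  at_most2 <- sum(table$read_count[table$read_count <= 2L]) / total
  lm <- logo_matrices(table$peptide, weights = table$read_count,
                      alphabet = alphabet)
  list(unique_read_fraction = uniq,
       fraction_reads_seen_at_most_twice = at_most2,
       position_frequency = lm$frequency)
}

#' Write a ranked variant table to TSV
#' @param table a \code{\link{count_variants}} table.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_variant_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
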