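# Synthetic panning simulator: uniform naive libraries, affinity-weighted
# selection rounds, sequencing errors, mixed read orientation.

#' Simulation configuration
#'
#' Collects the knobs of the synthetic sequencing model. Defaults are
#' desk-scale: 50,000 reads per round stand in for the ~5e6 reads of a real
#' selection (scaled down two orders of magnitude so the full pipeline runs
#' in seconds), a 0.1\% per-base substitution rate typical of merged
#' short-read data, half the reads in antisense orientation, and clamped
#' Gaussian Phred scores (mean 35, sd 4) whose only relevant feature is
#' their relationship to the >= 21 quality filter.
#'
#' @param n_reads reads per round.
#' @param n_rounds selection rounds (default 3, as in the screen).
#' @param error_rate per-base substitution probability, in [0, 0.2].
#' @param n_rate per-base probability of an undetermined (N) call.
#' @param antisense_fraction fraction of reads emitted reverse-complemented.
#' @param qual_mean,qual_sd Gaussian Phred score parameters (clamped to
#'   [2, 40]).
#' @param seed integer seed fixing all randomness end-to-end; \code{NULL}
#'   uses the current RNG state.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(n_reads = 50000L, n_rounds = 3L, error_rate = 0.001,
                       n_rate = 1e-4, antisense_fraction = 0.5,
                       qual_mean = 35, qual_sd = 4, seed = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 0.2, n_rate >= 0, n_rate <= 1,
            antisense_fraction >= 0, antisense_fraction <= 1,
            n_reads >= 1, n_rounds >= 0)
  structure(list(n_reads = as.integer(n_reads),
                 n_rounds = as.integer(n_rounds),
                 error_rate = error_rate, n_rate = n_rate,
                 antisense_fraction = antisense_fraction,
                 qual_mean = qual_mean, qual_sd = qual_sd, seed = seed),
            class = "sim_config")
}

.maybe_seed <- function(seed) if (!is.null(seed)) set.seed(seed)

#' Binder model for the selection simulator
#'
#' One or more motif families, each given as a position-weight score table
#' over the variable positions (rows = positions, columns = alphabet,
#' non-negative entries), plus a family weight. A peptide's motif score
#' under a family is the sum of its per-position table entries; its
#' selection fitness is
#' \deqn{w(p) = background + \sum_f weight_f \exp(stringency \cdot s_f(p)),}
#' a softmax-style sharpening in which \code{stringency} is the single
#' knob controlling how strongly one selection round enriches high-scoring
#' peptides. Explicit phage-titer kinetics are not modelled.
#'
#' @param families list of families, each a list with \code{pwm}
#'   (positions x alphabet matrix) and \code{weight} (positive scalar).
#' @param background baseline fitness of non-binders (> 0 keeps the pool
#'   from collapsing onto exact matches).
#' @param stringency selection sharpness per round.
#' @return object of class \code{binder_model}.
#' @export
binder_model <- function(families, background = 0.05, stringency = 1.0) {
  stopifnot(length(families) >= 1L, background >= 0, stringency >= 0)
  for (f in families) {
    stopifnot(is.matrix(f$pwm), all(f$pwm >= 0), f$weight >= 0)
    if (is.null(colnames(f$pwm))) stop("family pwm needs letter colnames")
  }
  structure(list(families = families, background = background,
                 stringency = stringency),
            class = "binder_model")
}

#' Default loop-library binder model
#'
#' A single motif family shaped like the YLTIRLM consensus recovered from
#' the amyloid-beta monomer selection: hydrophobic residues (L/I preferred,
#' V/M tolerated) fixed at positions 2, 4 and 6; polar residues, more
#' varied, at positions 1, 3 and 5 (Y/S/T favoured at 1 and 3); position 7
#' mixed. The \code{fixed_positions} attribute records which positions the
#' model conserves, for use by recovery tests.
#'
#' @param alphabet alphabet of the variable positions.
#' @return a \code{\link{binder_model}} with one family.
#' @export
binder_model_loop_default <- function(alphabet = AA_NO_CYS) {
  pwm <- matrix(0, nrow = 7, ncol = length(alphabet),
                dimnames = list(NULL, alphabet))
  set_row <- function(pos, ...) {
    vals <- c(...)
    pwm[pos, names(vals)] <<- vals
  }
  # Varied polar positions score many letters equally (weak conservation
  # after selection); the fixed hydrophobic positions concentrate on L/I.
  polar <- setNames(rep(0.6, 8), c("Y", "S", "T", "N", "Q", "D", "E", "R"))
  hydro <- c(L = 1.0, I = 0.95, V = 0.5, M = 0.5)
  mixed <- setNames(rep(0.6, 8), c("M", "L", "Y", "Q", "T", "S", "F", "I"))
  do.call(set_row, c(list(1), as.list(polar)))
  do.call(set_row, c(list(2), as.list(hydro)))
  do.call(set_row, c(list(3), as.list(polar)))
  do.call(set_row, c(list(4), as.list(hydro)))
  do.call(set_row, c(list(5), as.list(setNames(rep(0.6, 8),
          c("R", "K", "E", "D", "S", "T", "N", "Q")))))
  do.call(set_row, c(list(6), as.list(hydro)))
  do.call(set_row, c(list(7), as.list(mixed)))
  model <- binder_model(list(list(pwm = pwm, weight = 1)))
  attr(model, "fixed_positions") <- c(2L, 4L, 6L)
  attr(model, "consensus") <- "YLTIRLM"
  model
}

# Motif score of each peptide under one family pwm.
.family_scores <- function(peptides, pwm) {
  L <- nrow(pwm)
  chars <- matrix(unlist(strsplit(peptides, "")), nrow = L)
  s <- numeric(length(peptides))
  for (p in seq_len(L)) {
    idx <- match(chars[p, ], colnames(pwm))
    row <- pwm[p, ]
    s <- s + ifelse(is.na(idx), 0, row[idx])
  }
  s
}

#' Selection fitness of peptides under a binder model
#'
#' @param peptides character vector.
#' @param model a \code{\link{binder_model}}.
#' @return numeric fitness values (strictly positive when
#'   \code{background > 0}).
#' @export
binder_fitness <- function(peptides, model) {
  w <- rep(model$background, length(peptides))
  for (f in model$families)
    w <- w + f$weight * exp(model$stringency *
                              .family_scores(peptides, f$pwm))
  w
}

#' Simulate a uniform naive library
#'
#' Draws \code{n_reads} variable-region peptides uniformly over
#' \code{alphabet^k} and returns the pool as a counted table. If
#' \code{fastq} is given, reads are also rendered to FASTQ via
#' \code{\link{write_reads_fastq}} (codon sampling, sequencing errors,
#' qualities, mixed orientation).
#'
#' @param template a \code{\link{scaffold_template}}.
#' @param config a \code{\link{sim_config}} (its \code{seed}, if set, fixes
#'   all randomness of this call).
#' @param design codon design for read rendering.
#' @param fastq optional FASTQ(.gz) output path.
#' @return list with \code{pool} (data.frame peptide / count),
#'   \code{peptides} (one per read, in emission order) and \code{fastq}
#'   (path or NULL).
#' @export
simulate_naive_library <- function(template, config = sim_config(),
                                   design = codon_design(), fastq = NULL) {
  validate_template(template)
  .maybe_seed(config$seed)
  k <- length(template$randomized_positions)
  mat <- matrix(sample(template$alphabet, config$n_reads * k, replace = TRUE),
                ncol = k)
  peptides <- apply(mat, 1, paste, collapse = "")
  pool <- pool_from_peptides(peptides)
  path <- NULL
  if (!is.null(fastq))
    path <- write_reads_fastq(peptides, template, config, design, fastq)
  list(pool = pool, peptides = peptides, fastq = path)
}

pool_from_peptides <- function(peptides) {
  counts <- table(peptides)
  df <- data.frame(peptide = names(counts), count = as.integer(counts),
                   stringsAsFactors = FALSE)
  df[order(-df$count, df$peptide), , drop = FALSE]
}

#' Simulate affinity-weighted selection rounds
#'
#' Starting from a peptide pool, performs \code{config$n_rounds} rounds of
#' selection: each round draws \code{config$n_reads} reads multinomially
#' with probability proportional to \code{count * fitness}, where fitness
#' comes from \code{\link{binder_fitness}}. Resampling itself supplies the
#' amplification noise. With zero rounds the pool is returned unchanged.
#'
#' @param pool data.frame with \code{peptide} and \code{count} (e.g. from
#'   \code{\link{simulate_naive_library}}).
#' @param model a \code{\link{binder_model}}.
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{rounds}, a list of pools (one per round,
#'   \code{rounds[[r]]} after round r), and \code{final}, the last pool
#'   (the input pool when \code{n_rounds = 0}).
#' @export
simulate_selection <- function(pool, model, config = sim_config()) {
  stopifnot(all(c("peptide", "count") %in% names(pool)))
  .maybe_seed(config$seed)
  rounds <- vector("list", config$n_rounds)
  current <- pool
  if (config$n_rounds > 0L) {
    for (r in seq_len(config$n_rounds)) {
      w <- current$count * binder_fitness(current$peptide, model)
      if (all(w == 0)) stop("degenerate selection: all survival weights zero")
      draw <- as.vector(rmultinom(1, config$n_reads, prob = w))
      keep <- draw > 0L
      current <- data.frame(peptide = current$peptide[keep],
                            count = draw[keep], stringsAsFactors = FALSE)
      current <- current[order(-current$count, current$peptide), , drop = FALSE]
      rownames(current) <- NULL
      rounds[[r]] <- current
    }
  }
  list(rounds = rounds, final = current)
}

#' Apply sequencing errors to reads
#'
#' Substitutes bases independently with probability \code{error_rate}
#' (uniformly among the three other bases) and introduces undetermined (N)
#' calls at rate \code{n_rate}. Erroneous and N bases are assigned lower
#' simulated qualities on average (mean 15 vs the profile mean), so most
#' but not all are caught by the Phred filter.
#'
#' @param bases character vector of reads.
#' @param quals list of integer quality vectors parallel to \code{bases},
#'   or an integer matrix (one column per read) for equal-length reads.
#' @param error_rate substitution probability per base, in [0, 0.2].
#' @param n_rate N probability per base.
#' @return list with mutated \code{bases}, \code{quals} (same shape as
#'   supplied) and \code{n_substitutions}, the number of substituted
#'   (non-N) bases.
#' @export
add_sequencing_errors <- function(bases, quals, error_rate, n_rate = 0) {
  stopifnot(error_rate >= 0, error_rate <= 0.2, n_rate >= 0, n_rate <= 1)
  if (error_rate == 0 && n_rate == 0)
    return(list(bases = bases, quals = quals, n_substitutions = 0L))
  as_matrix <- is.matrix(quals)
  nucs <- c("A", "C", "G", "T")
  L <- nchar(bases)
  n_err <- rbinom(length(bases), L, error_rate)
  n_n <- rbinom(length(bases), L, n_rate)
  n_sub <- sum(n_err)
  for (i in which(n_err + n_n > 0L)) {
    if (n_err[i] > 0L) {
      pos <- sample.int(L[i], n_err[i])
      for (p in pos) {
        alt <- setdiff(nucs, substr(bases[i], p, p))
        substr(bases[i], p, p) <- alt[sample.int(length(alt), 1L)]
      }
      lowq <- pmin(pmax(round(rnorm(n_err[i], 15, 5)), 2L), 40L)
      if (as_matrix) quals[pos, i] <- lowq else quals[[i]][pos] <- lowq
    }
    if (n_n[i] > 0L) {
      pos <- sample.int(L[i], n_n[i])
      for (p in pos) substr(bases[i], p, p) <- "N"
      lowq <- pmin(pmax(round(rnorm(n_n[i], 15, 5)), 2L), 40L)
      if (as_matrix) quals[pos, i] <- lowq else quals[[i]][pos] <- lowq
    }
  }
  list(bases = bases, quals = quals, n_substitutions = n_sub)
}

#' Render peptides to a FASTQ file
#'
#' For each peptide, builds construct DNA (forward primer, coding sequence
#' with codons sampled among those permitted by the design, reverse-primer
#' site), applies sequencing errors and N calls, draws clamped Gaussian
#' Phred qualities, reverse-complements an \code{antisense_fraction} of
#' reads, and writes Phred+33 FASTQ (gzipped if the path ends in
#' \code{.gz}).
#'
#' @param peptides one peptide per read.
#' @param template a \code{\link{scaffold_template}}.
#' @param config a \code{\link{sim_config}} (\code{seed} is ignored here;
#'   seeding belongs to the calling simulator).
#' @param design codon design.
#' @param path output FASTQ path.
#' @param id_prefix read-name prefix.
#' @return invisibly, \code{path}.
#' @export
write_reads_fastq <- function(peptides, template, config = sim_config(),
                              design = codon_design(), path,
                              id_prefix = "simread") {
  n <- length(peptides)
  bases <- .assemble_constructs(peptides, template, design)
  L <- nchar(bases[1])
  qmat <- matrix(as.integer(
    pmin(pmax(round(rnorm(L * n, config$qual_mean, config$qual_sd)), 2L), 40L)),
    nrow = L)
  err <- add_sequencing_errors(bases, qmat, config$error_rate, config$n_rate)
  bases <- err$bases; qmat <- err$quals
  flip <- runif(n) < config$antisense_fraction
  if (any(flip)) {
    bases[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(bases[flip])))
    qmat[, flip] <- qmat[L:1, flip]
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  ids <- sprintf("@%s_%06d", id_prefix, seq_len(n))
  qchar <- strsplit(intToUtf8(seq(2L, 40L) + 33L), "")[[1]]
  qstr <- do.call(paste0, lapply(seq_len(L), function(i)
    qchar[qmat[i, ] - 1L]))
  writeLines(as.vector(rbind(ids, bases, "+", qstr)), con)
  invisible(path)
}

# Vectorized construct assembly: constant-region DNA is built once from the
# template; per-read variable codons are sampled among those permitted.
.assemble_constructs <- function(peptides, template,
                                 design = codon_design(),
                                 primers = DEFAULT_PRIMERS) {
  k <- length(template$randomized_positions)
  if (any(nchar(peptides) != k))
    stop("peptides must match the template's randomized positions in length")
  chars <- strsplit(template$constant_sequence, "")[[1]]
  chmat <- matrix(unlist(strsplit(peptides, "")), nrow = k)
  pieces <- list()
  acc <- primers$fwd
  vslot <- 0L
  for (i in seq_along(chars)) {
    if (i %in% template$randomized_positions) {
      vslot <- vslot + 1L
      pieces <- c(pieces, list(acc), list(.sample_codons(chmat[vslot, ],
                                                         design)))
      acc <- ""
    } else {
      acc <- paste0(acc, reverse_translate(chars[i], design))
    }
  }
  pieces <- c(pieces, list(paste0(acc, revcomp(primers$rev))))
  do.call(paste0, pieces)
}

# Uniform codon choice per residue, vectorized over a letter vector.
.sample_codons <- function(letters, design) {
  out <- character(length(letters))
  for (aa in unique(letters)) {
    cs <- design$codons[[aa]]
    if (is.null(cs))
      stop("no codon available for residue: ", aa)
    idx <- which(letters == aa)
    out[idx] <- if (length(cs) == 1L) cs
                else cs[sample.int(length(cs), length(idx), replace = TRUE)]
  }
  out
}

#' Run a complete synthetic panning experiment
#'
#' Naive library, \code{n_rounds} of affinity-weighted selection, FASTQ
#' rendering of every round's reads, and a ground-truth TSV (peptide, true
#' fitness) for downstream assertions. All randomness flows from
#' \code{config$seed}: equal configurations give byte-identical output.
#'
#' @param template a \code{\link{scaffold_template}}.
#' @param model a \code{\link{binder_model}}.
#' @param config a \code{\link{sim_config}}.
#' @param out_dir directory for FASTQ/TSV output; \code{NULL} keeps
#'   everything in memory.
#' @param design codon design.
#' @return list with \code{naive} (pool), \code{rounds} (list of pools),
#'   \code{final}, \code{fastq_paths}, \code{truth_path}.
#' @export
simulate_panning <- function(template, model = binder_model_loop_default(),
                             config = sim_config(), out_dir = NULL,
                             design = codon_design()) {
  .maybe_seed(config$seed)
  inner <- config; inner$seed <- NULL
  naive <- simulate_naive_library(template, inner, design)
  sel <- simulate_selection(naive$pool, model, inner)
  fastq_paths <- character(0)
  truth_path <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    pools <- c(list(naive$pool), sel$rounds)
    labels <- c("round0", if (config$n_rounds > 0)
      paste0("round", seq_len(config$n_rounds)))
    fastq_paths <- vapply(seq_along(pools), function(k) {
      reads <- rep(pools[[k]]$peptide, pools[[k]]$count)
      p <- file.path(out_dir, paste0(labels[k], ".fastq.gz"))
      write_reads_fastq(reads, template, inner, design, p,
                        id_prefix = labels[k])
      p
    }, character(1))
    names(fastq_paths) <- labels
    truth <- data.frame(peptide = sel$final$peptide,
                        count = sel$final$count,
                        fitness = binder_fitness(sel$final$peptide, model))
    truth_path <- file.path(out_dir, "ground_truth.tsv")
    write.table(truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(naive = naive$pool, rounds = sel$rounds, final = sel$final,
       fastq_paths = fastq_paths, truth_path = truth_path)
}
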