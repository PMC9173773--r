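# The simulator is first-class code: these tests pin its statistical
# behaviour, not just its plumbing.

test_that("naive libraries are uniform and round-trip losslessly at zero error", {
  cfg <- sim_config(n_reads = 1000, error_rate = 0, n_rate = 0,
                    antisense_fraction = 0, qual_sd = 2, seed = 101)
  path <- tempfile(fileext = ".fastq.gz")
  nav <- simulate_naive_library(loop_tpl, cfg, fastq = path)
  res <- run_qc(path, loop_tpl)
  expect_equal(res$report$retention, 1.0)
  expect_identical(res$peptides$peptide, nav$peptides)
  # letters approximately uniform across all positions pooled
  freqs <- table(factor(unlist(strsplit(nav$peptides, "")),
                        levels = AA_NO_CYS)) / (1000 * 7)
  expect_lt(max(abs(freqs - 1 / 19)), 4 * sqrt((1 / 19) / (1000 * 7)))
})

test_that("unique-read fraction matches the analytic expectation", {
  # P(read unique) = (1 - 1/N)^(n-1) under uniform sampling of N variants
  cfg <- sim_config(n_reads = 10000, seed = 102)
  nav <- simulate_naive_library(loop_tpl, cfg)
  tab <- count_variants(nav$peptides)
  qc <- library_qc(tab)
  N <- 19^7; n <- cfg$n_reads
  expected <- (1 - 1 / N)^(n - 1)
  tol <- 3 * sqrt(expected * (1 - expected) / n) + 1e-4
  expect_lt(abs(qc$unique_read_fraction - expected), tol)
})

test_that("equal seeds give byte-identical FASTQ output", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  cfg <- sim_config(n_reads = 500, n_rounds = 1, seed = 103)
  r1 <- simulate_panning(loop_tpl, config = cfg, out_dir = d1)
  r2 <- simulate_panning(loop_tpl, config = cfg, out_dir = d2)
  for (k in seq_along(r1$fastq_paths)) {
    expect_identical(readLines(gzfile(r1$fastq_paths[k])),
                     readLines(gzfile(r2$fastq_paths[k])))
  }
  expect_identical(r1$final, r2$final)
})

test_that("zero selection rounds leave the pool untouched", {
  set.seed(104)
  pool <- pool_from_counts <- data.frame(
    peptide = random_peptides(20, 7), count = rep(5L, 20))
  sel <- simulate_selection(pool, binder_model_loop_default(),
                            sim_config(n_rounds = 0))
  expect_identical(sel$final, pool)
  expect_length(sel$rounds, 0L)
})

test_that("a strong motif family enriches monotonically across rounds", {
  model <- binder_model_loop_default()
  top1 <- matrix(NA_real_, nrow = 10, ncol = 4)
  for (s in 1:10) {
    cfg <- sim_config(n_reads = 5000, n_rounds = 3, seed = 200 + s)
    res <- simulate_panning(loop_tpl, model, cfg)
    pools <- c(list(res$naive), res$rounds)
    top1[s, ] <- vapply(pools, function(p) max(p$count) / sum(p$count),
                        numeric(1))
  }
  means <- colMeans(top1)
  expect_true(all(diff(means) > 0))
})

test_that("two families enrich at the replicator-equation ratio", {
  # deterministic fitnesses wA = 2 wB: after r rounds the read-share ratio
  # is the initial ratio times (wA/wB)^r
  pwmA <- matrix(0, 7, 19, dimnames = list(NULL, AA_NO_CYS))
  pwmA[, "A"] <- 1  # motif score = number of A residues
  modelAB <- binder_model(list(list(pwm = pwmA, weight = 1)),
                          background = 0, stringency = log(2))
  # two peptides whose fitnesses differ exactly twofold (scores 7 vs 6)
  pool <- data.frame(peptide = c("AAAAAAA", "GAAAAAA"),
                     count = c(1000L, 1000L))
  wa <- binder_fitness(pool$peptide, modelAB)
  expect_equal(wa[1] / wa[2], 2)
  ratio_fit <- wa[1] / wa[2]
  set.seed(105)
  sel <- simulate_selection(pool, modelAB,
                            sim_config(n_reads = 2e5, n_rounds = 3))
  counts <- setNames(sel$final$count, sel$final$peptide)
  observed <- counts[["AAAAAAA"]] / counts[["GAAAAAA"]]
  expected <- ratio_fit^3
  # multinomial noise on the minority count dominates; allow 4 relative sd
  sd_rel <- 4 / sqrt(min(counts))
  expect_lt(abs(log(observed / expected)), sd_rel + log(1.1))
})

test_that("sequencing errors follow the requested rates", {
  expect_identical(add_sequencing_errors("ACGT", list(rep(35L, 4)), 0, 0),
                   list(bases = "ACGT", quals = list(rep(35L, 4)),
                        n_substitutions = 0L))
  set.seed(106)
  bases <- vapply(1:1000, function(i)
    paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""),
    character(1))
  quals <- replicate(1000, rep(35L, 100), simplify = FALSE)
  out <- add_sequencing_errors(bases, quals, 0.01)
  n_bases <- 1000 * 100
  expect_lt(abs(out$n_substitutions - n_bases * 0.01),
            3 * sqrt(n_bases * 0.01 * 0.99))
  # substituted bases really differ
  diff_count <- sum(mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
    bases[1:50], out$bases[1:50]))
  expect_gt(diff_count, 0)

  # N calls surface as contains_N fates downstream
  cfgN <- sim_config(n_reads = 200, error_rate = 0, n_rate = 0.01,
                     qual_sd = 2, seed = 107)
  path <- tempfile(fileext = ".fastq")
  nav <- simulate_naive_library(loop_tpl, cfgN, fastq = path)
  rep_n <- run_qc(path, loop_tpl)$report
  expect_gt(rep_n$counts$contains_N, 0L)
  expect_error(add_sequencing_errors("ACGT", list(rep(35L, 4)), 0.5),
               "error_rate")
})

test_that("a planted binder ranks first after selection", {
  cfg <- sim_config(n_reads = 50000, seed = 108)
  res <- simulate_panning(loop_tpl, binder_model_loop_default(), cfg)
  tab <- count_variants(rep(res$final$peptide, res$final$count))
  model <- binder_model_loop_default()
  fit_top <- binder_fitness(tab$peptide[1], model)
  fit_med <- median(binder_fitness(tab$peptide, model))
  expect_gt(fit_top, fit_med)  # the winner is a genuine high-fitness binder
  expect_gt(selection_summary(tab)$top_freq_percent, 0.5)
})
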