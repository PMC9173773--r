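times_6h <- seq(0, 6, length.out = 200)

test_that("no nucleation source means no fibril mass", {
  p <- kinetic_params(k_n = 0, seed_mass_fraction = 0)
  tr <- simulate_trace(p, times_6h)
  expect_equal(max(tr$signal), 0)
})

test_that("elongation-only kinetics match the closed-form solution", {
  # with k_n = k_2 = 0 and seeds P0: m(t) = m0 exp(-2 k+ P0 t)
  p <- kinetic_params(k_n = 0, k_2 = 0, m0 = 3, seed_mass_fraction = 0.3)
  tt <- seq(0, 0.2, length.out = 100)
  mom <- attr(simulate_trace(p, tt), "moments")
  m_exact <- p$m0 * exp(-2 * p$k_plus * p$seed_number_conc * tt)
  expect_lt(max(abs(mom[, "m"] - m_exact)), 1e-4 * p$m0)
  # no lag phase: signal strictly increasing from the start
  expect_gt(mom[2, "M"], mom[1, "M"])
})

test_that("secondary-dominated half-times scale as m0^(-(n2+1)/2)", {
  p <- function(m0) kinetic_params(k_n = 1e-12, m0 = m0)
  grid <- function(m0) seq(0, 80, length.out = 4000)
  t50a <- halftime(simulate_trace(p(2), grid(2)))
  t50b <- halftime(simulate_trace(p(4), grid(4)))
  gamma <- log(t50b / t50a) / log(2)
  expect_lt(abs(gamma - (-1.5)) / 1.5, 0.05)
})

test_that("halftime interpolates the first upward crossing", {
  step <- tht_trace(c(0, 9.999, 10, 20), c(0, 0, 1, 1))
  expect_equal(halftime(step), 10, tolerance = 1e-3)

  p <- kinetic_params()
  coarse <- simulate_trace(p, seq(0, 6, length.out = 60))
  dense <- simulate_trace(p, seq(0, 6, length.out = 6000))
  # brute-force dense-grid crossing as oracle
  oracle <- dense$times[which(dense$signal >= 0.5)[1]]
  expect_equal(halftime(coarse), oracle, tolerance = 6 / 60)

  flat <- tht_trace(c(0, 1, 2), c(0.3, 0.2, 0.1))
  expect_error(halftime(flat), "never crosses")
})

test_that("mass is conserved and fibril mass is monotone under fuzzing", {
  set.seed(41)
  for (i in 1:10) {
    p <- kinetic_params(k_n = 10^runif(1, -9, -5),
                        k_2 = 10^runif(1, -6, -4),
                        k_plus = 10^runif(1, 3.5, 4.5),
                        m0 = runif(1, 1, 5),
                        seed_mass_fraction = sample(c(0, 0.01, 0.3), 1))
    tr <- simulate_trace(p, seq(0, 10, length.out = 300))
    mom <- attr(tr, "moments")
    total <- p$m0 + p$seed_mass
    expect_lt(max(abs(mom[, "m"] + mom[, "M"] - total)), 1e-6 * total)
    expect_true(all(diff(mom[, "M"]) > -1e-9))
    expect_true(all(diff(mom[, "P"]) > -1e-12))
  }
})

test_that("aggregation completes whenever a nucleation source or seed exists", {
  long <- seq(0, 50, length.out = 500)
  for (p in list(kinetic_params(),                      # primary + secondary
                 kinetic_params(k_n = 0, seed_mass_fraction = 0.01),
                 kinetic_params(k_2 = 0, seed_mass_fraction = 0.3))) {
    tr <- simulate_trace(p, long)
    expect_gt(tr$signal[length(long)], 0.99)
  }
})

test_that("fit_inhibition recovers planted secondary-nucleation factors", {
  set.seed(42)
  p <- kinetic_params()
  tt <- seq(0.05, 6, length.out = 80)
  traces <- simulate_inhibition_dataset(p, "secondary", c(0, 1, 3),
                                        c(1, 0.5, 0.2), tt, noise_sd = 0.01)
  fit <- fit_inhibition(traces, "secondary", params0 = kinetic_params())
  expect_equal(unname(fit$factors[1]), 1)
  expect_lt(abs(fit$factors[["1"]] - 0.5) / 0.5, 0.15)
  expect_lt(abs(fit$factors[["3"]] - 0.2) / 0.2, 0.15)
  expect_lt(fit$mean_residual_error, 0.02)
})

test_that("fit_inhibition validates its inputs", {
  p <- kinetic_params()
  tt <- seq(0.05, 6, length.out = 40)
  only0 <- simulate_inhibition_dataset(p, "secondary", 0, 1, tt)
  expect_error(fit_inhibition(only0, "secondary"), "two or more")
  no_ref <- simulate_inhibition_dataset(p, "secondary", c(1, 3), c(0.5, 0.2),
                                        tt)
  expect_error(fit_inhibition(no_ref, "secondary"), "zero-inhibitor")
})

test_that("null data yield factors near one in every mode", {
  set.seed(43)
  p <- kinetic_params()
  tt <- seq(0.05, 6, length.out = 60)
  traces <- simulate_inhibition_dataset(p, "secondary", c(0, 3), c(1, 1), tt)
  for (mode in INHIBITION_MODES) {
    fit <- fit_inhibition(traces, mode, params0 = p, n_starts = 1)
    expect_gt(fit$factors[["3"]], 0.9)
  }
})

test_that("select_mode identifies the generating inhibition mode", {
  set.seed(44)
  p <- kinetic_params()
  tt <- seq(0.05, 6, length.out = 60)
  traces <- simulate_inhibition_dataset(p, "secondary", c(0, 1, 3),
                                        c(1, 0.5, 0.2), tt, noise_sd = 0.01)
  ranking <- select_mode(traces, params0 = p, n_starts = 2)
  expect_identical(ranking$mode[1], "secondary")
  expect_true(all(diff(ranking$mean_residual_error) >= 0))
})

test_that("seeded assays separate secondary nucleation from elongation", {
  p <- kinetic_params(m0 = 2)
  low <- simulate_seeded_assay(p, 0.01, list(mode = "secondary", factor = 0.1))
  expect_gt(halftime(low$inhibited) / halftime(low$control), 1.2)

  high <- simulate_seeded_assay(p, 0.30, list(mode = "secondary", factor = 0.1))
  expect_lt(abs(halftime(high$inhibited) / halftime(high$control) - 1), 0.05)

  none <- simulate_seeded_assay(p, 0.01, list(mode = "secondary", factor = 1))
  expect_identical(none$control$signal, none$inhibited$signal)
})

test_that("trace CSVs round-trip and raw traces are normalized", {
  p <- kinetic_params()
  traces <- simulate_inhibition_dataset(p, "primary", c(0, 2), c(1, 0.3),
                                        seq(0, 6, length.out = 50))
  path <- tempfile(fileext = ".csv")
  write_tht_traces(traces, path)
  back <- read_tht_traces(path)
  expect_length(back, 2L)
  concs <- sort(vapply(back, `[[`, numeric(1), "inhibitor_conc"))
  expect_equal(concs, c(0, 2))
  sig0 <- traces[[1]]$signal
  back0 <- back[[which(vapply(back, `[[`, numeric(1), "inhibitor_conc") == 0)]]
  expect_equal(back0$signal, sig0, tolerance = 1e-8)

  raw <- tht_trace(0:10, 5 + 90 * c(0, 0, 0.1, 0.3, 0.6, 0.9, 1, 1, 1, 1, 1),
                   normalized = FALSE)
  expect_equal(range(raw$signal), c(0, 1))
  expect_error(tht_trace(c(0, 1), c(0, 2)), "outside")
  expect_error(tht_trace(c(1, 0), c(0, 1)), "increasing")
})
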