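# Amyloid aggregation kinetics: two-moment model, selective-inhibition
# fitting and model selection.

#' Rate parameters for the two-moment aggregation model
#'
#' The model tracks fibril number P and fibril mass M:
#' \deqn{dP/dt = k_n m^{n_c} + k_2 m^{n_2} M, \quad dM/dt = 2 k_+ m P,}
#' with free monomer \eqn{m} consumed by elongation. \eqn{k_n} is the
#' primary nucleation rate constant, \eqn{k_2} secondary nucleation (new
#' aggregates formed from monomer on the fibril surface), \eqn{k_+}
#' elongation. Concentrations in uM, time in hours; \eqn{k_n} then has
#' units uM^(1 - n_c) / h, \eqn{k_2} uM^(-n_2) / h and \eqn{k_+} 1/(uM h).
#'
#' Defaults are typical of recombinant amyloid-beta 42 at low-micromolar
#' concentration and neutral-to-basic pH (half-times of one to two hours at
#' 3 uM): \code{k_plus = 1.08e4} (3e6 /M/s), \code{k_n = 3.6e-7} (1e-4
#' /M/s), \code{k_2 = 3.6e-5} (1e4 /M^2/s), reaction orders
#' \code{n_c = n_2 = 2}.
#'
#' Seeds are specified by their mass as a fraction of \code{m0}; the seed
#' number concentration is derived from an assumed mean seed length
#' (monomer units per preformed fibril, default 500, typical of sonicated
#' seed preparations), or can be given directly.
#'
#' @param k_n,k_2,k_plus rate constants (>= 0).
#' @param n_c,n_2 reaction orders (>= 1).
#' @param m0 initial free monomer concentration (uM).
#' @param seed_mass_fraction initial fibril mass as a fraction of
#'   \code{m0}, in [0, 1].
#' @param mean_seed_length average monomers per seed fibril.
#' @param seed_number_conc explicit seed number concentration (uM);
#'   overrides \code{mean_seed_length}.
#' @return object of class \code{kinetic_params}.
#' @export
kinetic_params <- function(k_n = 3.6e-7, k_2 = 3.6e-5, k_plus = 1.08e4,
                           n_c = 2, n_2 = 2, m0 = 3,
                           seed_mass_fraction = 0, mean_seed_length = 500,
                           seed_number_conc = NULL) {
  stopifnot(k_n >= 0, k_2 >= 0, k_plus >= 0, n_c >= 1, n_2 >= 1, m0 > 0,
            seed_mass_fraction >= 0, seed_mass_fraction <= 1)
  M0 <- seed_mass_fraction * m0
  P0 <- if (!is.null(seed_number_conc)) seed_number_conc
        else M0 / mean_seed_length
  structure(list(k_n = k_n, k_2 = k_2, k_plus = k_plus, n_c = n_c,
                 n_2 = n_2, m0 = m0,
                 seed_mass_fraction = seed_mass_fraction,
                 seed_mass = M0, seed_number_conc = P0),
            class = "kinetic_params")
}

#' A ThT-style kinetic trace
#'
#' @param times hours, strictly increasing.
#' @param signal normalized fibril mass in [0, 1] (5\% noise tolerance on
#'   either side), or raw fluorescence with \code{normalized = FALSE}.
#' @param m0 monomer concentration label (uM).
#' @param inhibitor_conc inhibitor concentration label (uM).
#' @param seed_fraction seed mass fraction label.
#' @param normalized whether \code{signal} is already normalized fibril
#'   mass; raw traces are mapped to [0, 1] by an affine baseline/plateau
#'   transform on construction.
#' @return object of class \code{tht_trace}.
#' @export
tht_trace <- function(times, signal, m0 = NA_real_, inhibitor_conc = 0,
                      seed_fraction = 0, normalized = TRUE) {
  stopifnot(length(times) == length(signal), length(times) >= 2)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!normalized) {
    base <- min(signal); plateau <- max(signal)
    if (plateau <= base) stop("cannot normalize a flat trace")
    signal <- (signal - base) / (plateau - base)
  } else if (any(signal < -0.05) || any(signal > 1.05)) {
    stop("normalized signal outside [-0.05, 1.05]")
  }
  structure(list(times = as.numeric(times), signal = as.numeric(signal),
                 m0 = m0, inhibitor_conc = inhibitor_conc,
                 seed_fraction = seed_fraction),
            class = "tht_trace")
}

# Raw moment solution at the requested times.
.moments <- function(params, times, n_steps = 4000L) {
  r <- .integrate_moments(times, params$k_n, params$k_2, params$k_plus,
                          params$n_c, params$n_2, params$m0,
                          params$seed_mass, params$seed_number_conc,
                          as.integer(n_steps))
  total <- params$m0 + params$seed_mass
  drift <- max(abs(r[, "M"] + r[, "m"] - total))
  if (!is.finite(drift) || drift > 1e-6 * total)
    stop(sprintf("integrator failure: mass conservation drift %.3g (total %.3g); increase n_steps", drift, total))
  r
}

#' Simulate a normalized aggregation trace
#'
#' Integrates the two-moment model (classical fourth-order Runge-Kutta,
#' \code{n_steps} uniform steps to the last requested time) and returns the
#' fibril mass normalized by the total aggregateable material
#' \code{m0 + seed mass}. Mass conservation is verified at the output
#' points to within 1e-6 of the total; a violation raises an error rather
#' than returning a corrupted trace.
#'
#' @param params a \code{\link{kinetic_params}}.
#' @param times output times (h), increasing.
#' @param n_steps integration steps (default 4000).
#' @return a \code{\link{tht_trace}} with attribute \code{moments}, the
#'   raw (P, M, m) matrix.
#' @export
simulate_trace <- function(params, times, n_steps = 4000L) {
  r <- .moments(params, times, n_steps)
  total <- params$m0 + params$seed_mass
  tr <- tht_trace(times, pmin(r[, "M"] / total, 1), m0 = params$m0,
                  seed_fraction = params$seed_mass_fraction)
  attr(tr, "moments") <- r
  tr
}

#' Half-time of a sigmoidal trace
#'
#' Time of the first upward crossing of half-plateau (0.5 for normalized
#' traces), by linear interpolation between the bracketing points.
#'
#' @param trace a \code{\link{tht_trace}} (or list with \code{times} and
#'   \code{signal}).
#' @param level crossing level, default 0.5.
#' @return t50 in hours.
#' @export
halftime <- function(trace, level = 0.5) {
  s <- trace$signal; t <- trace$times
  above <- s >= level
  if (above[1]) return(t[1])
  k <- which(!above[-length(s)] & above[-1])
  if (length(k) == 0L)
    stop("trace never crosses the half-plateau level")
  k <- k[1]
  t[k] + (level - s[k]) * (t[k + 1] - t[k]) / (s[k + 1] - s[k])
}

# Apply a selective multiplicative reduction to one rate constant.
.apply_factor <- function(params, mode, factor) {
  field <- switch(mode, primary = "k_n", secondary = "k_2",
                  elongation = "k_plus",
                  stop("unknown inhibition mode: ", mode))
  params[[field]] <- params[[field]] * factor
  params
}

#' Kinetic inhibition modes
#' @export
INHIBITION_MODES <- c("primary", "secondary", "elongation")

#' Simulate a dataset of traces under selective inhibition
#'
#' Convenience generator for fitting studies: one trace per inhibitor
#' concentration, the mode's rate constant multiplied by the matching
#' factor, plus optional i.i.d. Gaussian noise on the normalized signal.
#'
#' @param params zero-inhibitor \code{\link{kinetic_params}}.
#' @param mode one of \code{"primary"}, \code{"secondary"},
#'   \code{"elongation"}.
#' @param inhibitor_concs concentrations (first is usually 0).
#' @param factors multiplicative reduction per concentration (1 for zero
#'   inhibitor).
#' @param times output times (h).
#' @param noise_sd Gaussian noise sd on the normalized signal.
#' @return list of \code{\link{tht_trace}} objects.
#' @export
simulate_inhibition_dataset <- function(params, mode, inhibitor_concs,
                                        factors, times, noise_sd = 0) {
  stopifnot(length(inhibitor_concs) == length(factors))
  lapply(seq_along(factors), function(i) {
    p <- .apply_factor(params, mode, factors[i])
    tr <- simulate_trace(p, times)
    if (noise_sd > 0)
      tr$signal <- pmin(pmax(tr$signal + rnorm(length(times), 0, noise_sd),
                             -0.05), 1.05)
    tr$inhibitor_conc <- inhibitor_concs[i]
    tr
  })
}

# Residual objective shared by the three fitting modes. Free parameters:
# log10 k_n, log10 k_2 and, per nonzero inhibitor concentration, a logit
# factor in (0, 1). k_plus is held fixed: normalized unseeded traces only
# constrain the products k_plus*k_n and k_plus*k_2, so one constant must be
# anchored (see the methods vignette); the per-concentration factors are
# identifiable regardless of the anchoring.
.fit_objective <- function(par, traces, mode, base, nz_idx) {
  kn <- 10^par[1]; k2 <- 10^par[2]
  factors <- rep(1, length(traces))
  if (length(nz_idx))
    factors[nz_idx] <- stats::plogis(par[-(1:2)])
  sse <- 0
  for (i in seq_along(traces)) {
    p <- base
    p$k_n <- kn; p$k_2 <- k2
    p <- .apply_factor(p, mode, factors[i])
    pred <- tryCatch(simulate_trace(p, traces[[i]]$times)$signal,
                     error = function(e) NULL)
    if (is.null(pred)) return(1e6)
    sse <- sse + sum((pred - traces[[i]]$signal)^2)
  }
  sse
}

.trace_mre <- function(par, traces, mode, base, nz_idx) {
  kn <- 10^par[1]; k2 <- 10^par[2]
  factors <- rep(1, length(traces))
  if (length(nz_idx)) factors[nz_idx] <- stats::plogis(par[-(1:2)])
  rms <- vapply(seq_along(traces), function(i) {
    p <- base
    p$k_n <- kn; p$k_2 <- k2
    p <- .apply_factor(p, mode, factors[i])
    pred <- simulate_trace(p, traces[[i]]$times)$signal
    sqrt(mean((pred - traces[[i]]$signal)^2))
  }, numeric(1))
  mean(rms)  # plateau of a normalized trace is 1
}

#' Global fit of traces under one selective-inhibition hypothesis
#'
#' Least-squares fit of all traces simultaneously: the rate constants are
#' shared across traces and only the rate constant selected by \code{mode}
#' is multiplied by a free factor in (0, 1] for each nonzero inhibitor
#' concentration (the zero-inhibitor factor is fixed at 1). The elongation
#' rate constant is anchored at its \code{params0} value because
#' normalized traces determine only the products \eqn{k_+ k_n} and
#' \eqn{k_+ k_2}; under \code{mode = "elongation"} the per-concentration
#' factor still multiplies \eqn{k_+}, rescaling both products, and remains
#' identifiable.
#'
#' Optimisation is Nelder-Mead from a small deterministic multi-start grid
#' of log-spaced rate-constant initialisations.
#'
#' @param traces list of \code{\link{tht_trace}} over inhibitor
#'   concentrations, sharing monomer and seed conditions, including a
#'   zero-inhibitor trace; at least two concentrations.
#' @param mode \code{"primary"}, \code{"secondary"} or \code{"elongation"}.
#' @param params0 starting \code{\link{kinetic_params}} (also supplies
#'   m0, orders, seed state and the anchored \eqn{k_+}).
#' @param n_starts number of multi-start initialisations (1--3).
#' @param maxit Nelder-Mead iteration cap per start.
#' @return object of class \code{inhibition_fit}: list with \code{mode},
#'   \code{params} (fitted \code{kinetic_params}), \code{factors} (named by
#'   inhibitor concentration, 1 for zero inhibitor),
#'   \code{mean_residual_error} (mean over traces of the RMS residual of
#'   the normalized signal) and \code{converged}.
#' @export
fit_inhibition <- function(traces, mode = INHIBITION_MODES,
                           params0 = kinetic_params(), n_starts = 3L,
                           maxit = 400L) {
  mode <- match.arg(mode)
  concs <- vapply(traces, `[[`, numeric(1), "inhibitor_conc")
  if (length(unique(concs)) < 2L)
    stop("need traces at two or more inhibitor concentrations")
  if (!any(concs == 0))
    stop("a zero-inhibitor reference trace is required")
  nz_idx <- which(concs != 0)
  base <- params0
  starts <- list(c(0, 0), c(-1, 1), c(1, -1))[seq_len(max(1, min(n_starts, 3)))]
  best <- NULL
  for (s in starts) {
    par0 <- c(log10(params0$k_n) + s[1], log10(params0$k_2) + s[2],
              rep(0, length(nz_idx)))  # plogis(0) = 0.5
    fit <- optim(par0, .fit_objective, traces = traces, mode = mode,
                 base = base, nz_idx = nz_idx, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  factors <- rep(1, length(traces))
  if (length(nz_idx)) factors[nz_idx] <- stats::plogis(best$par[-(1:2)])
  fitted <- base
  fitted$k_n <- 10^best$par[1]
  fitted$k_2 <- 10^best$par[2]
  mre <- .trace_mre(best$par, traces, mode, base, nz_idx)
  structure(list(mode = mode, params = fitted,
                 factors = setNames(factors, concs),
                 mean_residual_error = mre,
                 converged = best$convergence == 0L),
            class = "inhibition_fit")
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat(sprintf("inhibition fit, mode = %s: MRE %.4g%s\n", x$mode,
              x$mean_residual_error,
              if (x$converged) "" else " (not converged)"))
  cat("  factors:", paste(sprintf("%s uM -> %.3f", names(x$factors),
                                  x$factors), collapse = ", "), "\n")
  invisible(x)
}

#' Rank inhibition modes by goodness of fit
#'
#' Fits the trace set three times, assuming a selective reduction of the
#' rate constant for primary nucleation, secondary nucleation and
#' elongation respectively, and ranks the three hypotheses by mean
#' residual error. The top-ranked mode is the best-supported microscopic
#' target of the inhibitor.
#'
#' @inheritParams fit_inhibition
#' @return data.frame with columns \code{mode} and
#'   \code{mean_residual_error}, sorted ascending, with attribute
#'   \code{fits} holding the three \code{inhibition_fit} objects.
#' @export
select_mode <- function(traces, params0 = kinetic_params(), n_starts = 3L,
                        maxit = 400L) {
  fits <- lapply(INHIBITION_MODES, function(m)
    fit_inhibition(traces, m, params0, n_starts = n_starts, maxit = maxit))
  names(fits) <- INHIBITION_MODES
  mres <- vapply(fits, `[[`, numeric(1), "mean_residual_error")
  out <- data.frame(mode = INHIBITION_MODES,
                    mean_residual_error = unname(mres))
  out <- out[order(out$mean_residual_error), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Simulate a matched seeded assay with and without inhibitor
#'
#' Seeded experiments discriminate inhibition modes experimentally: at low
#' seed (~1\%) primary nucleation is bypassed and secondary nucleation
#' dominates, so a secondary-nucleation inhibitor delays the reaction
#' strongly; at high seed (~30\%) elongation of the supplied seeds
#' dominates and the same inhibitor has almost no effect.
#'
#' @param params unseeded \code{\link{kinetic_params}} (its seed fields are
#'   overridden).
#' @param seed_fraction seed mass fraction (e.g. 0.01 or 0.30).
#' @param inhibition list with \code{mode} and \code{factor}.
#' @param times output times (h); default a dense grid to five control
#'   half-time scales.
#' @param mean_seed_length monomers per seed fibril.
#' @return list with \code{control} and \code{inhibited}
#'   \code{\link{tht_trace}} objects.
#' @export
simulate_seeded_assay <- function(params, seed_fraction,
                                  inhibition = list(mode = "secondary",
                                                    factor = 0.1),
                                  times = NULL, mean_seed_length = 500) {
  p <- kinetic_params(k_n = params$k_n, k_2 = params$k_2,
                      k_plus = params$k_plus, n_c = params$n_c,
                      n_2 = params$n_2, m0 = params$m0,
                      seed_mass_fraction = seed_fraction,
                      mean_seed_length = mean_seed_length)
  if (is.null(times)) {
    probe <- simulate_trace(p, seq(0, 20, length.out = 400))
    t50 <- tryCatch(halftime(probe), error = function(e) 4)
    times <- seq(0, 5 * t50, length.out = 400)
  }
  control <- simulate_trace(p, times)
  inhibited <- simulate_trace(.apply_factor(p, inhibition$mode,
                                            inhibition$factor), times)
  inhibited$inhibitor_conc <- NA_real_
  list(control = control, inhibited = inhibited)
}

#' Read kinetic traces from CSV
#'
#' Expected columns: \code{time_h}, \code{signal}, \code{monomer_uM},
#' \code{inhibitor_uM}, \code{seed_fraction}. Rows are grouped into one
#' trace per (monomer, inhibitor, seed) combination.
#'
#' @param path CSV file.
#' @param normalized whether \code{signal} is already normalized fibril
#'   mass (raw traces are normalized per trace by baseline/plateau).
#' @return list of \code{\link{tht_trace}} objects.
#' @export
read_tht_traces <- function(path, normalized = TRUE) {
  df <- utils::read.csv(path)
  need <- c("time_h", "signal", "monomer_uM", "inhibitor_uM", "seed_fraction")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  key <- interaction(df$monomer_uM, df$inhibitor_uM, df$seed_fraction,
                     drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$time_h), ]
    tht_trace(g$time_h, g$signal, m0 = g$monomer_uM[1],
              inhibitor_conc = g$inhibitor_uM[1],
              seed_fraction = g$seed_fraction[1], normalized = normalized)
  }) |> unname()
}

#' Write kinetic traces to CSV
#' @param traces list of \code{\link{tht_trace}} objects.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_tht_traces <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(time_h = tr$times, signal = tr$signal, monomer_uM = tr$m0,
               inhibitor_uM = tr$inhibitor_conc,
               seed_fraction = tr$seed_fraction)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
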