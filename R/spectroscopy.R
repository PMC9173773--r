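# Binding-readout arithmetic: FRET efficiency and size scaling.

#' FRET transfer efficiency from donor emission
#'
#' \eqn{E = (I_0 - I) / I_0}, where \eqn{I} is the background-subtracted
#' donor emission intensity (e.g. at 522 nm for an Alexa488 donor) and
#' \eqn{I_0} the intensity in the absence of transfer. Values below zero
#' (donor enhancement artifacts) are passed through but flagged with a
#' warning attribute rather than clipped.
#'
#' @param I donor emission intensity (>= 0); vectorised.
#' @param I0 donor emission in the absence of transfer (> 0); scalar or
#'   vector recycled against \code{I}.
#' @return efficiency value(s) in (-Inf, 1]; attribute
#'   \code{enhancement_flag} marks entries with E < 0.
#' @examples
#' fret_efficiency(72, 100)  # 0.28
#' @export
fret_efficiency <- function(I, I0) {
  if (any(I0 <= 0)) stop("I0 must be positive")
  if (any(I < 0)) stop("I must be non-negative")
  E <- (I0 - I) / I0
  if (any(E < 0)) {
    warning("negative transfer efficiency (donor enhancement?) passed through")
    attr(E, "enhancement_flag") <- E < 0
  }
  E
}

#' Apparent molecular-weight ratio from a hydrodynamic-radius ratio
#'
#' For globular species molecular weight scales with the cube of the
#' hydrodynamic radius, so a species whose apparent \eqn{R_h} is a factor
#' \code{rh_ratio} larger has an apparent molecular weight larger by
#' \code{rh_ratio^3} (a 3-fold radius increase implies ~27-fold mass).
#'
#' @param rh_ratio positive hydrodynamic-radius ratio; vectorised.
#' @return \code{rh_ratio^3}.
#' @examples
#' mw_ratio_from_rh(3)  # 27
#' @export
mw_ratio_from_rh <- function(rh_ratio) {
  if (any(rh_ratio <= 0)) stop("rh_ratio must be positive")
  rh_ratio^3
}

#' Upper bound on monomers per diffusing complex
#'
#' Converts an apparent molecular-weight ratio into a bound on the number
#' of target monomers per complex, given explicit component masses and the
#' number of labelled binder molecules assumed per complex: the reference
#' species is the free binder, so the complex mass is
#' \code{mw_ratio * binder_mass}, of which \code{n_binders * binder_mass}
#' is binder.
#'
#' @param mw_ratio apparent molecular-weight ratio (complex / free binder).
#' @param binder_mass molar mass of the binder (Da).
#' @param monomer_mass molar mass of the target monomer (Da).
#' @param n_binders binder molecules assumed per complex (>= 1).
#' @return maximum number of whole target monomers consistent with the
#'   inputs (floor of the mass balance; at least 0).
#' @export
max_monomers_per_complex <- function(mw_ratio, binder_mass, monomer_mass,
                                     n_binders = 1) {
  stopifnot(mw_ratio > 0, binder_mass > 0, monomer_mass > 0, n_binders >= 1)
  residual <- mw_ratio * binder_mass - n_binders * binder_mass
  max(floor(residual / monomer_mass), 0)
}

#' FRET efficiency table from a time-course CSV
#'
#' Reads columns \code{time}, \code{I}, \code{I0} and appends \code{E}.
#' @param path input CSV.
#' @param out optional output CSV path.
#' @return data.frame with added \code{E} column.
#' @export
fret_table <- function(path, out = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("I", "I0") %in% names(df)))
    stop("CSV must have columns I and I0")
  df$E <- as.numeric(fret_efficiency(df$I, df$I0))
  if (!is.null(out)) utils::write.csv(df, out, row.names = FALSE)
  df
}
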