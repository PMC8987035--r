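# Analytic electron-optics calculators for low-voltage imaging: relativistic
# electron parameters, the chromatic-aberration envelope and its effect on
# spectral SNR, radiation-damage fits against 1/beta^2, and the information
# coefficient.

# electron rest energy, eV; fixed so derived values reproduce bit-for-bit
.mc2_eV <- 510998.95

#' Relativistic electron wavelength
#'
#' `lambda = 12.2643 / sqrt(V * (1 + 0.978476e-6 * V))` Angstrom.
#'
#' @param V acceleration voltage in volts (> 0); vectorized.
#' @return Wavelength in Angstrom.
#' @export
wavelength <- function(V) {
  stopifnot(all(V > 0))
  12.2643 / sqrt(V * (1 + 0.978476e-6 * V))
}

#' Squared ratio of electron velocity to the speed of light
#'
#' `beta^2 = 1 - 1/gamma^2`, `gamma = 1 + eV / (m0 c^2)` with
#' `m0 c^2 = 510998.95 eV`.
#'
#' @param V acceleration voltage in volts (> 0); vectorized.
#' @export
beta2 <- function(V) {
  stopifnot(all(V > 0))
  g <- 1 + V / .mc2_eV
  1 - 1 / g^2
}

#' Optics parameters for the chromatic envelope
#'
#' @param V acceleration voltage, volts.
#' @param Cc chromatic aberration coefficient, mm.
#' @param dE energy spread (FWHM-like delta-E) of the source, eV.
#' @param dI_over_I relative lens-current instability (default 0).
#' @param dV_over_V relative voltage instability (default 0).
#' @export
optics_params <- function(V, Cc = 2.7, dE = 0.7, dI_over_I = 0,
                          dV_over_V = 0) {
  stopifnot(V > 0, Cc >= 0, dE >= 0)
  structure(list(V = V, Cc = Cc, dE = dE, dI_over_I = dI_over_I,
                 dV_over_V = dV_over_V), class = "optics_params")
}

# defocus spread delta (Angstrom): Cc * sqrt(4 (dI/I)^2 + (dE/V)^2 + (dV/V)^2)
.defocus_spread <- function(p) {
  (p$Cc * 1e7) * sqrt(4 * p$dI_over_I^2 + (p$dE / p$V)^2 + p$dV_over_V^2)
}

#' Chromatic-aberration (temporal-coherence) envelope
#'
#' `E(u) = exp(-0.5 * (pi * lambda * delta)^2 * u^4)` with the defocus
#' spread `delta = Cc * sqrt(4 (dI/I)^2 + (dE/V)^2 + (dV/V)^2)` (Cc
#' converted to Angstrom). Strictly decreasing in u, Cc and dE; equals 1 at
#' u = 0.
#'
#' @param u spatial frequency, 1/Angstrom; vectorized.
#' @param p an [optics_params()].
#' @return Envelope value in (0, 1].
#' @export
cc_envelope <- function(u, p) {
  stopifnot(all(u >= 0))
  delta <- .defocus_spread(p)
  exp(-0.5 * (pi * wavelength(p$V) * delta)^2 * u^4)
}

#' Depress a spectral SNR curve for different chromatic conditions
#'
#' `SNR'(u) = E_new(u)^2 * SNR(u) / E_ref(u)^2`: an SNR measured under
#' reference optics is rescaled to the envelope of another optical
#' configuration at the same physical frequency.
#'
#' @param snr [radial_curve()] with shells in 1/Angstrom.
#' @param p_ref optics under which `snr` was measured.
#' @param p_new optics to predict.
#' @return [radial_curve()] of depressed SNR; shells where the reference
#'   envelope underflows are set `NA`.
#' @export
depressed_snr <- function(snr, p_ref, p_new) {
  e_ref <- cc_envelope(snr$shells, p_ref)
  e_new <- cc_envelope(snr$shells, p_new)
  bad <- e_ref < 1e-30
  v <- ifelse(bad, NA_real_, e_new^2 * snr$values / e_ref^2)
  radial_curve(snr$shells, v, snr$n_terms)
}

#' Depress an FSC curve by the chromatic envelope ratio
#'
#' Converts FSC to SNR, applies [depressed_snr()], converts back.
#' @inheritParams depressed_snr
#' @param fsc [radial_curve()] of FSC, shells in 1/Angstrom.
#' @export
depressed_fsc <- function(fsc, p_ref, p_new) {
  snr_to_fsc(depressed_snr(fsc_to_snr(fsc), p_ref, p_new))
}

#' Least-squares fit of relative radiation damage against 1/beta^2
#'
#' Ordinary least squares of damage `y` on `1/beta^2(V)`: lower-voltage
#' electrons deposit more energy per path length, and per-electron damage
#' scales approximately with the inverse squared velocity ratio.
#'
#' @param points data.frame (or 2-column matrix) with columns `V` (volts)
#'   and `y` (relative damage).
#' @return list of class `damage_fit`: intercept, slope, r_square, points.
#' @export
damage_fit <- function(points) {
  points <- as.data.frame(points)
  names(points)[1:2] <- c("V", "y")
  stopifnot(nrow(points) >= 2L)
  x <- 1 / beta2(points$V)
  if (max(x) - min(x) < 1e-12) stop("degenerate abscissae: identical beta^2")
  fit <- lm(points$y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((points$y - mean(points$y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(intercept = coef(fit)[[1L]], slope = coef(fit)[[2L]],
                 r_square = r2, points = points), class = "damage_fit")
}

#' @export
print.damage_fit <- function(x, ...) {
  cat(sprintf("damage fit: y = %.5f + %.5f / beta^2 (R^2 = %.5f, n = %d)\n",
              x$intercept, x$slope, x$r_square, nrow(x$points)))
  invisible(x)
}

#' Information coefficient
#'
#' `IFC = T * sigma_e / sigma_i`: transmitted fraction times the ratio of
#' elastic (signal) to inelastic (damage) scattering cross-sections.
#'
#' @param T_frac transmission, in (0, 1].
#' @param sigma_e elastic cross-section (any consistent unit).
#' @param sigma_i inelastic cross-section (same unit).
#' @export
ifc <- function(T_frac, sigma_e, sigma_i) {
  stopifnot(T_frac > 0, T_frac <= 1, sigma_e > 0, sigma_i > 0)
  T_frac * sigma_e / sigma_i
}
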