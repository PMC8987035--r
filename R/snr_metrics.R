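# Frequency-resolved quality metrics: Fourier ring correlation, FSC<->SNR
# conversion, noise power spectra, slanted knife-edge MTF and DQE.

#' Construct a radial (shell-sampled) curve
#'
#' @param shells strictly increasing spatial frequencies, cycles/pixel.
#' @param values one value per shell.
#' @param n_terms Fourier samples averaged per shell (default 1).
#' @export
radial_curve <- function(shells, values, n_terms = rep(1L, length(shells))) {
  stopifnot(length(shells) == length(values), !is.unsorted(shells,
            strictly = TRUE), all(n_terms >= 1))
  structure(list(shells = as.numeric(shells), values = as.numeric(values),
                 n_terms = as.integer(n_terms)), class = "radial_curve")
}

#' @export
print.radial_curve <- function(x, ...) {
  cat(sprintf("radial_curve: %d shells in [%.4g, %.4g]\n", length(x$shells),
              min(x$shells), max(x$shells)))
  invisible(x)
}

#' @export
as.data.frame.radial_curve <- function(x, ...) {
  data.frame(shell = x$shells, value = x$values, n_terms = x$n_terms)
}

# shell index per Fourier sample: nearest integer ring in Fourier pixels
.ring_index <- function(nx, ny) {
  fx <- c(0:(nx %/% 2), -(((nx + 1) %/% 2 - 1):1)) / nx
  fy <- c(0:(ny %/% 2), -(((ny + 1) %/% 2 - 1):1)) / ny
  n <- min(nx, ny)
  u <- sqrt(outer(fx^2, fy^2, `+`))
  list(ring = round(u * n), u = u, n = n)
}

#' Fourier ring correlation of two images
#'
#' Per shell: `Re(sum(Fa * Conj(Fb))) / sqrt(sum|Fa|^2 * sum|Fb|^2)` over
#' the Fourier samples in the ring. Rings are 1 Fourier pixel wide; shell
#' frequencies are `j / min(dims)` cycles/pixel up to Nyquist (0.5).
#'
#' @param a,b numeric matrices with identical dimensions.
#' @return A [radial_curve()]; zero-power shells get value 0 with a warning.
#' @export
frc <- function(a, b) {
  if (inherits(a, "counted_image")) a <- a$array
  if (inherits(b, "counted_image")) b <- b$array
  stopifnot(identical(dim(a), dim(b)))
  ri <- .ring_index(nrow(a), ncol(a))
  fa <- fft(a); fb <- fft(b)
  keep <- ri$ring <= ri$n %/% 2
  ring <- ri$ring[keep]
  num <- as.vector(tapply(Re(fa[keep] * Conj(fb[keep])), ring, sum))
  pa <- as.vector(tapply(abs(fa[keep])^2, ring, sum))
  pb <- as.vector(tapply(abs(fb[keep])^2, ring, sum))
  nt <- as.vector(tapply(ring, ring, length))
  den <- sqrt(pa * pb)
  v <- ifelse(den > 0, num / pmax(den, .Machine$double.xmin), 0)
  if (any(den == 0)) warning("zero-power shell(s); FRC set to 0 there")
  j <- sort(unique(ring))
  radial_curve(j / ri$n, v, nt)
}

.fsc_cap <- 1 - 1e-9

#' Convert FSC to spectral SNR (and back)
#'
#' `SNR = 2 FSC / (1 - FSC)` for half-set correlations. FSC exactly 1 is an
#' error (infinite SNR); values in (1 - 1e-9, 1) are clamped to 1 - 1e-9.
#' Negative FSC maps through the same formula.
#'
#' @param fsc numeric vector or [radial_curve()].
#' @return Same shape as the input.
#' @export
fsc_to_snr <- function(fsc) {
  if (inherits(fsc, "radial_curve"))
    return(radial_curve(fsc$shells, fsc_to_snr(fsc$values), fsc$n_terms))
  if (any(fsc == 1)) stop("FSC = 1 gives infinite SNR")
  fsc <- pmin(fsc, .fsc_cap)
  2 * fsc / (1 - fsc)
}

#' @rdname fsc_to_snr
#' @param snr numeric vector or [radial_curve()].
#' @export
snr_to_fsc <- function(snr) {
  if (inherits(snr, "radial_curve"))
    return(radial_curve(snr$shells, snr_to_fsc(snr$values), snr$n_terms))
  snr / (2 + snr)
}

#' Frequency at which an FSC curve crosses a threshold
#'
#' Linear interpolation between the shells around the first downward
#' crossing; `NA` if the curve never falls below the threshold.
#'
#' @param curve an FSC [radial_curve()].
#' @param threshold default 0.143 (gold-standard criterion); 0.5 also common.
#' @return Frequency in the curve's shell units.
#' @export
fsc_resolution <- function(curve, threshold = 0.143) {
  v <- curve$values; s <- curve$shells
  below <- which(v < threshold)
  below <- below[below > 1L]
  if (length(below) == 0L) return(NA_real_)
  i <- below[1L]
  s[i - 1L] + (threshold - v[i - 1L]) * (s[i] - s[i - 1L]) / (v[i] - v[i - 1L])
}

#' Noise power spectrum of structure-free realizations
#'
#' Radially averaged power spectrum of mean-subtracted realizations,
#' averaged over realizations and normalized per pixel
#' (`|F|^2 / n_pixels`), so a Poisson point process of rate lambda gives a
#' flat NPS at level lambda.
#'
#' @param x a [frame_stack()], a list of matrices/[counted_image()]s, or a
#'   single matrix.
#' @return A [radial_curve()].
#' @export
nps <- function(x) {
  reals <- if (inherits(x, "frame_stack")) x$frames
  else if (is.matrix(x)) list(x)
  else lapply(x, function(e) if (inherits(e, "counted_image")) e$array else e)
  if (length(reals) == 1L) {
    m <- reals[[1L]]
    rowm <- rowMeans(m); colm <- colMeans(m)
    if (sd(rowm) > 2 * sd(m) / sqrt(ncol(m)) + 1e-12 ||
        sd(colm) > 2 * sd(m) / sqrt(nrow(m)) + 1e-12)
      warning("single realization looks non-flat; NPS may include structure")
  }
  ri <- .ring_index(nrow(reals[[1L]]), ncol(reals[[1L]]))
  keep <- ri$ring <= ri$n %/% 2
  ring <- ri$ring[keep]
  npix <- length(reals[[1L]])
  acc <- 0
  for (m in reals) {
    f <- fft(m - mean(m))
    acc <- acc + abs(f[keep])^2 / npix
  }
  acc <- acc / length(reals)
  pw <- as.vector(tapply(acc, ring, mean))
  nt <- as.vector(tapply(ring, ring, length))
  j <- sort(unique(ring))
  radial_curve(j / ri$n, pw, nt)
}

# Per-row edge crossing by centroid of the (smoothed) x-gradient. Rows are
# averaged over a small window along the edge first: the crossing position
# is linear in y, so row averaging reduces noise without biasing the line.
.edge_crossings <- function(img, y_window = 9L) {
  nx <- nrow(img); ny <- ncol(img)
  if (y_window > 1L && ny > y_window) {
    k <- matrix(1 / y_window, 1L, y_window)
    img <- EBImage::filter2(img, k, boundary = "replicate")
  }
  x0 <- rep(NA_real_, ny)
  for (j in seq_len(ny)) {
    p <- img[, j]
    if (nx > 8) p <- stats::filter(p, rep(1 / 3, 3), sides = 2)
    p[is.na(p)] <- 0
    # coarse pass: first crossing of half the open-side level
    lo <- median(p[1:max(3L, nx %/% 8L)], na.rm = TRUE)
    hi <- median(p[(nx - max(3L, nx %/% 8L) + 1L):nx], na.rm = TRUE)
    if (hi < lo) { tmp <- hi; hi <- lo; lo <- tmp }
    if (hi - lo <= 0) next
    coarse <- which(p > (lo + hi) / 2)[1L]
    if (is.na(coarse)) next
    # refine: gradient centroid within a window around the coarse crossing
    win <- max(2L, coarse - 5L):min(nx, coarse + 4L)
    g <- pmax(p[win] - p[win - 1L], 0)
    if (sum(g) <= 0) next
    # gradient between pixel centres i-1 and i sits at 0-based i - 1.5
    x0[j] <- sum((win - 1.5) * g) / sum(g)
  }
  x0
}

#' Slanted knife-edge MTF
#'
#' Fits the edge line through per-row crossing estimates, bins every pixel
#' by signed distance to the edge into an oversampled edge-spread function,
#' differentiates to the line-spread function and Fourier-transforms it.
#' The binning aperture and the finite-difference derivative each multiply
#' the spectrum by `sinc(pi u / oversample)`; the returned MTF is divided
#' by that factor squared. Normalized to 1 at u = 0.
#'
#' @param edge_stack a [frame_stack()] (frames are summed) or a matrix.
#' @param oversample sub-pixel bins per native pixel (default 4).
#' @param halfwidth distance range (px) kept around the edge (default 12).
#' @param min_r_squared minimum R^2 of the edge-line fit (default 0.9).
#' @return A [radial_curve()] of MTF up to native Nyquist, with attributes
#'   `edge` (list: intercept, slope, angle_deg, r_squared).
#' @export
knife_edge_mtf <- function(edge_stack, oversample = 4L, halfwidth = 12,
                           min_r_squared = 0.9) {
  img <- if (inherits(edge_stack, "frame_stack"))
    Reduce(`+`, edge_stack$frames) else edge_stack
  ny <- ncol(img)
  # the edge must separate two plateaus with real contrast
  strip <- max(3L, nrow(img) %/% 8L)
  lo_px <- img[seq_len(strip), ]; hi_px <- img[(nrow(img) - strip + 1L):nrow(img), ]
  contrast <- abs(median(hi_px) - median(lo_px))
  noise <- max(mad(lo_px), mad(hi_px)) / sqrt(length(lo_px))
  if (contrast < 5 * max(noise, .Machine$double.eps))
    stop("edge fit failure: no edge contrast between the image halves")
  x0 <- .edge_crossings(img)
  ok <- is.finite(x0)
  if (sum(ok) < 8L) stop("edge fit failure: too few usable rows")
  yy <- (seq_len(ny) - 1L)[ok]
  fit <- lm(x0[ok] ~ yy)
  r2 <- summary(fit)$r.squared
  # a nearly untilted edge fits a horizontal line with r^2 ~ 0; accept when
  # the residual scatter is small instead
  resid_sd <- sd(fit$residuals)
  if (r2 < min_r_squared && resid_sd > 2.0)
    stop(sprintf("edge fit failure: R^2 = %.3f, residual sd %.2f px",
                 r2, resid_sd))
  c0 <- coef(fit)[[1L]]; c1 <- coef(fit)[[2L]]
  xs <- matrix(seq_len(nrow(img)) - 1, nrow(img), ny)     # pixel centres
  ys <- matrix(seq_len(ny) - 1L, nrow(img), ny, byrow = TRUE)
  d <- (xs - c0 - c1 * ys) / sqrt(1 + c1^2)
  os <- as.integer(oversample)
  bin <- floor((d + halfwidth) * os)
  nb <- as.integer(2 * halfwidth * os)
  keep <- bin >= 0 & bin < nb
  esf <- as.vector(tapply(img[keep], factor(bin[keep], levels = 0:(nb - 1L)),
                          mean))
  if (anyNA(esf)) {  # fill rare empty bins by interpolation
    idx <- seq_along(esf)
    esf <- approx(idx[!is.na(esf)], esf[!is.na(esf)], idx, rule = 2)$y
  }
  lsf <- diff(esf) * os       # tails are flat, so no extra windowing needed
  sp <- abs(fft(lsf))
  freqs <- (seq_along(lsf) - 1L) / length(lsf) * os   # cycles per native px
  keepf <- freqs <= 0.5 + os / length(lsf)            # cover Nyquist
  u <- freqs[keepf]
  m <- sp[keepf] / sp[1L]
  corr <- ifelse(u > 0, (sin(pi * u / os) / (pi * u / os))^2, 1)
  m <- m / corr
  out <- radial_curve(u, m)
  attr(out, "edge") <- list(intercept = c0, slope = c1,
                            angle_deg = atan(c1) * 180 / pi, r_squared = r2)
  out
}

#' Detective quantum efficiency from MTF and NPS
#'
#' `DQE(u) = detected_fraction * MTF(u)^2 * counted_dose / NPS(u)`. With a
#' per-pixel NPS normalization this gives DQE(0) = 1 for an ideal counter
#' (every electron detected at its true position: Poisson NPS = dose). The
#' normalization constant (`counted_dose`) is recorded as an attribute.
#'
#' @param mtf,nps_curve [radial_curve()]s on shared shells.
#' @param counted_dose mean counted events per pixel.
#' @param detected_fraction fraction of incident electrons counted.
#' @return A [radial_curve()].
#' @export
dqe <- function(mtf, nps_curve, counted_dose, detected_fraction = 1) {
  if (!isTRUE(all.equal(mtf$shells, nps_curve$shells)))
    stop("MTF and NPS on mismatched shells")
  npv <- nps_curve$values
  dc_extrapolated <- FALSE
  if (length(npv) > 2L && nps_curve$shells[1L] == 0 && npv[1L] <= 0) {
    # the DC term of a mean-subtracted NPS is identically 0; extrapolate
    npv[1L] <- mean(npv[2:3])
    dc_extrapolated <- TRUE
  }
  if (any(npv <= 0)) stop("NPS must be positive")
  v <- detected_fraction * mtf$values^2 * counted_dose / npv
  out <- radial_curve(mtf$shells, v, mtf$n_terms)
  attr(out, "normalization") <- counted_dose
  attr(out, "dc_extrapolated") <- dc_extrapolated
  out
}

#' Frequency-resolved SNR gain between two curves, with a linear fit
#'
#' Forms the per-shell ratio `SNR_a / SNR_b`, fits a least-squares line to
#' the ratio over `[fit_lo, fit_hi] * nyquist`, and reports the fitted
#' value at 0.5 and 1.0 Nyquist.
#'
#' @param curve_a,curve_b [radial_curve()]s on shared shells; FSC curves by
#'   default (`kind = "fsc"`, converted through [fsc_to_snr()]) or SNR
#'   curves (`kind = "snr"`).
#' @param fit_lo,fit_hi fit window as fractions of Nyquist.
#' @param nyquist Nyquist frequency in shell units (default 0.5; pass the
#'   super-resolution Nyquist to fit beyond the native one).
#' @param kind "fsc" or "snr".
#' @return list(ratio = radial_curve, at_half_nyquist, at_nyquist, slope,
#'   intercept).
#' @export
snr_gain_fit <- function(curve_a, curve_b, fit_lo = 0.3, fit_hi = 0.8,
                         nyquist = 0.5, kind = c("fsc", "snr")) {
  kind <- match.arg(kind)
  if (!isTRUE(all.equal(curve_a$shells, curve_b$shells)))
    stop("curves on mismatched shells")
  sa <- if (kind == "fsc") fsc_to_snr(curve_a$values) else curve_a$values
  sb <- if (kind == "fsc") fsc_to_snr(curve_b$values) else curve_b$values
  ratio <- sa / sb
  sh <- curve_a$shells
  win <- sh >= fit_lo * nyquist & sh <= fit_hi * nyquist & is.finite(ratio)
  if (sum(win) < 3L) stop("fewer than 3 shells in fit window")
  fit <- lm(ratio[win] ~ sh[win])
  a <- coef(fit)[[1L]]; b <- coef(fit)[[2L]]
  list(ratio = radial_curve(sh, ratio, curve_a$n_terms),
       at_half_nyquist = a + b * 0.5 * nyquist,
       at_nyquist = a + b * nyquist,
       slope = b, intercept = a)
}
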