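test_that("Fourier ring correlation hits its exact limits", {
  set.seed(21)
  x <- matrix(rnorm(64 * 64), 64L, 64L)
  self <- frc(x, x)
  expect_true(all(abs(self$values - 1) < 1e-9))
  anti <- frc(x, -x)
  expect_true(all(abs(anti$values + 1) < 1e-9))
  expect_true(!is.unsorted(self$shells, strictly = TRUE))
  expect_lte(max(self$shells), 0.5)

  # independent white noise decorrelates shell by shell
  y <- matrix(rnorm(64 * 64), 64L, 64L)
  nul <- frc(x, y)
  expect_true(all(abs(nul$values) < 4 / sqrt(nul$n_terms)))
  expect_lt(abs(mean(nul$values)), 0.05)
})

test_that("FSC to SNR conversion matches the published worked example", {
  expect_equal(fsc_to_snr(0.80), 8.00, tolerance = 1e-12)
  expect_equal(fsc_to_snr(0.68), 4.25, tolerance = 1e-12)
  expect_equal(fsc_to_snr(0), 0)
  expect_error(fsc_to_snr(1), "infinite")

  # strictly increasing and inverse-consistent on (-1, 1)
  v <- seq(-0.95, 0.95, by = 0.05)
  s <- fsc_to_snr(v)
  expect_true(all(diff(s) > 0))
  expect_equal(snr_to_fsc(s), v, tolerance = 1e-12)

  cv <- radial_curve(c(0.1, 0.2), c(0.80, 0.68))
  expect_equal(fsc_to_snr(cv)$values, c(8.00, 4.25))
})

test_that("FSC threshold crossings interpolate linearly", {
  cv <- radial_curve(c(0.1, 0.2, 0.3, 0.4), c(0.9, 0.6, 0.4, 0.05))
  expect_equal(fsc_resolution(cv, 0.5), 0.25)
  expect_equal(fsc_resolution(cv, 0.143),
               0.3 + (0.143 - 0.4) / (0.05 - 0.4) * 0.1)
  expect_true(is.na(fsc_resolution(radial_curve(1:3 / 10, c(.9, .8, .7)))))
})

test_that("NPS of ideal point counting is white; patterns suppress high
           frequency; zero input gives zero", {
  set.seed(22)
  dims <- c(64L, 64L)
  reals <- lapply(1:60, function(i) {
    n <- rpois(1L, 3 * prod(dims))
    render_points(cbind(runif(n, 0, dims[1L]), runif(n, 0, dims[2L])),
                  dims, 1L)$array
  })
  flat <- nps(reals)
  lvl <- mean(flat$values[-1L])
  # whiteness: five coarse frequency bands all sit within 5% of the mean
  band <- cut(flat$shells[-1L], 5L)
  band_means <- tapply(flat$values[-1L], band, mean)
  expect_lt(max(abs(band_means - lvl)) / lvl, 0.05)
  expect_equal(lvl, 3, tolerance = 0.05)          # Poisson variance = dose

  pat <- data.frame(dx = c(0L, 1L, -1L, 0L, 0L),
                    dy = c(0L, 0L, 0L, 1L, -1L), value = rep(0.2, 5L))
  preals <- lapply(1:20, function(i) {
    n <- rpois(1L, 0.5 * prod(dims))
    anch <- cbind(sample(2:(dims[1L] - 3L), n, TRUE),
                  sample(2:(dims[2L] - 3L), n, TRUE))
    render_patterns(anch, rep(list(pat), n), dims, 1L)$array
  })
  pn <- nps(preals)
  lo <- mean(pn$values[pn$shells > 0 & pn$shells <= 0.15])
  hi <- mean(pn$values[pn$shells >= 0.35])
  expect_lt(hi, lo)

  z <- nps(matrix(0, 32L, 32L))
  expect_true(all(z$values == 0))
})

test_that("weighting an image scales its NPS by w squared per shell", {
  set.seed(23)
  dims <- c(64L, 64L)
  reals <- lapply(1:20, function(i) {
    n <- rpois(1L, 2 * prod(dims))
    render_points(cbind(runif(n, 0, dims[1L]), runif(n, 0, dims[2L])),
                  dims, 1L)$array
  })
  prof <- radial_curve(c(0, 0.25, 0.5, 0.75), c(1, 0.8, 0.45, 0.3))
  weighted <- lapply(reals, apply_radial_weight, profile = prof)
  n0 <- nps(reals); n1 <- nps(weighted)
  sel <- n0$shells > 0.03 & n0$shells <= 0.5
  w_at <- approx(prof$shells, prof$values, n0$shells[sel])$y
  ratio <- n1$values[sel] / n0$values[sel]
  expect_equal(ratio, w_at^2, tolerance = 0.02)
})

test_that("knife-edge MTF reproduces the pixel-aperture and Gaussian
           closed forms", {
  edge <- make_edge_image(96L, 96L, angle_deg = 3)
  m <- knife_edge_mtf(edge)
  expect_equal(m$values[1L], 1)
  e <- attr(m, "edge")
  expect_lt(abs(e$angle_deg - 3), 0.1)
  at_nyq <- approx(m$shells, m$values, 0.5)$y
  expect_equal(at_nyq, 2 / pi, tolerance = 0.02 * 2 / pi)
  # sinc curve over the mid frequencies
  mid <- m$shells > 0.05 & m$shells <= 0.5
  expect_equal(m$values[mid],
               abs(sin(pi * m$shells[mid]) / (pi * m$shells[mid])),
               tolerance = 0.02)

  gedge <- make_edge_image(96L, 96L, angle_deg = 3, sigma_blur = 0.8)
  gm <- knife_edge_mtf(gedge)
  gsel <- gm$shells > 0.02 & gm$shells <= 0.35
  expect_equal(gm$values[gsel],
               exp(-2 * pi^2 * 0.8^2 * gm$shells[gsel]^2),
               tolerance = 0.02)

  expect_error(knife_edge_mtf(matrix(rnorm(96 * 96), 96L, 96L)),
               "edge fit")
})

test_that("DQE is 1 at DC for an ideal counter, scales with detected
           fraction, and drops with position jitter", {
  set.seed(24)
  dims <- c(64L, 64L)
  dose <- 2
  mk_reals <- function(jitter) lapply(1:30, function(i) {
    n <- rpois(1L, dose * prod(dims))
    x <- runif(n, 0, dims[1L]); y <- runif(n, 0, dims[2L])
    if (jitter > 0) {           # wrap on the torus to stay flat
      x <- (x + rnorm(n, 0, jitter)) %% dims[1L]
      y <- (y + rnorm(n, 0, jitter)) %% dims[2L]
    }
    render_points(cbind(x, y), dims, 1L)$array
  })
  n_ideal <- nps(mk_reals(0))
  unit_mtf <- radial_curve(n_ideal$shells, rep(1, length(n_ideal$shells)))
  d <- dqe(unit_mtf, n_ideal, counted_dose = dose)
  expect_equal(d$values[1L], 1, tolerance = 0.1)
  d_half <- dqe(unit_mtf, n_ideal, counted_dose = dose,
                detected_fraction = 0.5)
  expect_equal(d_half$values, d$values / 2, tolerance = 1e-12)

  # jitter keeps the counting NPS white but destroys transfer: model the
  # jitter MTF as the Gaussian factor and compare DQE at Nyquist
  jit_mtf <- radial_curve(n_ideal$shells,
                          exp(-2 * pi^2 * 0.5^2 * n_ideal$shells^2))
  d_j <- dqe(jit_mtf, nps(mk_reals(0.5)), counted_dose = dose)
  expect_lt(d_j$values[length(d_j$values)],
            d$values[length(d$values)] * 0.5)
  expect_error(dqe(unit_mtf, radial_curve(c(0, 0.1), c(1, 1)), 1), "shell")
})

test_that("SNR gain fitting recovers exact linear ratios", {
  sh <- seq(0.02, 0.5, by = 0.02)
  a <- radial_curve(sh, rep(4, length(sh)))
  same <- snr_gain_fit(a, a, kind = "snr")
  expect_equal(same$at_half_nyquist, 1, tolerance = 1e-12)
  expect_equal(same$slope, 0, tolerance = 1e-12)

  dbl <- snr_gain_fit(radial_curve(sh, rep(8, length(sh))), a,
                      kind = "snr")
  expect_equal(dbl$at_nyquist, 2, tolerance = 1e-12)

  lin <- snr_gain_fit(radial_curve(sh, 4 * (1 + sh / 0.5)), a,
                      kind = "snr")
  expect_equal(lin$at_nyquist, 2, tolerance = 0.01)
  expect_equal(lin$at_half_nyquist, 1.5, tolerance = 0.01)

  # fsc input goes through the SNR conversion
  f1 <- radial_curve(sh, rep(0.80, length(sh)))
  f2 <- radial_curve(sh, rep(0.68, length(sh)))
  gf <- snr_gain_fit(f1, f2, kind = "fsc")
  expect_equal(gf$at_half_nyquist, 8 / 4.25, tolerance = 1e-9)

  expect_error(snr_gain_fit(a, a, fit_lo = 0.49, fit_hi = 0.5,
                            kind = "snr"), "3 shells")
})
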