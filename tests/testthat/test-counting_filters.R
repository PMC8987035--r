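test_that("position rules reproduce hand-computed centroids and peaks", {
  # mass centre: value-weighted mean
  expect_equal(mcf_position(make_cluster(c(0, 0, 1, 0), c(1, 1))),
               c(0.5, 0))
  expect_equal(mcf_position(make_cluster(c(2, 3, 3, 3), c(3, 1))),
               c(2.25, 3))
  expect_equal(mcf_position(make_cluster(c(7, 4), 2.5)), c(7, 4))

  # peak value with the nearest-to-centroid, then lexicographic tie rule
  expect_equal(pvf_position(make_cluster(c(2, 3, 2, 4), c(10, 5))), c(2, 3))
  # tie at 5/5: centroid x = 7/11 = 0.64 is nearer pixel (1,0)
  expect_equal(pvf_position(make_cluster(c(0, 0, 1, 0, 2, 0), c(5, 5, 1))),
               c(1, 0))
  # exact tie in distance falls back to lexicographic (y, x)
  expect_equal(pvf_position(make_cluster(c(0, 0, 1, 0), c(5, 5))), c(0, 0))
  expect_equal(pvf_position(make_cluster(c(3, 9), 1)), c(3, 9))

  # geometric centre ignores values
  expect_equal(gcf_position(make_cluster(c(0, 0, 2, 0), c(1, 1))), c(1, 0))
  expect_equal(gcf_position(make_cluster(c(0, 0, 2, 0), c(100, 1))),
               c(1, 0))
  full <- make_cluster(cbind(rep(4:6, 3), rep(4:6, each = 3)), rep(2, 9))
  expect_equal(gcf_position(full), c(5, 5))

  # on a symmetric cluster all three rules agree at the symmetry centre
  sym <- make_cluster(rbind(c(5, 5), c(4, 5), c(6, 5), c(5, 4), c(5, 6)),
                      c(9, 2, 2, 2, 2))
  expect_equal(mcf_position(sym), c(5, 5))
  expect_equal(gcf_position(sym), c(5, 5))
  expect_equal(pvf_position(sym), c(5, 5))
})

test_that("patterns are value^pow normalized, uniform at pow 0", {
  cl5 <- make_cluster(rbind(c(3, 3), c(4, 3), c(3, 4), c(2, 3), c(3, 2)),
                      c(5, 4, 3, 2, 1))
  p0 <- pca_pattern(cl5, pow = 0)
  expect_equal(p0$value, rep(0.2, 5L))
  expect_equal(sum(p0$value), 1)

  cl2 <- make_cluster(c(0, 0, 1, 0), c(3, 1))
  expect_equal(pca_pattern(cl2, pow = 1)$value, c(0.75, 0.25))
  expect_equal(pca_pattern(cl2, pow = 2)$value, c(0.9, 0.1))
  expect_equal(pca_pattern(cl2, pow = -1)$value, c(0.25, 0.75))
  expect_equal(sum(pca_pattern(cl5, pow = -2)$value), 1)
  # every advertised pow is accepted
  for (pw in c(0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 2, 3))
    for (sgn in c(-1, 1))
      expect_equal(sum(pca_pattern(cl5, pow = sgn * pw)$value), 1)
})

test_that("point rendering follows the floor(x*sr) mapping and conserves
           counts", {
  img <- render_points(cbind(10.3, 5.9), c(32L, 32L), sr_factor = 2L)
  expect_equal(img$array[21L, 12L], 1)            # 0-based (20, 11)
  expect_equal(sum(img$array), 1)

  set.seed(11)
  pos <- cbind(runif(200, 0, 32), runif(200, 0, 32))
  i1 <- render_points(pos, c(32L, 32L), 1L)
  i2 <- render_points(pos, c(32L, 32L), 2L)
  expect_equal(sum(i1$array), 200)
  expect_equal(sum(i2$array), 200)
  # 2x2 block-summing the sr=2 image reproduces the sr=1 image
  blk <- i2$array[seq(1, 63, 2), ] + i2$array[seq(2, 64, 2), ]
  blk <- blk[, seq(1, 63, 2)] + blk[, seq(2, 64, 2)]
  expect_equal(blk, i1$array)

  expect_error(render_points(cbind(40, 1), c(32L, 32L), 1L), "bounds")
})

test_that("pattern rendering deposits normalized footprints", {
  pat <- data.frame(dx = c(0L, 1L, -1L, 0L, 0L), dy = c(0L, 0L, 0L, 1L, -1L),
                    value = rep(0.2, 5L))
  img <- render_patterns(rbind(c(8L, 8L)), list(pat), c(16L, 16L), 1L)
  expect_equal(sum(img$array), 1)
  expect_equal(img$array[9L, 9L], 0.2)
  expect_equal(img$array[10L, 9L], 0.2)
  expect_equal(sort(which(img$array > 0)), c(121L, 136L, 137L, 138L, 153L))

  # with sr = 2 the mass lands in the central sub-pixel of each block
  img2 <- render_patterns(rbind(c(8L, 8L)), list(pat), c(16L, 16L), 2L)
  expect_equal(sum(img2$array), 1)
  expect_equal(img2$array[18L, 18L], 0.2)         # (8*2+1, 8*2+1) 0-based

  expect_error(render_patterns(rbind(c(0L, 0L)),
                               list(data.frame(dx = -2L, dy = 0L,
                                               value = 1)),
                               c(16L, 16L), 1L), "bounds")
})

test_that("large positive pow drives pattern rendering to the peak pixel", {
  cl <- make_cluster(rbind(c(6, 6), c(7, 6), c(6, 7), c(5, 6), c(6, 5)),
                     c(10, 6, 4, 2, 1))
  dims <- c(16L, 16L)
  hard <- render_patterns(rbind(floor(mcf_position(cl))),
                          list(pca_pattern(cl, pow = 50)), dims, 1L)
  point <- render_points(rbind(pvf_position(cl)), dims, 1L)
  expect_equal(hard$array, point$array, tolerance = 1e-6)
})

test_that("SNR weight profile follows w = sqrt(SNR2/SNR1 * NPS1/NPS2)", {
  sh <- seq(0.05, 0.5, by = 0.05)
  c1 <- radial_curve(sh, rep(4, 10))
  c2 <- radial_curve(sh, rep(4, 10))
  n1 <- radial_curve(sh, rep(2, 10))
  w <- snr_weight_profile(c1, c2, n1, n1)
  expect_true(all(abs(w$values - 1) < 1e-12))

  w2 <- snr_weight_profile(c1, radial_curve(sh, rep(16, 10)), n1, n1)
  expect_equal(w2$values[-1L], rep(2, 10))        # shell 0 prepended as 1
  expect_equal(w2$values[1L], 1)

  w3 <- snr_weight_profile(radial_curve(sh, rep(4.25, 10)),
                           radial_curve(sh, rep(8.00, 10)), n1, n1)
  expect_equal(w3$values[-1L], rep(sqrt(8 / 4.25), 10))
  expect_equal(w3$values[2L], 1.372, tolerance = 1e-3)

  expect_warning(
    snr_weight_profile(c1, radial_curve(sh, c(-1, rep(4, 9))), n1, n1),
    "non-positive")
  expect_error(snr_weight_profile(c1, radial_curve(sh[-1], rep(4, 9)),
                                  n1, n1), "shell")
})

test_that("radial weighting is exact against a brute-force DFT oracle", {
  set.seed(3)
  img <- matrix(rnorm(64), 8L, 8L)
  prof <- radial_curve(c(0, 0.2, 0.5, 0.75), c(1, 0.8, 0.3, 0.1))

  # identity weight leaves the image untouched
  unit <- radial_curve(c(0, 0.75), c(1, 1))
  expect_equal(apply_radial_weight(img, unit), img, tolerance = 1e-9)

  # brute-force double-loop DFT with the same radial interpolation
  n <- 8L
  fr <- function(i) if (i <= n / 2) i / n else (i - n) / n
  F <- matrix(0 + 0i, n, n)
  for (p in 0:(n - 1L)) for (q in 0:(n - 1L))
    F[p + 1L, q + 1L] <- sum(img * exp(-2i * pi * (p * (row(img) - 1L) +
                                       q * (col(img) - 1L)) / n))
  W <- matrix(0, n, n)
  for (p in 0:(n - 1L)) for (q in 0:(n - 1L))
    W[p + 1L, q + 1L] <- approx(prof$shells, prof$values,
                                sqrt(fr(p)^2 + fr(q)^2), rule = 2)$y
  G <- F * W
  out <- matrix(0, n, n)
  for (a in 0:(n - 1L)) for (b in 0:(n - 1L))
    out[a + 1L, b + 1L] <- Re(sum(G * exp(2i * pi *
      ((0:(n - 1L))[row(G)] * a + (0:(n - 1L))[col(G)] * b) / n))) / n^2
  expect_equal(apply_radial_weight(img, prof), out, tolerance = 1e-9)

  # real input stays real
  w <- apply_radial_weight(img, prof)
  expect_true(is.numeric(w))
})

test_that("counting conserves events and methods coincide on 1-px
           clusters", {
  m <- detector_model(dims = c(48L, 48L), read_noise_sigma = 0,
                      bse_probability = 0, charge_cloud_sigma = 0,
                      cloud_amplitude = 50)
  g <- generate_frame_stack(m, dose_rate = 0.004, n_frames = 6L, seed = 8L)
  imgs <- lapply(c("MCF", "PVF", "GCF", "Hybrid"), function(meth)
    count_stack(g$stack, meth, sr_factor = 2L))
  n <- imgs[[1L]]$image$n_events
  expect_gt(n, 20L)
  for (r in imgs) {
    expect_equal(sum(r$image$array), r$image$n_events, tolerance = 1e-9)
    expect_equal(r$image$array, imgs[[1L]]$image$array)
  }
})

test_that("Hybrid spreads each large cluster uniformly over its footprint", {
  fr <- matrix(0, 16L, 16L)
  fr[cbind(c(9, 8, 10, 9, 9), c(9, 9, 9, 8, 10))] <- 100   # 5-px plus
  stack <- frame_stack(list(fr))
  res <- count_stack(stack, "Hybrid", sr_factor = 1L,
                     params = detection_params(threshold_k = 5))
  expect_equal(res$image$n_events, 1L)
  expect_equal(sum(res$image$array), 1)
  got <- res$image$array[res$image$array > 0]
  expect_equal(got, rep(0.2, 5L))
  expect_equal(res$events$records$size_class, "large")
})

test_that("WPF weights only the large-cluster partial image and needs a
           profile", {
  m <- detector_model(dims = c(64L, 64L), read_noise_sigma = 1,
                      charge_cloud_sigma = 0.35, cloud_amplitude = 120,
                      amp_sdlog = 0.5, bse_probability = 0.6,
                      bse_sigma = 0.55, bse_offset = c(9, 0.2),
                      bse_amplitude_fraction = 1)
  g <- generate_frame_stack(m, dose_rate = 0.004, n_frames = 10L,
                            seed = 13L)
  expect_error(count_stack(g$stack, "WPF"), "profile")
  flat <- radial_curve(c(0, 0.3, 0.75), c(1, 1, 1))
  res <- count_stack(g$stack, "WPF", sr_factor = 1L, weight_profile = flat)
  expect_equal(sum(res$image$array), res$image$n_events, tolerance = 1e-6)
  expect_true(any(res$events$records$weight_flag))
  expect_equal(res$events$records$weight_flag,
               res$events$records$size_class == "large")

  # a non-flat weight with w(0) = 1 still conserves the total dose
  lp <- radial_curve(c(0, 0.2, 0.5, 0.75), c(1, 0.9, 0.4, 0.2))
  res2 <- count_stack(g$stack, "WPF", sr_factor = 1L, weight_profile = lp)
  expect_equal(sum(res2$image$array), res2$image$n_events,
               tolerance = 1e-6)
})
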