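# Counting filters: convert detected clusters into counted electrons.
#
# Every filter normalizes each electron's total contribution to 1, so the
# counted image integrates to the event count. Point filters (MCF, PVF,
# GCF) reduce a cluster to a single sub-pixel position; the pattern filter
# (PCA) deposits the whole normalized cluster footprint; WPF and Hybrid
# route clusters by size class.

#' Mass-centre (value-weighted centroid) of a cluster
#' @param cluster a cluster from [detect_events()].
#' @return c(x, y), continuous native-pixel coordinates.
#' @export
mcf_position <- function(cluster) {
  w <- cluster$values / sum(cluster$values)
  c(sum(cluster$pixels[, 1L] * w), sum(cluster$pixels[, 2L] * w))
}

#' Peak-value pixel of a cluster
#'
#' Ties on the maximum value are broken by smallest Euclidean distance to
#' the mass centre, then lexicographically by (y, x).
#' @inheritParams mcf_position
#' @return c(x, y) of the winning pixel (integer-valued).
#' @export
pvf_position <- function(cluster) {
  v <- cluster$values
  cand <- which(v == max(v))
  if (length(cand) > 1L) {
    mc <- mcf_position(cluster)
    d2 <- (cluster$pixels[cand, 1L] - mc[1L])^2 +
          (cluster$pixels[cand, 2L] - mc[2L])^2
    best <- which(d2 <= min(d2) + 1e-12)
    cand <- cand[best]
    if (length(cand) > 1L) {
      o <- order(cluster$pixels[cand, 2L], cluster$pixels[cand, 1L])
      cand <- cand[o[1L]]
    }
  }
  as.numeric(cluster$pixels[cand[1L], ])
}

#' Geometric centre (unweighted mean of pixel coordinates) of a cluster
#' @inheritParams mcf_position
#' @return c(x, y).
#' @export
gcf_position <- function(cluster) {
  c(mean(cluster$pixels[, 1L]), mean(cluster$pixels[, 2L]))
}

#' Normalized pattern of a cluster (pattern counting)
#'
#' Each pixel value is raised to `pow` and the result normalized to unit
#' sum. `pow = 0` gives the uniform pattern 1/n on every member pixel;
#' large positive `pow` approaches a delta at the peak pixel; negative
#' `pow` inverts the weighting (the detection floor keeps values positive).
#'
#' @inheritParams mcf_position
#' @param pow exponent applied to pixel values before normalization.
#' @return data.frame with `dx`, `dy` (offsets from the cluster's anchor
#'   pixel, `floor(mcf_position)`) and `value` (sums to 1).
#' @export
pca_pattern <- function(cluster, pow = 1) {
  v <- cluster$values^pow
  if (!all(is.finite(v)) || sum(v) <= 0)
    stop("pattern not finite: pow = ", pow, " overflows for these values")
  v <- v / sum(v)
  anchor <- floor(mcf_position(cluster))
  data.frame(dx = as.integer(cluster$pixels[, 1L] - anchor[1L]),
             dy = as.integer(cluster$pixels[, 2L] - anchor[2L]),
             value = v)
}

#' Construct a counted image
#' @param array non-negative numeric matrix on the output grid.
#' @param sr_factor integer super-resolution factor (output grid = native
#'   dims x sr_factor).
#' @param n_events number of electrons accumulated.
#' @export
counted_image <- function(array, sr_factor = 1L, n_events = 0L) {
  structure(list(array = array, sr_factor = as.integer(sr_factor),
                 n_events = as.integer(n_events)),
            class = "counted_image")
}

#' @export
print.counted_image <- function(x, ...) {
  cat(sprintf("counted_image: %d x %d (sr %d), %d events, sum %.6g\n",
              nrow(x$array), ncol(x$array), x$sr_factor, x$n_events,
              sum(x$array)))
  invisible(x)
}

#' Accumulate point events into a counted image
#'
#' An event at continuous position (x, y) adds its weight to output pixel
#' `(floor(x*sr), floor(y*sr))`: native pixel i covers `[i, i+1)`, and the
#' super-resolution grid subdivides each native pixel into `sr` equal
#' sub-pixels.
#'
#' @param positions n x 2 matrix of (x, y) positions in native-pixel units.
#' @param dims native detector dims c(nx, ny).
#' @param sr_factor super-resolution factor (>= 1).
#' @param weights per-event weight, default 1.
#' @return A [counted_image()] whose array sums to `sum(weights)`.
#' @export
render_points <- function(positions, dims, sr_factor = 1L, weights = 1) {
  positions <- matrix(positions, ncol = 2L)
  sr <- as.integer(sr_factor)
  stopifnot(sr >= 1L)
  n <- nrow(positions)
  if (n > 0L && (any(positions[, 1L] < 0) || any(positions[, 1L] >= dims[1L]) ||
                 any(positions[, 2L] < 0) || any(positions[, 2L] >= dims[2L])))
    stop("event position out of bounds")
  out <- matrix(0, dims[1L] * sr, dims[2L] * sr)
  if (n > 0L) {
    ix <- floor(positions[, 1L] * sr)
    iy <- floor(positions[, 2L] * sr)
    w <- rep_len(weights, n)
    for (k in seq_len(n)) out[ix[k] + 1L, iy[k] + 1L] <-
        out[ix[k] + 1L, iy[k] + 1L] + w[k]
  }
  counted_image(out, sr, n)
}

#' Accumulate pattern events into a counted image
#'
#' Patterns are native-granularity: each member pixel of an event's pattern
#' adds its normalized value at that native pixel. With `sr_factor > 1` the
#' value lands in the central sub-pixel (offset `floor(sr/2)`) of the
#' aligned sr block.
#'
#' @param anchors n x 2 matrix of native anchor pixels (0-based integers).
#' @param patterns list of n pattern data.frames (`dx`, `dy`, `value`).
#' @param dims native detector dims.
#' @param sr_factor super-resolution factor.
#' @return A [counted_image()] summing to the number of events.
#' @export
render_patterns <- function(anchors, patterns, dims, sr_factor = 1L) {
  anchors <- matrix(anchors, ncol = 2L)
  sr <- as.integer(sr_factor)
  out <- matrix(0, dims[1L] * sr, dims[2L] * sr)
  mid <- sr %/% 2L
  for (k in seq_along(patterns)) {
    p <- patterns[[k]]
    px <- anchors[k, 1L] + p$dx
    py <- anchors[k, 2L] + p$dy
    if (any(px < 0 | px >= dims[1L] | py < 0 | py >= dims[2L]))
      stop("pattern pixel out of bounds")
    ii <- cbind(px * sr + mid + 1L, py * sr + mid + 1L)
    for (j in seq_len(nrow(ii)))
      out[ii[j, 1L], ii[j, 2L]] <- out[ii[j, 1L], ii[j, 2L]] + p$value[j]
  }
  counted_image(out, sr, length(patterns))
}

#' SNR weighting profile from two FSC-derived SNR curves
#'
#' `w(u) = sqrt(SNR2/SNR1) * sqrt(NPS1/NPS2)`: the per-shell weight that
#' maximizes the SNR of the sum of two images with different per-electron
#' SNR and noise spectra (class 2 is the one being weighted). Shells where
#' any input is non-positive get w = 0 with a warning.
#'
#' @param snr1,snr2 [radial_curve()]s of SNR on identical shells.
#' @param nps1,nps2 [radial_curve()]s of NPS on the same shells.
#' @return A `weight_profile`: radial_curve of w with `w(0)` prepended as 1
#'   if shell 0 is absent (total dose preserved when applied).
#' @export
snr_weight_profile <- function(snr1, snr2, nps1, nps2) {
  sh <- snr1$shells
  for (c2 in list(snr2, nps1, nps2))
    if (!isTRUE(all.equal(c2$shells, sh))) stop("curves on mismatched shells")
  bad <- snr1$values <= 0 | snr2$values <= 0 | nps1$values <= 0 |
         nps2$values <= 0
  w <- numeric(length(sh))
  w[!bad] <- sqrt(snr2$values[!bad] / snr1$values[!bad]) *
             sqrt(nps1$values[!bad] / nps2$values[!bad])
  if (any(bad))
    warning(sum(bad), " shell(s) with non-positive input; w clamped to 0")
  if (sh[1L] > 0) { sh <- c(0, sh); w <- c(1, w) }
  structure(radial_curve(sh, w), class = c("weight_profile", "radial_curve"))
}

#' Apply a radial frequency weight to a counted image
#'
#' Multiplies the image's discrete Fourier transform by `w(|u|)` (linear
#' interpolation between the profile's shells, end values held beyond the
#' sampled range) and inverts. `u` is in cycles per output-grid pixel. If
#' the profile does not sample u = 0 the DC weight defaults to 1, so the
#' event count is conserved.
#'
#' @param image a [counted_image()] (or plain matrix).
#' @param profile a [radial_curve()] of weights covering [0, 0.5 * sqrt(2)].
#' @return Weighted [counted_image()] (real-valued).
#' @export
apply_radial_weight <- function(image, profile) {
  arr <- if (inherits(image, "counted_image")) image$array else image
  nx <- nrow(arr); ny <- ncol(arr)
  fx <- c(0:(nx %/% 2), -(((nx + 1) %/% 2 - 1):1)) / nx
  if (nx == 1L) fx <- 0
  fy <- c(0:(ny %/% 2), -(((ny + 1) %/% 2 - 1):1)) / ny
  if (ny == 1L) fy <- 0
  u <- sqrt(outer(fx^2, fy^2, `+`))
  w <- matrix(approx(profile$shells, profile$values, xout = u,
                     rule = 2)$y, nx, ny)
  if (profile$shells[1L] > 0) w[1L, 1L] <- 1
  res <- Re(fft(fft(arr) * w, inverse = TRUE)) / (nx * ny)
  if (inherits(image, "counted_image"))
    counted_image(res, image$sr_factor, image$n_events)
  else res
}

.pca_pow_default <- c(small = 1, medium = 1, large = 0)

#' Count a movie stack with a chosen filter
#'
#' Runs [detect_stack()] and routes every cluster through the selected
#' counting rule:
#' \describe{
#'   \item{MCF / PVF / GCF}{one position rule for all clusters, rendered as
#'     points at `sr_factor`.}
#'   \item{PCA}{normalized patterns with a per-class `pow` (defaults: 1 for
#'     small/medium, 0 for large).}
#'   \item{WPF}{MCF points for small/medium clusters; PVF points for large
#'     clusters, marked `weight_flag = TRUE`; the large-cluster partial
#'     image is multiplied by the supplied radial weight profile in Fourier
#'     space before the partial images are summed.}
#'   \item{Hybrid}{MCF points for small/medium; uniform (`pow = 0`)
#'     patterns for large. No SNR weighting.}
#' }
#'
#' @param stack a [frame_stack()].
#' @param method one of "MCF", "PVF", "GCF", "PCA", "WPF", "Hybrid".
#' @param params a [detection_params()].
#' @param sr_factor super-resolution factor (default 2).
#' @param pow named per-class exponents for PCA, e.g.
#'   `c(small = 1, medium = 1, large = 0)`.
#' @param weight_profile a `weight_profile` (required for WPF).
#' @return list(image = [counted_image()], events = [event_stream()]).
#' @export
count_stack <- function(stack, method = c("MCF", "PVF", "GCF", "PCA", "WPF",
                                          "Hybrid"),
                        params = detection_params(), sr_factor = 2L,
                        pow = .pca_pow_default, weight_profile = NULL) {
  method <- match.arg(method)
  if (method == "WPF" && is.null(weight_profile))
    stop("WPF requires a weight_profile")
  dims <- frame_dims(stack)
  clusters <- detect_stack(stack, params)
  cls <- vapply(clusters, classify_cluster, character(1L))
  pos_rule <- switch(method, MCF = mcf_position, PVF = pvf_position,
                     GCF = gcf_position, NULL)
  n <- length(clusters)
  rec <- data.frame(frame_index = vapply(clusters, `[[`, 0L, "frame_index"),
                    x = numeric(n), y = numeric(n), size_class = cls,
                    weight_flag = FALSE)
  rec$pattern <- vector("list", n)

  if (method %in% c("MCF", "PVF", "GCF")) {
    pos <- t(vapply(clusters, pos_rule, numeric(2L)))
    if (n == 0L) pos <- matrix(0, 0, 2)
    rec$x <- pos[, 1L]; rec$y <- pos[, 2L]
    img <- render_points(pos, dims, sr_factor)
  } else if (method == "PCA") {
    pw <- .pca_pow_default; pw[names(pow)] <- pow
    pats <- lapply(seq_len(n), function(i)
      pca_pattern(clusters[[i]], pw[[cls[i]]]))
    anchors <- t(vapply(clusters, function(cl) floor(mcf_position(cl)),
                        numeric(2L)))
    if (n == 0L) anchors <- matrix(0, 0, 2)
    mc <- t(vapply(clusters, mcf_position, numeric(2L)))
    if (n > 0L) { rec$x <- mc[, 1L]; rec$y <- mc[, 2L] }
    rec$pattern <- pats
    img <- render_patterns(anchors, pats, dims, sr_factor)
  } else {                                   # WPF or Hybrid
    sm <- which(cls != "large"); lg <- which(cls == "large")
    pos_sm <- t(vapply(clusters[sm], mcf_position, numeric(2L)))
    if (length(sm) == 0L) pos_sm <- matrix(0, 0, 2)
    img_sm <- render_points(pos_sm, dims, sr_factor)
    if (length(sm) > 0L) { rec$x[sm] <- pos_sm[, 1L]; rec$y[sm] <- pos_sm[, 2L] }
    if (method == "WPF") {
      pos_lg <- t(vapply(clusters[lg], pvf_position, numeric(2L)))
      if (length(lg) == 0L) pos_lg <- matrix(0, 0, 2)
      img_lg <- render_points(pos_lg, dims, sr_factor)
      img_lg <- apply_radial_weight(img_lg, weight_profile)
      if (length(lg) > 0L) {
        rec$x[lg] <- pos_lg[, 1L]; rec$y[lg] <- pos_lg[, 2L]
        rec$weight_flag[lg] <- TRUE
      }
    } else {
      pats <- lapply(clusters[lg], pca_pattern, pow = 0)
      anchors <- t(vapply(clusters[lg], function(cl) floor(mcf_position(cl)),
                          numeric(2L)))
      if (length(lg) == 0L) anchors <- matrix(0, 0, 2)
      img_lg <- render_patterns(anchors, pats, dims, sr_factor)
      if (length(lg) > 0L) {
        mc <- t(vapply(clusters[lg], mcf_position, numeric(2L)))
        rec$x[lg] <- mc[, 1L]; rec$y[lg] <- mc[, 2L]
        rec$pattern[lg] <- pats
      }
    }
    img <- counted_image(img_sm$array + img_lg$array, as.integer(sr_factor), n)
  }
  ev <- event_stream(rec, dims, sr_factor, method, stack$voltage)
  list(image = img, events = ev)
}
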