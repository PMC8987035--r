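# Shared fixture builders. Everything is generated in code; no binary
# fixtures on disk.

# a small random stack of integer-ish frames
make_stack <- function(n_frames = 3L, nx = 16L, ny = 16L, seed = 1L) {
  set.seed(seed)
  frame_stack(lapply(seq_len(n_frames), function(i)
    matrix(rpois(nx * ny, 5), nx, ny)), pixel_size = 1.2)
}

# a cluster object as produced by detect_events; `pixels` is an n x 2
# matrix or a flat c(x1, y1, x2, y2, ...) vector
make_cluster <- function(pixels, values, frame_index = 0L) {
  px <- if (is.matrix(pixels)) pixels
        else matrix(as.integer(pixels), ncol = 2L, byrow = TRUE)
  storage.mode(px) <- "integer"
  n <- nrow(px)
  list(pixels = px, values = rep_len(as.numeric(values), n),
       frame_index = as.integer(frame_index))
}

# random event records (optionally with patterns)
make_records <- function(n, dims = c(64L, 64L), with_patterns = FALSE,
                         seed = 1L) {
  set.seed(seed)
  rec <- data.frame(
    frame_index = sort(sample.int(10L, n, replace = TRUE)) - 1L,
    x = runif(n, 0, dims[1L] - 1e-6),
    y = runif(n, 0, dims[2L] - 1e-6),
    size_class = sample(c("small", "medium", "large"), n, replace = TRUE),
    weight_flag = sample(c(TRUE, FALSE), n, replace = TRUE))
  rec$pattern <- lapply(seq_len(n), function(i) {
    if (!with_patterns || i %% 3 != 0L) return(NULL)
    k <- sample(2:5, 1L)
    v <- runif(k); v <- v / sum(v)
    data.frame(dx = sample(-2:2, k, replace = TRUE),
               dy = sample(-2:2, k, replace = TRUE), value = v)
  })
  rec
}

# analytic slanted-edge image: pixel value = fraction of the pixel
# footprint [i-0.5, i+0.5) lying on the open side of the edge line
# x = c0 + tan(angle) * (y - cy), optionally convolved with a Gaussian of
# width sigma_blur along the edge normal (sampled, not integrated).
make_edge_image <- function(nx = 96L, ny = 96L, angle_deg = 3,
                            sigma_blur = 0) {
  tn <- tan(angle_deg * pi / 180)
  cx <- nx / 2; cy <- ny / 2
  xs <- matrix(0:(nx - 1L), nx, ny)
  ys <- matrix(0:(ny - 1L), nx, ny, byrow = TRUE)
  d <- (xs - cx - tn * (ys - cy)) / sqrt(1 + tn^2)  # signed normal distance
  if (sigma_blur > 0) {
    pnorm(d / sigma_blur)
  } else {
    pmin(pmax(d + 0.5, 0), 1)                       # pixel-aperture edge
  }
}

# truth events that have no neighbour within `radius` px in the same frame
isolated_truth <- function(truth, radius = 3) {
  keep <- rep(TRUE, nrow(truth))
  for (f in unique(truth$frame_index)) {
    idx <- which(truth$frame_index == f)
    if (length(idx) < 2L) next
    dd <- as.matrix(dist(cbind(truth$x[idx], truth$y[idx])))
    diag(dd) <- Inf
    keep[idx[apply(dd, 1L, min) < radius]] <- FALSE
  }
  truth[keep, , drop = FALSE]
}
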