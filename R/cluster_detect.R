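# Single-electron event detection in raw DDD frames.
#
# A fast electron deposits charge in a small group of neighbouring pixels
# (a "cluster"). Detection runs a negated Laplacian-of-Gaussian filter over
# the raw frame, thresholds the response at a robust multiple of the noise
# sigma, groups marked pixels into connected components, and keeps each
# interior component as one candidate event.

#' Detection parameters
#'
#' @param kernel_sigma Gaussian scale of the blob filter, pixels.
#' @param kernel_radius half-width of the kernel; kernel is
#'   `(2*radius+1)^2`.
#' @param threshold_k threshold as a multiple of the robust noise sigma of
#'   the filtered frame.
#' @param connectivity pixel adjacency for component grouping: 4 or 8.
#' @param min_sigma absolute floor (counts) for the noise-sigma estimate:
#'   one detector count by default, the quantization scale of the readout,
#'   so noiseless frames (robust sigma 0) still threshold sensibly.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(kernel_sigma = 0.8, kernel_radius = 1L,
                             threshold_k = 4.0, connectivity = 8L,
                             min_sigma = 1.0) {
  stopifnot(kernel_sigma > 0, kernel_radius >= 1, threshold_k > 0,
            connectivity %in% c(4L, 8L), min_sigma > 0)
  structure(list(kernel_sigma = kernel_sigma,
                 kernel_radius = as.integer(kernel_radius),
                 threshold_k = threshold_k,
                 connectivity = as.integer(connectivity),
                 min_sigma = min_sigma),
            class = "detection_params")
}

#' Negated Laplacian-of-Gaussian blob kernel
#'
#' Samples -LoG(x, y; sigma) at integer offsets in
#' `[-radius, radius]^2` and shifts the result to zero sum, so the response
#' to any constant image is exactly 0 and the central value is positive
#' (bright blobs give positive responses).
#'
#' @param sigma Gaussian scale in pixels (> 0).
#' @param radius kernel half-width in pixels (>= 1).
#' @return A `(2*radius+1)` square numeric matrix summing to 0.
#' @export
log_kernel <- function(sigma = 0.8, radius = 1L) {
  stopifnot(sigma > 0, radius >= 1)
  off <- seq.int(-radius, radius)
  r2 <- outer(off^2, off^2, `+`)
  # -LoG = (2 - r^2/sigma^2)/sigma^2 * gaussian (positive at the centre)
  k <- (2 - r2 / sigma^2) / sigma^2 * exp(-r2 / (2 * sigma^2))
  k - mean(k)
}

# FFT convolution with circular boundary (EBImage); border clusters are
# discarded downstream, so wrap-around cannot leak into kept events.
.convolve_frame <- function(frame, kernel) {
  EBImage::filter2(frame, kernel, boundary = "circular")
}

# Connectivity-generic connected-component labelling on a set of marked
# pixels: build the adjacency among marked coordinates by hashed coordinate
# matching and take graph components.
.label_components <- function(idx_xy, dims, connectivity) {
  n <- nrow(idx_xy)
  if (n == 0L) return(integer(0))
  key <- idx_xy[, 1L] + dims[1L] * idx_xy[, 2L]   # unique encode, 0-based
  offs <- if (connectivity == 4L)
    rbind(c(1L, 0L), c(0L, 1L))
  else
    rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    nb_key <- (idx_xy[, 1L] + offs[k, 1L]) + dims[1L] * (idx_xy[, 2L] + offs[k, 2L])
    ok <- idx_xy[, 1L] + offs[k, 1L] >= 0 & idx_xy[, 1L] + offs[k, 1L] < dims[1L] &
          idx_xy[, 2L] + offs[k, 2L] >= 0 & idx_xy[, 2L] + offs[k, 2L] < dims[2L]
    m <- match(nb_key, key)
    hit <- which(ok & !is.na(m))
    if (length(hit)) edges <- rbind(edges, cbind(hit, m[hit]))
  }
  g <- igraph::graph_from_edgelist(
    rbind(edges, cbind(seq_len(n), seq_len(n))), directed = FALSE)
  igraph::components(g)$membership[seq_len(n)]
}

#' Detect single-electron clusters in one raw frame
#'
#' Pipeline: (i) convolve with [log_kernel()]; (ii) estimate the noise sigma
#' of the filtered frame robustly (median absolute deviation x 1.4826);
#' (iii) mark pixels whose filtered value exceeds `threshold_k * sigma`;
#' (iv) group marked pixels into connected components; (v) each interior
#' component becomes a cluster whose pixel values are the raw values minus
#' the raw-frame median, floored at 1e-6 (so value-weighted estimators and
#' negative `pow` exponents stay defined). Components touching the frame
#' border are discarded: a truncated charge footprint biases every position
#' estimator.
#'
#' @param frame numeric matrix (raw detector counts).
#' @param params a [detection_params()].
#' @param frame_index 0-based frame index recorded on each cluster.
#' @return List of clusters; each is a list with `pixels` (n x 2 integer
#'   matrix of 0-based (x, y)), `values` (positive numeric), `frame_index`.
#' @export
detect_events <- function(frame, params = detection_params(),
                          frame_index = 0L) {
  stopifnot(is.matrix(frame))
  kern <- log_kernel(params$kernel_sigma, params$kernel_radius)
  if (any(dim(frame) < dim(kern))) stop("frame smaller than kernel")
  conv <- .convolve_frame(frame, kern)
  sigma <- max(mad(conv, center = median(conv)), params$min_sigma)
  marked <- which(conv > params$threshold_k * sigma, arr.ind = TRUE)
  if (nrow(marked) == 0L) return(list())
  xy <- cbind(marked[, 1L] - 1L, marked[, 2L] - 1L)   # 0-based
  lab <- .label_components(xy, dim(frame), params$connectivity)
  med <- median(frame)
  out <- list()
  for (comp in split(seq_len(nrow(xy)), lab)) {
    px <- xy[comp, , drop = FALSE]
    if (any(px[, 1L] == 0L) || any(px[, 1L] == dim(frame)[1L] - 1L) ||
        any(px[, 2L] == 0L) || any(px[, 2L] == dim(frame)[2L] - 1L))
      next                                  # border cluster
    vals <- pmax(frame[px + 1L] - med, 1e-6)
    out[[length(out) + 1L]] <- list(pixels = px, values = vals,
                                    frame_index = as.integer(frame_index))
  }
  out
}

#' Detect clusters in every frame of a stack
#'
#' @param stack a [frame_stack()].
#' @param params a [detection_params()].
#' @return Flat list of clusters with their `frame_index` set.
#' @export
detect_stack <- function(stack, params = detection_params()) {
  stopifnot(inherits(stack, "frame_stack"))
  out <- lapply(seq_len(n_frames(stack)) - 1L, function(k)
    detect_events(stack$frames[[k + 1L]], params, frame_index = k))
  do.call(c, out)
}

#' Classify a cluster by footprint size
#'
#' 1-2 pixels are "small", 3-4 "medium", 5 or more "large". The split
#' follows the empirical break in positional accuracy: events with large
#' footprints (typically carrying backscatter background) localize much
#' worse than compact ones.
#'
#' @param cluster a cluster from [detect_events()].
#' @return `"small"`, `"medium"` or `"large"`.
#' @export
classify_cluster <- function(cluster) {
  n <- nrow(cluster$pixels)
  stopifnot(n >= 1L)
  if (n <= 2L) "small" else if (n <= 4L) "medium" else "large"
}

#' Partition clusters by size class, optionally subsampling each class
#'
#' @param clusters list of clusters.
#' @param subsample_per_class if given, draw exactly this many clusters per
#'   class without replacement.
#' @param seed RNG seed used for the subsampling draw.
#' @return Named list `small`, `medium`, `large` of cluster lists.
#' @export
split_by_class <- function(clusters, subsample_per_class = NULL, seed = 1L) {
  cls <- vapply(clusters, classify_cluster, character(1L))
  parts <- lapply(size_classes, function(s) clusters[cls == s])
  names(parts) <- size_classes
  if (!is.null(subsample_per_class)) {
    m <- as.integer(subsample_per_class)
    for (s in size_classes)
      if (length(parts[[s]]) < m)
        stop(sprintf("class '%s' has %d clusters, %d requested",
                     s, length(parts[[s]]), m))
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    parts <- lapply(parts, function(p) p[sample.int(length(p), m)])
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    names(parts) <- size_classes
  }
  parts
}
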