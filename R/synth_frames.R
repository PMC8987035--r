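# Synthetic raw-frame generator with ground truth.
#
# Emulates the statistical structure of pre-counting DDD movies: sparse
# Poisson electron arrivals; a per-event integrated-Gaussian charge cloud
# whose amplitude follows a heavy-tailed (log-normal) energy-loss spread;
# for a fraction of events an additional displaced, broader, weaker blob
# standing in for backscattered-electron background; Gaussian read noise
# and a per-pixel gain map. Ground-truth incident positions are recorded
# so detection recall and position error are measurable exactly.

#' Detector model for synthetic frame generation
#'
#' @param dims detector dims c(nx, ny), pixels.
#' @param gain_map per-pixel multiplier matrix (default identity).
#' @param read_noise_sigma Gaussian read noise, counts.
#' @param charge_cloud_sigma width of the primary charge cloud, px.
#' @param cloud_amplitude mean integrated cloud signal, counts.
#' @param amp_sdlog log-normal sdlog of the amplitude spread (heavy-tailed
#'   stand-in for the Landau energy-loss distribution; mean preserved).
#' @param bse_probability fraction of events with a displaced backscatter
#'   blob.
#' @param bse_offset radial-offset distribution of the blob: a single mean
#'   (px) for an exponential draw; a length-2 `c(shape, scale)` for a gamma
#'   draw (the gamma default approximates the simulated backscatter
#'   exit-radius shape at 14-um pixels); or a longer numeric vector of
#'   radii (px) sampled empirically — e.g. a [simulate_bse()] `exit_radii`
#'   vector scaled to pixels.
#' @param bse_sigma width of the blob, px.
#' @param bse_amplitude_fraction blob amplitude relative to the primary.
#' @export
detector_model <- function(dims = c(128L, 128L), gain_map = NULL,
                           read_noise_sigma = 1, charge_cloud_sigma = 0.4,
                           cloud_amplitude = 20, amp_sdlog = 0.3,
                           bse_probability = 0.1, bse_offset = 1.5,
                           bse_sigma = 0.9, bse_amplitude_fraction = 0.35) {
  stopifnot(length(dims) == 2L, all(dims > 7),
            bse_probability >= 0, bse_probability <= 1,
            read_noise_sigma >= 0, charge_cloud_sigma >= 0)
  structure(list(dims = as.integer(dims), gain_map = gain_map,
                 read_noise_sigma = read_noise_sigma,
                 charge_cloud_sigma = charge_cloud_sigma,
                 cloud_amplitude = cloud_amplitude, amp_sdlog = amp_sdlog,
                 bse_probability = bse_probability, bse_offset = bse_offset,
                 bse_sigma = bse_sigma,
                 bse_amplitude_fraction = bse_amplitude_fraction),
            class = "detector_model")
}

# Integrated Gaussian: signal A centred at continuous (x, y), sigma s.
# Pixel i is centred at coordinate i with footprint [i - 0.5, i + 0.5), so
# an event exactly at an integer position deposits symmetrically into that
# pixel. Added in place.
.deposit_cloud <- function(frame, x, y, A, s, dims) {
  if (s < 1e-3) {                       # point deposit
    ix <- round(x); iy <- round(y)
    if (ix >= 0 && ix < dims[1L] && iy >= 0 && iy < dims[2L])
      frame[ix + 1L, iy + 1L] <- frame[ix + 1L, iy + 1L] + A
    return(frame)
  }
  r <- ceiling(3 * s) + 1L
  xlo <- max(0L, round(x) - r); xhi <- min(dims[1L] - 1L, round(x) + r)
  ylo <- max(0L, round(y) - r); yhi <- min(dims[2L] - 1L, round(y) + r)
  if (xlo > xhi || ylo > yhi) return(frame)
  ix <- xlo:xhi; iy <- ylo:yhi
  wx <- pnorm(ix + 0.5, x, s) - pnorm(ix - 0.5, x, s)
  wy <- pnorm(iy + 0.5, y, s) - pnorm(iy - 0.5, y, s)
  frame[ix + 1L, iy + 1L] <- frame[ix + 1L, iy + 1L] + A * outer(wx, wy)
  frame
}

.draw_bse_offset <- function(model, k) {
  b <- model$bse_offset
  if (length(b) == 1L) rexp(k, rate = 1 / b)
  else if (length(b) == 2L) stats::rgamma(k, shape = b[1L], scale = b[2L])
  else sample(b, k, replace = TRUE)
}

#' Generate a synthetic raw movie stack with ground truth
#'
#' Per frame the event count is Poisson(`dose_rate * n_pixels`), positions
#' are uniform, and each event deposits an integrated-Gaussian charge
#' cloud. With probability `bse_probability` a second broader, weaker blob
#' is added at a random radial offset. Read noise and gain are applied
#' last. Reproducible from `seed`.
#'
#' @param model a [detector_model()].
#' @param dose_rate events/pixel/frame (> 0).
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param intensity optional non-negative matrix (detector dims) of
#'   relative event density: positions are drawn per pixel proportional to
#'   it (uniform within the pixel), emulating a structured specimen
#'   instead of a flat field.
#' @return list(stack = [frame_stack()], truth = data.frame with
#'   `frame_index`, `x`, `y`, `had_bse`).
#' @export
generate_frame_stack <- function(model, dose_rate = 0.01, n_frames = 10L,
                                 seed = 1L, intensity = NULL) {
  stopifnot(dose_rate > 0, n_frames >= 1L)
  set.seed(seed)
  dims <- model$dims
  npx <- prod(dims)
  if (!is.null(intensity)) {
    stopifnot(identical(dim(intensity), dim(matrix(0, dims[1L], dims[2L]))),
              all(intensity >= 0), sum(intensity) > 0)
    ip <- as.vector(intensity) / sum(intensity)
  }
  frames <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  n_close <- 0L; n_tot <- 0L
  for (f in seq_len(n_frames)) {
    k <- rpois(1L, dose_rate * npx)
    if (is.null(intensity)) {
      x <- runif(k, 0, dims[1L]); y <- runif(k, 0, dims[2L])
    } else {
      px <- sample.int(npx, k, replace = TRUE, prob = ip) - 1L
      x <- px %% dims[1L] + runif(k) - 0.5
      y <- px %/% dims[1L] + runif(k) - 0.5
      x <- pmin(pmax(x, 0), dims[1L] - 1e-9)
      y <- pmin(pmax(y, 0), dims[2L] - 1e-9)
    }
    amp <- model$cloud_amplitude *
      rlnorm(k, meanlog = -model$amp_sdlog^2 / 2, sdlog = model$amp_sdlog)
    bse <- runif(k) < model$bse_probability
    fr <- matrix(0, dims[1L], dims[2L])
    for (i in seq_len(k))
      fr <- .deposit_cloud(fr, x[i], y[i], amp[i],
                           model$charge_cloud_sigma, dims)
    if (any(bse)) {
      off <- .draw_bse_offset(model, sum(bse))
      ang <- runif(sum(bse), 0, 2 * pi)
      bx <- x[bse] + off * cos(ang); by <- y[bse] + off * sin(ang)
      ab <- amp[bse] * model$bse_amplitude_fraction
      for (i in seq_along(bx))
        fr <- .deposit_cloud(fr, bx[i], by[i], ab[i], model$bse_sigma, dims)
    }
    if (model$read_noise_sigma > 0)
      fr <- fr + matrix(rnorm(npx, 0, model$read_noise_sigma),
                        dims[1L], dims[2L])
    if (!is.null(model$gain_map)) fr <- fr * model$gain_map
    frames[[f]] <- fr
    truth[[f]] <- data.frame(frame_index = f - 1L, x = x, y = y,
                             had_bse = bse)
    if (k > 1L) {
      dd <- as.matrix(dist(cbind(x, y)))
      diag(dd) <- Inf
      n_close <- n_close + sum(apply(dd, 1L, min) < 2)
      n_tot <- n_tot + k
    }
  }
  if (n_tot > 0L && n_close / n_tot > 0.2)
    warning("coincidence regime: >20% of events overlap within 2 px")
  list(stack = frame_stack(frames, pixel_size = 1.0),
       truth = do.call(rbind, truth))
}

#' Generate a knife-edge stack (events only on one half-plane)
#'
#' As [generate_frame_stack()] but events falling on the blocked side of a
#' straight edge through the frame centre (tilted by `edge_angle` degrees
#' from the y axis) are removed, so the open-half event density equals
#' `dose_rate`.
#'
#' @inheritParams generate_frame_stack
#' @param edge_angle edge tilt in degrees, |angle| <= 10.
#' @return A [frame_stack()].
#' @export
generate_knife_edge_stack <- function(model, dose_rate = 0.01,
                                      n_frames = 10L, edge_angle = 3,
                                      seed = 1L) {
  stopifnot(abs(edge_angle) <= 10)
  set.seed(seed)
  dims <- model$dims
  npx <- prod(dims)
  cx <- dims[1L] / 2; cy <- dims[2L] / 2
  tn <- tan(edge_angle * pi / 180)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    k <- rpois(1L, dose_rate * npx)
    x <- runif(k, 0, dims[1L]); y <- runif(k, 0, dims[2L])
    open <- x > cx + tn * (y - cy)            # open half-plane
    x <- x[open]; y <- y[open]
    amp <- model$cloud_amplitude *
      rlnorm(length(x), meanlog = -model$amp_sdlog^2 / 2,
             sdlog = model$amp_sdlog)
    fr <- matrix(0, dims[1L], dims[2L])
    for (i in seq_along(x))
      fr <- .deposit_cloud(fr, x[i], y[i], amp[i],
                           model$charge_cloud_sigma, dims)
    if (model$read_noise_sigma > 0)
      fr <- fr + matrix(rnorm(npx, 0, model$read_noise_sigma),
                        dims[1L], dims[2L])
    if (!is.null(model$gain_map)) fr <- fr * model$gain_map
    frames[[f]] <- fr
  }
  frame_stack(frames, pixel_size = 1.0)
}

#' Tune a detector model to target size-class fractions
#'
#' Coarse grid search followed by local refinement over
#' (`charge_cloud_sigma`, `bse_probability`, `cloud_amplitude`), minimizing
#' the L1 distance between detected small/medium/large fractions and the
#' target. The targets of interest are the measured per-voltage cluster
#' statistics (e.g. 33.8/38.6/27.6% at 120 kV).
#'
#' @param target_fractions numeric c(small, medium, large), summing to 1.
#' @param base_model starting [detector_model()] (dims, noise reused).
#' @param dose_rate,n_frames stack size per objective evaluation.
#' @param params [detection_params()] used in the objective.
#' @param search_budget maximum number of objective evaluations.
#' @param seed seed for the evaluation stacks.
#' @return list: `model`, `achieved` (fractions), `l1`; error if the best
#'   L1 exceeds 0.15.
#' @export
tune_to_class_fractions <- function(target_fractions,
                                    base_model = detector_model(
                                      dims = c(96L, 96L), amp_sdlog = 0.5,
                                      bse_sigma = 0.55,
                                      bse_offset = c(9, 0.2),
                                      bse_amplitude_fraction = 1.0),
                                    dose_rate = 0.005, n_frames = 20L,
                                    params = detection_params(),
                                    search_budget = 90L, seed = 7L) {
  stopifnot(length(target_fractions) == 3L,
            abs(sum(target_fractions) - 1) < 1e-6)
  evals <- 0L
  objective <- function(sigma, bp, amp) {
    m <- base_model
    m$charge_cloud_sigma <- sigma; m$bse_probability <- bp
    m$cloud_amplitude <- amp
    g <- generate_frame_stack(m, dose_rate, n_frames, seed = seed)
    cl <- detect_stack(g$stack, params)
    evals <<- evals + 1L
    if (length(cl) == 0L) return(list(l1 = 2, frac = c(0, 0, 0), model = m))
    cls <- vapply(cl, classify_cluster, character(1L))
    frac <- as.numeric(table(factor(cls, levels = size_classes))) / length(cl)
    list(l1 = sum(abs(frac - target_fractions)), frac = frac, model = m)
  }
  grid <- expand.grid(sigma = c(0.22, 0.3, 0.4),
                      bp = c(0.05, 0.25, 0.5, 0.8),
                      amp = c(50, 100, 160))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    if (evals >= search_budget) break
    r <- objective(grid$sigma[i], grid$bp[i], grid$amp[i])
    if (is.null(best) || r$l1 < best$l1) best <- r
  }
  # local coordinate refinement with shrinking steps
  step <- c(sigma = 0.05, bp = 0.1, amp = 25)
  cur <- c(sigma = best$model$charge_cloud_sigma,
           bp = best$model$bse_probability,
           amp = best$model$cloud_amplitude)
  while (evals < search_budget && best$l1 > 0.02) {
    improved <- FALSE
    for (par in names(cur)) {
      for (dir in c(-1, 1)) {
        if (evals >= search_budget) break
        cand <- cur
        cand[par] <- cand[par] + dir * step[par]
        if (par == "sigma" && (cand[par] < 0.05 || cand[par] > 1.2)) next
        if (par == "bp" && (cand[par] < 0 || cand[par] > 0.95)) next
        if (par == "amp" && cand[par] < 5) next
        r <- objective(cand[["sigma"]], cand[["bp"]], cand[["amp"]])
        if (r$l1 < best$l1 - 1e-9) {
          best <- r; cur <- cand; improved <- TRUE
        }
      }
    }
    if (!improved) {
      step <- step / 2
      if (all(step < c(0.01, 0.02, 3))) break
    }
  }
  if (best$l1 > 0.15)
    stop(sprintf("tuning budget exhausted at L1 = %.3f (target 0.15)",
                 best$l1))
  list(model = best$model, achieved = best$frac, l1 = best$l1,
       evaluations = evals)
}

#' Match counted events against ground truth and summarize position error
#'
#' Greedy nearest-neighbour matching per frame within `match_radius`:
#' candidate pairs are sorted by distance and assigned one-to-one. Reports
#' RMSE and bias of matched pairs and the match rate, overall and per size
#' class.
#'
#' @param events an [event_stream()].
#' @param truth ground-truth data.frame from [generate_frame_stack()].
#' @param match_radius maximum pairing distance, px (default 2).
#' @param exclude_border truth events (and counted events) within this many
#'   pixels of the frame edge are dropped before matching, mirroring the
#'   border-cluster discard in detection (default 3).
#' @return list: `overall` (rmse, bias_x, bias_y, match_rate,
#'   n_matched), `by_class` (data.frame per size class),
#'   `unmatched_events` fraction.
#' @export
position_error_stats <- function(events, truth, match_radius = 2,
                                 exclude_border = 3) {
  stopifnot(inherits(events, "event_stream"))
  r <- events$records
  if (nrow(r) == 0L || nrow(truth) == 0L) stop("empty events or truth")
  if (exclude_border > 0) {
    d <- events$header$dims
    inb <- function(x, y) x >= exclude_border & x < d[1L] - exclude_border &
                          y >= exclude_border & y < d[2L] - exclude_border
    truth <- truth[inb(truth$x, truth$y), , drop = FALSE]
    r <- r[inb(r$x, r$y), , drop = FALSE]
    if (nrow(r) == 0L || nrow(truth) == 0L) stop("empty events or truth")
  }
  matched <- vector("list", 0L)
  n_ev_matched <- 0L
  for (f in sort(unique(truth$frame_index))) {
    te <- truth[truth$frame_index == f, , drop = FALSE]
    ev <- r[r$frame_index == f, , drop = FALSE]
    if (nrow(ev) == 0L) next
    d <- outer(ev$x, te$x, `-`)^2 + outer(ev$y, te$y, `-`)^2
    cand <- which(d <= match_radius^2, arr.ind = TRUE)
    if (nrow(cand) == 0L) next
    cand <- cand[order(d[cand]), , drop = FALSE]
    used_e <- logical(nrow(ev)); used_t <- logical(nrow(te))
    for (i in seq_len(nrow(cand))) {
      ei <- cand[i, 1L]; ti <- cand[i, 2L]
      if (used_e[ei] || used_t[ti]) next
      used_e[ei] <- TRUE; used_t[ti] <- TRUE
      matched[[length(matched) + 1L]] <- data.frame(
        dx = ev$x[ei] - te$x[ti], dy = ev$y[ei] - te$y[ti],
        size_class = ev$size_class[ei], had_bse = te$had_bse[ti])
    }
    n_ev_matched <- n_ev_matched + sum(used_e)
  }
  if (length(matched) == 0L)
    return(list(overall = list(rmse = NA_real_, bias_x = NA_real_,
                               bias_y = NA_real_, match_rate = 0,
                               n_matched = 0L),
                by_class = NULL, unmatched_events = 1))
  mm <- do.call(rbind, matched)
  summ <- function(df) list(
    rmse = sqrt(mean(df$dx^2 + df$dy^2)),
    bias_x = mean(df$dx), bias_y = mean(df$dy),
    n_matched = nrow(df))
  ov <- summ(mm)
  ov$match_rate <- nrow(mm) / nrow(truth)
  bc <- do.call(rbind, lapply(size_classes, function(s) {
    sub <- mm[mm$size_class == s, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    data.frame(size_class = s, rmse = sqrt(mean(sub$dx^2 + sub$dy^2)),
               bias_x = mean(sub$dx), bias_y = mean(sub$dy),
               n_matched = nrow(sub))
  }))
  list(overall = ov, by_class = bc,
       unmatched_events = 1 - n_ev_matched / nrow(r))
}

#' Preset detector models emulating per-voltage cluster statistics
#'
#' Fixed parameter sets (found once with [tune_to_class_fractions()]
#' against the measured per-voltage small/medium/large fractions) for
#' quick construction of realistic stacks: higher-voltage electrons make
#' smaller clusters and far fewer backscatter events.
#'
#' @param preset "120kv", "200kv" or "300kv".
#' @param dims detector dims.
#' @return A [detector_model()].
#' @export
preset_model <- function(preset = c("120kv", "200kv", "300kv"),
                         dims = c(128L, 128L)) {
  preset <- match.arg(preset)
  p <- switch(preset,
    "120kv" = list(sigma = 0.431, bp = 0.788, amp = 96.9),
    "200kv" = list(sigma = 0.226, bp = 0.475, amp = 100),
    "300kv" = list(sigma = 0.300, bp = 0.800, amp = 50))
  detector_model(dims = dims, charge_cloud_sigma = p$sigma,
                 bse_probability = p$bp, cloud_amplitude = p$amp,
                 amp_sdlog = 0.5, bse_sigma = 0.55, bse_offset = c(9, 0.2),
                 bse_amplitude_fraction = 1.0)
}
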