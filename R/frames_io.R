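#' @useDynLib lowvoltcount, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft mad median rnorm runif rpois rlnorm rexp quantile coef lm sd setNames approx optimize
#' @importFrom utils head tail
"_PACKAGE"

# ---------------------------------------------------------------------------
# Coordinate convention (used everywhere in this package):
# pixel indices are 0-based and a pixel's centre sits at integer coordinates
# (pixel (i, j) has footprint [i-0.5, i+0.5) x [j-0.5, j+0.5)). Continuous
# event positions live in this frame; position estimators therefore return
# plain value-weighted arithmetic on pixel indices. Rendering uses the fixed
# mapping sub-pixel = floor(x * sr_factor) - a uniform half-sub-pixel offset
# relative to the centre convention that cancels in every difference-based
# metric (FRC, RMSE, aggregation). Frames are stored as R matrices with the
# first (row) index = x (fastest-varying axis on disk), second index = y.
# ---------------------------------------------------------------------------

#' Construct a frame stack
#'
#' A `frame_stack` holds an ordered list of equally sized 2-D pixel arrays
#' from a direct-detection camera before counting, together with pixel-size
#' and (optional) acceleration-voltage metadata.
#'
#' @param frames list of numeric matrices with identical dimensions.
#' @param pixel_size length per pixel (Angstrom); `NA` allowed.
#' @param voltage acceleration voltage in volts, or `NA`.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_size = NA_real_, voltage = NA_real_) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("`frames` must be a non-empty list of matrices")
  d <- dim(frames[[1L]])
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (!is.matrix(f) || !identical(dim(f), d))
      stop("all frames must be matrices with identical dimensions")
    if (!all(is.finite(f))) stop("frame pixel values must be finite")
    if (!is.double(f)) { storage.mode(f) <- "double"; frames[[k]] <- f }
  }
  structure(list(frames = frames, pixel_size = pixel_size, voltage = voltage),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("frame_stack: %d frame(s) of %d x %d px, pixel size %s A\n",
              length(x$frames), d[1L], d[2L],
              ifelse(is.na(x$pixel_size), "?", format(x$pixel_size))))
  invisible(x)
}

n_frames <- function(stack) length(stack$frames)
frame_dims <- function(stack) dim(stack$frames[[1L]])

# ---- MRC/MRCS I/O ----------------------------------------------------------
# Minimal MRC2014 implementation: modes 0 (int8), 1 (int16), 2 (float32),
# little-endian, no extended header on write. Pixel size is stored as
# cella/mx per axis.

.mrc_mode_bytes <- c(`0` = 1L, `1` = 2L, `2` = 4L)

#' Read an MRC/MRCS movie stack
#'
#' Frames are returned in file order; the x axis is the fastest-varying
#' (column) axis of the file and maps to the first matrix index.
#'
#' @param path path to an MRC or MRCS file (modes 0, 1, 2).
#' @param gain optional multiplicative gain map (matrix matching the frame
#'   dimensions) applied to every frame on read; default identity.
#' @return A [frame_stack()].
#' @export
read_stack <- function(path, gain = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  fsize <- file.info(path)$size
  if (fsize < 1024) stop("malformed MRC header: file shorter than 1024 bytes")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_i <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  nx <- hdr_i[1L]; ny <- hdr_i[2L]; nz <- hdr_i[3L]; mode <- hdr_i[4L]
  mx <- hdr_i[8L]; my <- hdr_i[9L]; mz <- hdr_i[10L]
  cella <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  seek(con, 4 * 23)                         # nsymbt is word 24 (0-based 23)
  nsymbt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (nx < 1 || ny < 1 || mode < 0) stop("malformed MRC header")
  if (nz < 1) stop("empty stack: nz < 1")
  if (!as.character(mode) %in% names(.mrc_mode_bytes))
    stop("unsupported MRC mode: ", mode)
  bpx <- .mrc_mode_bytes[[as.character(mode)]]
  need <- 1024 + nsymbt + as.numeric(nx) * ny * nz * bpx
  if (fsize < need)
    stop(sprintf("malformed MRC file: %d bytes, header implies >= %.0f", fsize, need))
  px <- if (mx > 0 && cella[1L] > 0) cella[1L] / mx else {
    warning("MRC header has no pixel size; assuming 1.0")
    1.0
  }
  seek(con, 1024 + nsymbt)
  frames <- vector("list", nz)
  for (k in seq_len(nz)) {
    v <- if (mode == 2L)
      readBin(con, "numeric", n = nx * ny, size = 4L, endian = "little")
    else
      readBin(con, "integer", n = nx * ny, size = bpx, endian = "little",
              signed = TRUE)
    f <- matrix(as.numeric(v), nrow = nx, ncol = ny)
    if (!is.null(gain)) {
      if (!identical(dim(gain), dim(f))) stop("gain map dimensions mismatch")
      f <- f * gain
    }
    frames[[k]] <- f
  }
  frame_stack(frames, pixel_size = px)
}

#' Write a frame stack (or single counted image) as MRC/MRCS
#'
#' @param stack a [frame_stack()] or a single matrix.
#' @param path output path.
#' @param mode MRC data mode: 1 (int16) or 2 (float32). Default 2.
#' @export
write_stack <- function(stack, path, mode = 2L) {
  if (is.matrix(stack)) stack <- frame_stack(list(stack))
  stopifnot(inherits(stack, "frame_stack"), mode %in% c(1L, 2L))
  d <- frame_dims(stack); nz <- n_frames(stack)
  px <- if (is.na(stack$pixel_size)) 1.0 else stack$pixel_size
  all_v <- unlist(lapply(stack$frames, as.vector), use.names = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d[1L], d[2L], nz, mode, 0L, 0L, 0L,
                        d[1L], d[2L], nz)), con, size = 4L, endian = "little")
  writeBin(c(px * d[1L], px * d[2L], px * nz, 90, 90, 90), con, size = 4L,
           endian = "little")
  writeBin(c(1L, 2L, 3L), con, size = 4L, endian = "little")      # mapc/r/s
  writeBin(c(min(all_v), max(all_v), mean(all_v)), con, size = 4L,
           endian = "little")
  writeBin(c(0L, 0L), con, size = 4L, endian = "little")          # ispg, nsymbt
  writeBin(raw(100), con)                                         # extra
  writeBin(c(0, 0, 0), con, size = 4L, endian = "little")         # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)                # machst LE
  writeBin(sd(all_v), con, size = 4L, endian = "little")          # rms
  writeBin(0L, con, size = 4L, endian = "little")                 # nlabl
  writeBin(raw(800), con)                                         # labels
  if (mode == 2L) {
    writeBin(as.numeric(all_v), con, size = 4L, endian = "little")
  } else {
    if (any(abs(all_v - round(all_v)) > 1e-6))
      warning("non-integer pixel values rounded for mode-1 output")
    writeBin(as.integer(round(all_v)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Sum consecutive movie frames
#'
#' Groups frames in file order into blocks of up to `p` consecutive frames and
#' sums each block elementwise, conserving the total pixel sum. `p = 1`
#' returns an identical stack.
#'
#' @param stack a [frame_stack()].
#' @param p number of consecutive frames per output frame (>= 1).
#' @return A [frame_stack()] with `ceiling(n/p)` frames.
#' @export
sum_frames <- function(stack, p) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!is.numeric(p) || length(p) != 1L || p < 1 || p != round(p))
    stop("`p` must be an integer >= 1")
  p <- as.integer(p)
  n <- n_frames(stack)
  groups <- split(seq_len(n), (seq_len(n) - 1L) %/% p)
  out <- lapply(groups, function(idx) Reduce(`+`, stack$frames[idx]))
  frame_stack(unname(out), pixel_size = stack$pixel_size,
              voltage = stack$voltage)
}

# ---- Event records and streams --------------------------------------------

size_classes <- c("small", "medium", "large")

#' Construct an event stream
#'
#' Counted electrons: one record per event with frame index, continuous
#' position (native-pixel units), size class, an SNR-weighting flag and an
#' optional normalized pattern (the PCA representation of the cluster).
#'
#' @param records data.frame with columns `frame_index` (integer, 0-based),
#'   `x`, `y` (continuous, native px), `size_class` (small/medium/large),
#'   `weight_flag` (logical). May carry a list column `pattern`, each element
#'   `NULL` or a data.frame with `dx`, `dy` (integer pixel offsets) and
#'   `value` (non-negative, summing to 1).
#' @param dims detector dimensions, c(nx, ny).
#' @param sr_factor super-resolution factor of any rendering derived from the
#'   stream (metadata).
#' @param method counting method name.
#' @param voltage acceleration voltage (V) or `NA`.
#' @return An object of class `event_stream`.
#' @export
event_stream <- function(records, dims, sr_factor = 1L, method = "unknown",
                         voltage = NA_real_) {
  stopifnot(length(dims) == 2L, all(dims > 0))
  if (is.null(records) || nrow(records) == 0L) {
    records <- data.frame(frame_index = integer(), x = numeric(),
                          y = numeric(), size_class = character(),
                          weight_flag = logical())
    records$pattern <- list()
  }
  need <- c("frame_index", "x", "y", "size_class", "weight_flag")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (!"pattern" %in% names(records)) records$pattern <- vector("list", nrow(records))
  if (nrow(records) > 0L) {
    if (is.unsorted(records$frame_index))
      records <- records[order(records$frame_index), , drop = FALSE]
    if (!all(records$size_class %in% size_classes))
      stop("size_class must be one of small/medium/large")
    ok <- records$x >= 0 & records$x < dims[1L] &
          records$y >= 0 & records$y < dims[2L]
    if (!all(ok)) stop("event positions must lie within frame bounds")
    for (p in records$pattern)
      if (!is.null(p) && abs(sum(p$value) - 1) > 1e-9)
        stop("pattern values must sum to 1")
  }
  rownames(records) <- NULL
  structure(list(records = records,
                 header = list(dims = as.integer(dims),
                               sr_factor = as.integer(sr_factor),
                               method = method, voltage = voltage)),
            class = "event_stream")
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("event_stream: %d record(s), %d x %d detector, sr %d, method %s\n",
              nrow(x$records), x$header$dims[1L], x$header$dims[2L],
              x$header$sr_factor, x$header$method))
  invisible(x)
}

.evt_version <- 1L

.fmt_g <- function(x) sprintf("%.17g", x)

#' Write an event stream to a versioned plain-text `.evt` file
#'
#' Line-based format, documented here and fixed: a header of `#key value`
#' lines (`LVEVT` version, `dims`, `sr_factor`, `method`, `voltage`) followed
#' by one tab-separated record per line: `frame_index x y size_class
#' weight_flag pattern`, where `pattern` is `.` or `dx,dy,value;...` triplets.
#' Floating point fields use 17 significant digits so the round trip is
#' lossless.
#'
#' @param stream an [event_stream()].
#' @param path output path.
#' @export
write_events <- function(stream, path) {
  stopifnot(inherits(stream, "event_stream"))
  h <- stream$header
  r <- stream$records
  pat_str <- vapply(r$pattern, function(p) {
    if (is.null(p)) "." else
      paste(sprintf("%d,%d,%s", p$dx, p$dy, .fmt_g(p$value)), collapse = ";")
  }, character(1L))
  lines <- c(
    sprintf("#LVEVT %d", .evt_version),
    sprintf("#dims %d %d", h$dims[1L], h$dims[2L]),
    sprintf("#sr_factor %d", h$sr_factor),
    sprintf("#method %s", h$method),
    sprintf("#voltage %s", .fmt_g(h$voltage)),
    if (nrow(r) > 0L)
      sprintf("%d\t%s\t%s\t%s\t%d\t%s", r$frame_index, .fmt_g(r$x),
              .fmt_g(r$y), r$size_class, as.integer(r$weight_flag), pat_str)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a `.evt` event stream written by [write_events()]
#'
#' @param path path to the file.
#' @return An [event_stream()].
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 5L || !startsWith(lines[1L], "#LVEVT"))
    stop("not an LVEVT event file")
  ver <- as.integer(strsplit(lines[1L], " ")[[1L]][2L])
  if (is.na(ver) || ver != .evt_version)
    stop("unsupported LVEVT version: ", lines[1L])
  hv <- function(key) {
    ln <- lines[startsWith(lines, paste0("#", key, " "))][1L]
    strsplit(sub(paste0("^#", key, " "), "", ln), " ")[[1L]]
  }
  dims <- as.integer(hv("dims"))
  sr <- as.integer(hv("sr_factor"))
  method <- paste(hv("method"), collapse = " ")
  vs <- hv("voltage")
  voltage <- if (identical(vs, "NA")) NA_real_ else as.numeric(vs)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0L)
    return(event_stream(NULL, dims, sr, method, voltage))
  parts <- strsplit(body, "\t", fixed = TRUE)
  rec <- data.frame(
    frame_index = as.integer(vapply(parts, `[[`, "", 1L)),
    x = as.numeric(vapply(parts, `[[`, "", 2L)),
    y = as.numeric(vapply(parts, `[[`, "", 3L)),
    size_class = vapply(parts, `[[`, "", 4L),
    weight_flag = as.integer(vapply(parts, `[[`, "", 5L)) == 1L)
  rec$pattern <- lapply(parts, function(p) {
    s <- p[[6L]]
    if (s == ".") return(NULL)
    tri <- do.call(rbind, lapply(strsplit(s, ";", fixed = TRUE)[[1L]],
                                 function(t) as.numeric(strsplit(t, ",")[[1L]])))
    data.frame(dx = as.integer(tri[, 1L]), dy = as.integer(tri[, 2L]),
               value = tri[, 3L])
  })
  event_stream(rec, dims, sr, method, voltage)
}
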