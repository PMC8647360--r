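# Lightweight S3 containers shared by all modules.

#' Construct an image stack with physical calibration
#'
#' An `ImageStack` wraps a numeric array with named axes (any subset of
#' `t`, `z`, `c`, `y`, `x`; `y` and `x` are mandatory and last) together
#' with the pixel size in micrometres and, for time series, the frame
#' interval in seconds.
#'
#' @param data numeric array; dimensions in the order given by `axes`.
#'   A plain matrix is interpreted as a single `y,x` frame.
#' @param axes character string naming the axes, e.g. `"tcyx"`.
#' @param pixel_size pixel size in micrometres (> 0).
#' @param frame_interval frame interval in seconds (required when a `t`
#'   axis is present).
#' @param bit_depth nominal bit depth of the raw data (8, 16 or 32).
#' @return an object of class `ImageStack`.
#' @export
image_stack <- function(data, axes = NULL, pixel_size, frame_interval = NA_real_,
                        bit_depth = 16L) {
  if (is.matrix(data)) {
    dim(data) <- c(1L, dim(data))
    if (is.null(axes)) axes <- "tyx" else axes <- paste0("t", axes)
  }
  if (is.null(axes)) stop("`axes` must be given for array input")
  ax <- strsplit(axes, "")[[1]]
  if (length(ax) != length(dim(data)))
    stop("axes '", axes, "' do not match array of ", length(dim(data)), " dims")
  if (!all(ax %in% c("t", "z", "c", "y", "x")) || anyDuplicated(ax))
    stop("axes must be a subset of t,z,c,y,x without repeats")
  if (!identical(utils::tail(ax, 2), c("y", "x")))
    stop("the last two axes must be y, x")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(data = data, axes = ax, pixel_size = pixel_size,
                 frame_interval = frame_interval, bit_depth = bit_depth),
            class = "ImageStack")
}

#' Extract a single 2D frame from an ImageStack
#'
#' @param stack an `ImageStack`.
#' @param t,z,c indices along the time, z and channel axes (ignored when the
#'   axis is absent).
#' @return a numeric `y` by `x` matrix.
#' @export
get_frame <- function(stack, t = 1L, z = 1L, c = 1L) {
  stopifnot(inherits(stack, "ImageStack"))
  idx <- lapply(stack$axes, function(a)
    switch(a, t = t, z = z, c = c, y = TRUE, x = TRUE))
  out <- do.call(`[`, c(list(stack$data), idx, list(drop = FALSE)))
  d <- dim(out)
  matrix(out, d[length(d) - 1L], d[length(d)])
}

#' @export
print.ImageStack <- function(x, ...) {
  cat("ImageStack <", paste(x$axes, dim(x$data), sep = "=", collapse = ", "),
      "> pixel ", x$pixel_size, " um",
      if (!is.na(x$frame_interval)) paste0(", dt ", x$frame_interval, " s"),
      "\n", sep = "")
  invisible(x)
}

n_frames <- function(stack) {
  i <- match("t", stack$axes)
  if (is.na(i)) 1L else dim(stack$data)[i]
}

#' Construct a trajectory set
#'
#' A `TrajectorySet` is a long-format table of tracked points (one row per
#' point, columns `track_id`, `frame`, `x_um`, `y_um`, optionally
#' `intensity` and `gap_after`) plus the acquisition calibration.
#'
#' @param tracks data.frame with at least `track_id`, `frame`, `x_um`, `y_um`.
#' @param dt frame interval in seconds.
#' @param pixel_size pixel size in micrometres (optional; `NA` for
#'   trajectory data that never touched an image).
#' @param provenance free-text provenance string.
#' @return an object of class `TrajectorySet`.
#' @export
trajectory_set <- function(tracks, dt, pixel_size = NA_real_,
                           provenance = "") {
  need <- c("track_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(tracks)))
    stop("tracks must have columns ", paste(need, collapse = ", "))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  o <- order(tracks$track_id, tracks$frame)
  tracks <- tracks[o, , drop = FALSE]
  rownames(tracks) <- NULL
  if (any(!is.finite(tracks$x_um)) || any(!is.finite(tracks$y_um)))
    stop("positions must be finite")
  fr <- split(tracks$frame, tracks$track_id)
  if (any(vapply(fr, function(f) any(diff(f) <= 0), logical(1))))
    stop("frames must be strictly increasing within a track")
  structure(list(tracks = tracks, dt = dt, pixel_size = pixel_size,
                 provenance = provenance),
            class = "TrajectorySet")
}

#' @export
print.TrajectorySet <- function(x, ...) {
  cat("TrajectorySet:", length(unique(x$tracks$track_id)), "tracks,",
      nrow(x$tracks), "points, dt =", x$dt, "s\n")
  invisible(x)
}

#' Split a TrajectorySet into per-track data frames
#' @param ts a `TrajectorySet`.
#' @return named list of data.frames, one per track.
#' @export
split_tracks <- function(ts) {
  stopifnot(inherits(ts, "TrajectorySet"))
  split(ts$tracks, ts$tracks$track_id)
}

#' Write / read trajectory tables as delimited text
#'
#' Plain tab-separated tables with header
#' `track_id, frame, x_um, y_um[, ...]`.
#'
#' @param ts a `TrajectorySet`.
#' @param path output file.
#' @export
write_tracks <- function(ts, path) {
  stopifnot(inherits(ts, "TrajectorySet"))
  utils::write.table(ts$tracks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @param dt,pixel_size calibration to attach on read.
#' @export
read_tracks <- function(path, dt, pixel_size = NA_real_) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  trajectory_set(tab, dt = dt, pixel_size = pixel_size,
                 provenance = paste0("file:", path))
}
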