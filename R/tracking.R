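# Single-particle detection (sub-pixel 2D Gaussian fitting) and
# frame-to-frame linking by linear assignment.

#' Detect single molecules with sub-pixel 2D Gaussian localization
#'
#' Candidate pixels are local maxima of a Gaussian-smoothed frame above a
#' robust noise floor; each candidate is refined by least-squares fitting of
#' a 2D Gaussian (amplitude, x, y, offset; sigma fixed at `psf_sigma` by
#' default or free with `fit_sigma = TRUE`). Detections whose fit fails or
#' whose amplitude falls below `snr_min` times the noise are discarded.
#'
#' @param frame 2D matrix.
#' @param pixel_size um/pixel.
#' @param psf_sigma PSF sigma in pixels (> 0.5).
#' @param snr_min minimum amplitude/noise ratio.
#' @param fit_sigma fit sigma as a free parameter?
#' @return data.frame: `x_um`, `y_um`, `amplitude`, `offset`, `sigma_px`.
#' @export
detect_molecules <- function(frame, pixel_size, psf_sigma = 1.5,
                             snr_min = 4, fit_sigma = FALSE) {
  stopifnot(is.matrix(frame))
  if (psf_sigma <= 0.5) stop("psf_sigma must be > 0.5 px")
  sm <- gauss_blur(frame, psf_sigma)
  bkg <- stats::median(frame)
  noise <- stats::mad(frame)
  if (noise == 0) noise <- stats::sd(frame)
  if (noise == 0) noise <- 1e-12
  # smoothing reduces peak height; half the raw-amplitude gate is a safe
  # candidate threshold, the fit-amplitude gate below is the real filter
  cand <- local_maxima(sm, min_value = bkg + 0.5 * snr_min * noise)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      amplitude = numeric(0), offset = numeric(0),
                      sigma_px = numeric(0))
  if (nrow(cand) == 0) return(empty)
  w <- max(3L, ceiling(3 * psf_sigma))
  nr <- nrow(frame); nc <- ncol(frame)
  res <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- unname(cand[i, 1]); c <- unname(cand[i, 2])
    rr <- max(1, r - w):min(nr, r + w)
    cc <- max(1, c - w):min(nc, c + w)
    z <- as.vector(frame[rr, cc])
    gr <- rep(rr, times = length(cc))
    gc <- rep(cc, each = length(rr))
    st <- list(A = max(frame[r, c] - bkg, noise), x0 = c, y0 = r, b = bkg)
    lo <- c(A = 0, x0 = min(cc) - 1, y0 = min(rr) - 1, b = -Inf)
    up <- c(A = Inf, x0 = max(cc) + 1, y0 = max(rr) + 1, b = Inf)
    if (fit_sigma) {
      st$s <- psf_sigma; lo <- c(lo, s = 0.3); up <- c(up, s = 5 * psf_sigma)
      form <- z ~ A * exp(-((gc - x0)^2 + (gr - y0)^2) / (2 * s^2)) + b
    } else {
      s <- psf_sigma
      form <- z ~ A * exp(-((gc - x0)^2 + (gr - y0)^2) / (2 * s^2)) + b
    }
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      form, start = st, lower = lo, upper = up,
      control = minpack.lm::nls.lm.control(maxiter = 60))), silent = TRUE)
    if (inherits(fit, "try-error")) next
    cf <- stats::coef(fit)
    if (cf[["A"]] < snr_min * noise) next
    res[[i]] <- data.frame(
      x_um = (cf[["x0"]] - 0.5) * pixel_size,
      y_um = (cf[["y0"]] - 0.5) * pixel_size,
      amplitude = cf[["A"]], offset = cf[["b"]],
      sigma_px = if (fit_sigma) cf[["s"]] else psf_sigma)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) return(empty)
  out <- do.call(rbind, res)
  # deduplicate fits that converged to the same molecule
  keep <- rep(TRUE, nrow(out))
  if (nrow(out) > 1) {
    d <- as.matrix(stats::dist(out[, c("x_um", "y_um")] / pixel_size))
    for (i in 2:nrow(out))
      if (any(d[i, 1:(i - 1)][keep[1:(i - 1)]] < psf_sigma)) keep[i] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

lap_match <- function(d2, max_cost2) {
  # one-to-one assignment minimizing total squared displacement with
  # birth/death cost max_cost2, as a max-weight bipartite matching on
  # admissible pairs (weight = max_cost2 - d2 >= 0)
  nr <- nrow(d2); nc <- ncol(d2)
  adm <- which(d2 <= max_cost2, arr.ind = TRUE)
  if (nrow(adm) == 0) return(integer(0))
  edges <- as.vector(t(cbind(adm[, 1], nr + adm[, 2])))
  g <- igraph::make_bipartite_graph(rep(c(FALSE, TRUE), c(nr, nc)), edges,
                                    directed = FALSE)
  wt <- max_cost2 - d2[adm] + 1e-12 * max_cost2
  m <- igraph::max_bipartite_match(g, weights = wt)$matching
  # matching[i] = index of matched column vertex (nr+j) or NA
  out <- integer(0)
  for (i in seq_len(nr)) {
    j <- m[i]
    if (!is.na(j)) out <- rbind(out, c(i, j - nr))
  }
  out
}

#' Link single-molecule detections into trajectories
#'
#' Frame-to-frame one-to-one assignment minimizing total squared
#' displacement among candidate pairs within `max_step`; unassigned
#' detections start or terminate tracks. No gap closing and no motion
#' model. Tracks with fewer than `min_steps` displacements are dropped
#' (`min_steps = 6` keeps tracks of at least 7 points, i.e. at least
#' six 33-ms steps, 200 ms).
#'
#' @param detections data.frame with `frame`, `x_um`, `y_um` (e.g. rows of
#'   [detect_molecules()] results bound together with a `frame` column).
#' @param dt frame interval, s.
#' @param max_step maximum step length in um (default 0.720).
#' @param min_steps minimum number of displacements per kept track.
#' @param pixel_size recorded in the output set.
#' @return a [trajectory_set()].
#' @export
link_molecules <- function(detections, dt, max_step = 0.720,
                           min_steps = 6, pixel_size = NA_real_) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(detections)))
  det <- detections[order(detections$frame), , drop = FALSE]
  frames <- sort(unique(det$frame))
  det$track <- NA_integer_
  next_id <- 1L
  by_frame <- split(seq_len(nrow(det)), det$frame)
  prev_idx <- integer(0)
  for (fi in seq_along(frames)) {
    cur_idx <- by_frame[[as.character(frames[fi])]]
    if (fi > 1 && frames[fi] == frames[fi - 1] + 1 &&
        length(prev_idx) > 0 && length(cur_idx) > 0) {
      d2 <- outer(det$x_um[prev_idx], det$x_um[cur_idx], `-`)^2 +
        outer(det$y_um[prev_idx], det$y_um[cur_idx], `-`)^2
      pairs <- lap_match(d2, max_step^2)
      if (length(pairs) > 0)
        det$track[cur_idx[pairs[, 2]]] <- det$track[prev_idx[pairs[, 1]]]
    }
    new <- cur_idx[is.na(det$track[cur_idx])]
    if (length(new) > 0) {
      det$track[new] <- next_id + seq_along(new) - 1L
      next_id <- next_id + length(new)
    }
    prev_idx <- cur_idx
  }
  keep_ids <- names(which(table(det$track) >= min_steps + 1L))
  det <- det[det$track %in% as.integer(keep_ids), , drop = FALSE]
  if (nrow(det) == 0)
    return(trajectory_set(data.frame(track_id = integer(0), frame = integer(0),
                                     x_um = numeric(0), y_um = numeric(0)),
                          dt = dt, pixel_size = pixel_size))
  det$track_id <- match(det$track, sort(unique(det$track)))
  cols <- intersect(c("track_id", "frame", "x_um", "y_um", "amplitude"),
                    names(det))
  trajectory_set(det[, cols], dt = dt, pixel_size = pixel_size,
                 provenance = "link_molecules")
}

#' Link foci detections with gap closing
#'
#' Same assignment core as [link_molecules()] but a track may survive up to
#' `max_gap` frames without a detection; candidate pairs are limited by the
#' maximum object speed times the elapsed time. Gap positions are flagged
#' (`gap_after`), never interpolated. Tracks with fewer than `min_length`
#' detected points are dropped.
#'
#' @param detections data.frame with `frame`, `x_um`, `y_um`.
#' @param dt frame interval, s (foci imaging: 0.551 s).
#' @param max_gap maximum gap in frames (default 3).
#' @param min_length minimum detected points per kept track (default 30).
#' @param max_speed maximum object speed, um/s (default 200).
#' @param pixel_size recorded in the output set.
#' @return a [trajectory_set()] whose tracks carry a `gap_after` flag.
#' @export
link_foci <- function(detections, dt, max_gap = 3, min_length = 30,
                      max_speed = 200, pixel_size = NA_real_) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(detections)))
  det <- detections[order(detections$frame), , drop = FALSE]
  det$track <- NA_integer_
  frames <- min(det$frame):max(det$frame)
  by_frame <- split(seq_len(nrow(det)), det$frame)
  next_id <- 1L
  # active tracks: last detection row index + frames since seen
  act_row <- integer(0); act_age <- integer(0)
  for (f in frames) {
    cur_idx <- by_frame[[as.character(f)]]
    if (is.null(cur_idx)) cur_idx <- integer(0)
    matched_cur <- rep(FALSE, length(cur_idx))
    matched_act <- rep(FALSE, length(act_row))
    if (length(act_row) > 0 && length(cur_idx) > 0) {
      dtime <- (act_age + 1L) * dt
      lim2 <- (max_speed * dtime)^2
      d2 <- outer(det$x_um[act_row], det$x_um[cur_idx], `-`)^2 +
        outer(det$y_um[act_row], det$y_um[cur_idx], `-`)^2
      d2[d2 > lim2] <- Inf                     # per-row admissibility
      maxc2 <- (max_speed * (max_gap + 1) * dt)^2
      pairs <- lap_match(d2, maxc2)
      if (length(pairs) > 0) {
        for (k in seq_len(nrow(pairs))) {
          a <- pairs[k, 1]; b <- pairs[k, 2]
          det$track[cur_idx[b]] <- det$track[act_row[a]]
          matched_act[a] <- TRUE; matched_cur[b] <- TRUE
        }
      }
    }
    new <- cur_idx[!matched_cur]
    if (length(new) > 0) {
      det$track[new] <- next_id + seq_along(new) - 1L
      next_id <- next_id + length(new)
    }
    # update active list
    keep <- which(!matched_act & act_age < max_gap)
    act_row <- c(act_row[keep], cur_idx)
    act_age <- c(act_age[keep] + 1L, rep(0L, length(cur_idx)))
  }
  keep_ids <- names(which(table(det$track) >= min_length))
  det <- det[det$track %in% as.integer(keep_ids), , drop = FALSE]
  if (nrow(det) == 0)
    return(trajectory_set(data.frame(track_id = integer(0), frame = integer(0),
                                     x_um = numeric(0), y_um = numeric(0)),
                          dt = dt, pixel_size = pixel_size))
  det$track_id <- match(det$track, sort(unique(det$track)))
  det <- det[order(det$track_id, det$frame), , drop = FALSE]
  gap_after <- unlist(lapply(split(det$frame, det$track_id),
                             function(f) c(diff(f) > 1, FALSE)),
                      use.names = FALSE)
  out <- det[, c("track_id", "frame", "x_um", "y_um")]
  out$gap_after <- gap_after
  trajectory_set(out, dt = dt, pixel_size = pixel_size,
                 provenance = "link_foci")
}

#' Detect and link molecules across a movie
#'
#' Convenience driver: [detect_molecules()] on every frame, then
#' [link_molecules()].
#'
#' @param movie an [image_stack()] with a `t` axis.
#' @param ... passed to [detect_molecules()].
#' @param max_step,min_steps passed to [link_molecules()].
#' @return a [trajectory_set()].
#' @export
track_movie <- function(movie, ..., max_step = 0.720, min_steps = 6) {
  stopifnot(inherits(movie, "ImageStack"))
  nt <- n_frames(movie)
  dets <- vector("list", nt)
  for (t in seq_len(nt)) {
    d <- detect_molecules(get_frame(movie, t = t), movie$pixel_size, ...)
    if (nrow(d) > 0) { d$frame <- t; dets[[t]] <- d }
  }
  dets <- do.call(rbind, dets)
  if (is.null(dets))
    return(trajectory_set(data.frame(track_id = integer(0), frame = integer(0),
                                     x_um = numeric(0), y_um = numeric(0)),
                          dt = movie$frame_interval,
                          pixel_size = movie$pixel_size))
  link_molecules(dets, dt = movie$frame_interval, max_step = max_step,
                 min_steps = min_steps, pixel_size = movie$pixel_size)
}
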