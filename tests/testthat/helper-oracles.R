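# Independent oracles and fixture builders used across the suite.

# brute-force time-averaged MSD by explicit double loop over point pairs
brute_msd <- function(frame, x, y, max_lag) {
  out <- numeric(max_lag)
  for (k in seq_len(max_lag)) {
    acc <- c()
    for (i in seq_along(frame)) for (j in seq_along(frame)) {
      if (frame[j] - frame[i] == k)
        acc <- c(acc, (x[j] - x[i])^2 + (y[j] - y[i])^2)
    }
    out[k] <- if (length(acc)) mean(acc) else NA_real_
  }
  out
}

# brute-force Mann-Whitney U by pair counting (ties count 1/2)
brute_u <- function(a, b) {
  u <- 0
  for (i in seq_along(a)) for (j in seq_along(b))
    u <- u + (a[i] > b[j]) + 0.5 * (a[i] == b[j])
  u
}

# image whose pixel values are point samples of an analytic 2D Gaussian at
# pixel centers (peak `amp` over offset `bg`); center given in pixel units
point_gauss_image <- function(nrow, ncol, cx_px, cy_px, amp, sigma_px,
                              bg = 0) {
  cc <- col(matrix(0, nrow, ncol)) - 0.5
  rr <- row(matrix(0, nrow, ncol)) - 0.5
  bg + amp * exp(-((cc - cx_px)^2 + (rr - cy_px)^2) / (2 * sigma_px^2))
}

# exact discretized mean-reverting (spring) states, no imaging:
# r_{i+1} = r_i - kdt * (r_i - anchor) + N(0, s^2) per axis
ou_track <- function(n, kdt, step_sd, anchor = c(0, 0)) {
  x <- numeric(n); y <- numeric(n)
  x[1] <- anchor[1]; y[1] <- anchor[2]
  for (i in 2:n) {
    x[i] <- x[i - 1] - kdt * (x[i - 1] - anchor[1]) + rnorm(1, 0, step_sd)
    y[i] <- y[i - 1] - kdt * (y[i - 1] - anchor[2]) + rnorm(1, 0, step_sd)
  }
  data.frame(frame = seq_len(n), x_um = x, y_um = y)
}

# fraction of recovered tracks whose per-frame positions match some ground
# truth path within tol_um (median over shared frames)
track_match_fraction <- function(recovered, truth, tol_um) {
  rec <- split_tracks(recovered)
  tp <- split_tracks(truth)
  if (length(rec) == 0) return(0)
  ok <- vapply(rec, function(tr) {
    errs <- vapply(tp, function(g) {
      m <- merge(tr, g, by = "frame")
      if (nrow(m) < 3) return(Inf)
      stats::median(sqrt((m$x_um.x - m$x_um.y)^2 + (m$y_um.x - m$y_um.y)^2))
    }, numeric(1))
    min(errs) < tol_um
  }, logical(1))
  mean(ok)
}

# shared end-to-end fixture: many sparse single-molecule movies (one per
# simulated cell) over blob maps, bound-in-enriched molecules 1.5x more
# mobile; tracks come from the rendered images, not the ground truth
run_end_to_end <- function(n_movies = 40, n_bound = 20, n_mobile = 10,
                           n_frames = 60, seed = 1) {
  assoc <- NULL
  for (m in seq_len(n_movies)) {
    map <- make_blob_map(96, 96, n_blobs = 6, blob_sigma_px = 6,
                         seed = seed + 100 + m)
    sim <- simulate_two_population_movie(
      n_bound = n_bound, n_mobile = n_mobile, D_mobile = 0.5,
      D_bound = 0.008, kappa = 2, map = map, placement_bias = 0.5,
      dt = 1 / 30, n_frames = n_frames, pixel_size = 0.08, amplitude = 300,
      enriched_D_factor = 1.5, seed = seed + m)
    ts <- track_movie(sim$movie, psf_sigma = 1.5, snr_min = 4)
    dtab <- track_diffusion(ts, n_lags = 6)
    a <- associate_tracks(ts, sim$map, pixel_size = 0.08, d_table = dtab)
    a$track_id <- a$track_id + 1e6 * m
    assoc <- rbind(assoc, a)
  }
  assoc
}
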