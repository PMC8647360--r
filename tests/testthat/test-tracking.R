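# Sub-pixel localization, LAP linking, gap-closing foci tracker.

test_that("noiseless spots are localized to better than 0.05 px", {
  img <- matrix(10, 64, 64) +
    mintdyn:::render_spots(64, 64, 20.3 * 0.08, 41.7 * 0.08, 300,
                           1.5 * 0.08, 0.08)
  d <- detect_molecules(img, pixel_size = 0.08, psf_sigma = 1.5, snr_min = 4)
  expect_identical(nrow(d), 1L)
  expect_lt(abs(d$x_um / 0.08 - 20.3), 0.05)
  expect_lt(abs(d$y_um / 0.08 - 41.7), 0.05)
})

test_that("blank noisy frames yield no detections", {
  set.seed(51)
  blank <- matrix(rpois(64 * 64, 20), 64)
  d <- detect_molecules(blank, pixel_size = 0.08, psf_sigma = 1.5,
                        snr_min = 6)
  expect_identical(nrow(d), 0L)
})

test_that("localization RMSE stays below 0.5 px at moderate SNR", {
  set.seed(52)
  errs <- c()
  for (i in 1:20) {
    tx <- runif(1, 20, 40); ty <- runif(1, 20, 40)
    img <- matrix(20, 64, 64) +
      mintdyn:::render_spots(64, 64, tx * 0.08, ty * 0.08, 25, 1.5 * 0.08,
                             0.08)
    img[] <- rpois(length(img), img)
    d <- detect_molecules(img, pixel_size = 0.08, psf_sigma = 1.5,
                          snr_min = 3)
    if (nrow(d) == 1)
      errs <- c(errs, sqrt((d$x_um / 0.08 - tx)^2 + (d$y_um / 0.08 - ty)^2))
  }
  expect_gt(length(errs), 10)
  expect_lt(sqrt(mean(errs^2)), 0.5)
})

test_that("linking respects the maximum step length", {
  near <- data.frame(frame = c(1, 2), x_um = c(0, 0.5), y_um = 0)
  ts1 <- link_molecules(near, dt = 1 / 30, min_steps = 1)
  expect_identical(length(unique(ts1$tracks$track_id)), 1L)
  far <- data.frame(frame = c(1, 2), x_um = c(0, 0.8), y_um = 0)
  ts2 <- link_molecules(far, dt = 1 / 30, min_steps = 0)
  expect_identical(length(unique(ts2$tracks$track_id)), 2L)
})

test_that("tracks shorter than six steps are dropped", {
  mk <- function(n, x0) data.frame(frame = seq_len(n), x_um = x0,
                                   y_um = seq_len(n) * 0.01)
  det <- rbind(mk(7, 0), mk(6, 5))   # 6 steps vs 5 steps
  ts <- link_molecules(det, dt = 1 / 30)
  expect_identical(length(unique(ts$tracks$track_id)), 1L)
  expect_identical(nrow(ts$tracks), 7L)
})

test_that("linking is invariant to detection order within a frame", {
  set.seed(53)
  det <- data.frame(frame = rep(1:10, each = 5),
                    x_um = runif(50, 0, 2), y_um = runif(50, 0, 2))
  shuf <- det[order(det$frame, runif(50)), ]
  t1 <- link_molecules(det, dt = 1 / 30, min_steps = 2)
  t2 <- link_molecules(shuf, dt = 1 / 30, min_steps = 2)
  k1 <- t1$tracks[order(t1$tracks$frame, t1$tracks$x_um), c("frame", "x_um")]
  k2 <- t2$tracks[order(t2$tracks$frame, t2$tracks$x_um), c("frame", "x_um")]
  expect_equal(k1$x_um, k2$x_um)
})

test_that("no linked step ever exceeds the maximum step length", {
  set.seed(54)
  det <- data.frame(frame = rep(1:30, each = 8),
                    x_um = runif(240, 0, 4), y_um = runif(240, 0, 4))
  ts <- link_molecules(det, dt = 1 / 30, min_steps = 1)
  for (tr in split_tracks(ts)) {
    if (nrow(tr) < 2) next
    steps <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
    consec <- diff(tr$frame) == 1
    expect_true(all(steps[consec] <= 0.720 + 1e-12))
  }
})

test_that("movie tracking recovers ground-truth molecules", {
  map <- make_blob_map(96, 96, n_blobs = 8, blob_sigma_px = 4, seed = 55)
  sim <- simulate_two_population_movie(
    n_bound = 25, n_mobile = 12, map = map, placement_bias = 0.5,
    n_frames = 50, amplitude = 300, seed = 56)
  ts <- track_movie(sim$movie, psf_sigma = 1.5, snr_min = 4)
  expect_gt(length(unique(ts$tracks$track_id)), 20)
  # >= 90% of recovered tracks match a true molecule (median error < 1 px)
  expect_gte(track_match_fraction(ts, sim$paths, tol_um = 0.08), 0.9)
})

test_that("foci linking closes gaps up to 3 frames and flags them", {
  det <- data.frame(frame = c(1:10, 13:40), x_um = 0.05 * c(1:10, 13:40),
                    y_um = 1)
  ts <- link_foci(det, dt = 0.551, min_length = 30)
  expect_identical(length(unique(ts$tracks$track_id)), 1L)
  expect_identical(sum(ts$tracks$gap_after), 1L)
  # a 4-frame gap breaks the track; both pieces are then too short
  det2 <- data.frame(frame = c(1:10, 15:40), x_um = 0.05 * c(1:10, 15:40),
                     y_um = 1)
  ts2 <- link_foci(det2, dt = 0.551, min_length = 30)
  expect_identical(nrow(ts2$tracks), 0L)
})

test_that("29-frame foci tracks are deleted, 30-frame tracks kept", {
  mk <- function(n) data.frame(frame = seq_len(n), x_um = 0.01 * seq_len(n),
                               y_um = 0)
  t29 <- link_foci(mk(29), dt = 0.551)
  expect_identical(nrow(t29$tracks), 0L)
  t30 <- link_foci(mk(30), dt = 0.551)
  expect_identical(nrow(t30$tracks), 30L)
})

test_that("foci tracking follows a simulated fBm foci field", {
  ts <- simulate_fbm_tracks(0.0029, 0.69, 0.551, n_steps = 39, n_tracks = 30,
                            origin_spread = 12, seed = 57)
  px <- 0.065
  # render each frame, detect, relink, compare to truth
  frames <- lapply(1:40, function(f) {
    pts <- ts$tracks[ts$tracks$frame == f, ]
    matrix(10, 200, 200) +
      mintdyn:::render_spots(200, 200, pts$x_um, pts$y_um, 150, 2 * px, px)
  })
  dets <- do.call(rbind, lapply(seq_along(frames), function(f) {
    d <- detect_spots(frames[[f]], px, typical_diameter = 7, min_contrast = 5)
    if (nrow(d)) cbind(frame = f, d) else NULL
  }))
  lf <- link_foci(dets, dt = 0.551, min_length = 30, max_speed = 200)
  expect_gt(length(unique(lf$tracks$track_id)), 15)
  # median per-point tracking error below 1 px
  errs <- unlist(lapply(split_tracks(lf), function(tr) {
    best <- Inf
    for (g in split_tracks(ts)) {
      m <- merge(tr, g, by = "frame")
      if (nrow(m) < 5) next
      e <- sqrt((m$x_um.x - m$x_um.y)^2 + (m$y_um.x - m$y_um.y)^2)
      if (stats::median(e) < stats::median(best)) best <- e
    }
    best
  }))
  expect_lt(stats::median(errs[is.finite(errs)]), px)
})
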