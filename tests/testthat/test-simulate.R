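# Generators: determinism, the fBm law, population bookkeeping, FRAP model.

test_that("identical seeds give bit-identical outputs", {
  a <- simulate_fbm_tracks(0.01, 0.7, 0.551, 20, 5, seed = 42)
  b <- simulate_fbm_tracks(0.01, 0.7, 0.551, 20, 5, seed = 42)
  expect_identical(a$tracks, b$tracks)
  p1 <- simulate_foci_image_pair(30, 0.5, seed = 7, image_size = 96)
  p2 <- simulate_foci_image_pair(30, 0.5, seed = 7, image_size = 96)
  expect_identical(p1$stack$data, p2$stack$data)
  f1 <- simulate_frap_curve(noise_sd = 2, seed = 3)
  f2 <- simulate_frap_curve(noise_sd = 2, seed = 3)
  expect_identical(f1$bleach, f2$bleach)
  m1 <- sample_logD_mixture(n = 500, seed = 9)
  m2 <- sample_logD_mixture(n = 500, seed = 9)
  expect_identical(m1$D, m2$D)
})

test_that("fBm ensemble MSD follows 4 D t^alpha at every lag", {
  D <- 0.0029; alpha <- 0.69; dt <- 0.551
  ts <- simulate_fbm_tracks(D, alpha, dt, n_steps = 30, n_tracks = 1500,
                            seed = 11)
  ens <- ensemble_msd(ts, max_lag = 20)
  expected <- 4 * D * (ens$t_s)^alpha
  # within 3 standard errors of the across-track mean at every lag
  expect_true(all(abs(ens$msd - expected) < 3 * ens$sem))
})

test_that("fBm increment autocovariance matches the fGn closed form", {
  D <- 0.02; alpha <- 0.6; dt <- 1
  ts <- simulate_fbm_tracks(D, alpha, dt, n_steps = 30, n_tracks = 2000,
                            seed = 5)
  tr <- split_tracks(ts)
  dx <- vapply(tr, function(t) diff(t$x_um), numeric(30))
  gamma_hat <- vapply(0:5, function(k) {
    mean(dx[seq_len(30 - k), ] * dx[seq_len(30 - k) + k, ])
  }, numeric(1))
  k <- 0:5
  gamma_true <- D * dt^alpha *
    (abs(k + 1)^alpha - 2 * abs(k)^alpha + abs(k - 1)^alpha)
  expect_equal(gamma_hat, gamma_true, tolerance = 0.05)
  # Brownian limit: increments uncorrelated at all positive lags
  tsb <- simulate_fbm_tracks(0.05, 1, dt, n_steps = 30, n_tracks = 1000,
                             seed = 6)
  dxb <- vapply(split_tracks(tsb), function(t) diff(t$x_um), numeric(30))
  g1 <- mean(dxb[1:29, ] * dxb[2:30, ])
  expect_lt(abs(g1), 3 * 2 * 0.05 * dt / sqrt(29 * 1000))
})

test_that("degenerate fBm inputs behave as documented", {
  st <- simulate_fbm_tracks(0, 0.7, 0.5, 10, 3, loc_error = 0, seed = 1)
  expect_true(all(st$tracks$x_um == st$tracks$x_um[1]))
  expect_error(simulate_fbm_tracks(0.01, 2.5, 0.5, 10, 3), "alpha")
  expect_error(simulate_fbm_tracks(0.01, 0.7, -1, 10, 3), "dt")
})

test_that("foci image pair honours rho and spot count", {
  sim <- simulate_foci_image_pair(10, rho = 1, noise = FALSE,
                                  image_size = 128, seed = 2)
  a <- get_frame(sim$stack, c = 1); b <- get_frame(sim$stack, c = 2)
  # rho = 1, equal amplitudes: channels identical
  expect_equal(a, b)
  expect_identical(sim$truth$n_shared, 10)
  # exactly 10 local maxima above background in the noiseless frame
  mx <- mintdyn:::local_maxima(a, min_value = 10 + 1)
  expect_identical(nrow(mx), 10L)
  # rho = 1 with rescaled channel B: correlation inside mask still 1
  sim2 <- simulate_foci_image_pair(50, rho = 1, noise = FALSE,
                                   image_size = 128, amplitude_b = 300,
                                   seed = 2)
  a2 <- get_frame(sim2$stack, c = 1); b2 <- get_frame(sim2$stack, c = 2)
  expect_equal(cor(a2[sim2$mask], b2[sim2$mask]), 1, tolerance = 1e-12)
  expect_error(simulate_foci_image_pair(10, rho = 1.4), "rho")
})

test_that("rho = 0 image pairs are uncorrelated at zero shift", {
  r0 <- vapply(1:20, function(s) {
    sim <- simulate_foci_image_pair(200, rho = 0, noise = FALSE,
                                    image_size = 128, seed = s)
    a <- get_frame(sim$stack, c = 1); b <- get_frame(sim$stack, c = 2)
    cor(a[sim$mask], b[sim$mask])
  }, numeric(1))
  expect_lt(abs(mean(r0)), 0.1)
  expect_lt(max(abs(r0)), 0.2)
})

test_that("two-population movie bookkeeping is exact", {
  map <- make_blob_map(64, 64, n_blobs = 6, blob_sigma_px = 3, seed = 4)
  sim <- simulate_two_population_movie(
    n_bound = 12, n_mobile = 7, map = map, placement_bias = 1,
    n_frames = 10, noise = FALSE, seed = 3)
  expect_identical(as.vector(table(sim$truth$label)), c(12L, 7L))
  # placement_bias = 1: every bound anchor sits in an enriched pixel
  expect_true(all(sim$truth$in_enriched[sim$truth$label == "bound"]))
  expect_error(simulate_two_population_movie(1, 1, map = matrix(0, 0, 0)),
               "empty")
})

test_that("kappa = 0 bound molecules degenerate to Brownian motion", {
  map <- matrix(0, 48, 48)
  sim <- simulate_two_population_movie(
    n_bound = 200, n_mobile = 0, D_bound = 0.02, kappa = 0, map = map,
    placement_bias = 0, n_frames = 40, noise = FALSE, seed = 8)
  ens <- ensemble_msd(sim$paths, max_lag = 10)
  fit <- fit_anomalous(ens, n_lags = 10)
  expect_equal(fit$alpha, 1, tolerance = 0.1)
  expect_equal(fit$D, 0.02, tolerance = 0.15)
})

test_that("spring process recovers the prescribed relaxation per frame", {
  # oracle: regression on exact simulated states, no imaging involved
  set.seed(21)
  tr <- ou_track(20000, kdt = 0.2, step_sd = 0.05)
  sp <- spring_coefficient(tr, dt = 1)
  expect_equal(sp$slope_per_step, 0.2, tolerance = 0.15)
})

test_that("log10(D) mixture samples have the stated tail structure", {
  s <- sample_logD_mixture(mu_fast = -0.3, sd_fast = 0.25, w_fast = 1,
                           n = 5e4, seed = 13)
  # single component: mean/sd of log10(D) match the generator
  expect_equal(mean(s$logD), -0.3, tolerance = 0.01)
  expect_equal(sd(s$logD), 0.25, tolerance = 0.01)
  # fraction of fast samples above mean - 2 sd ~ Phi(2)
  frac <- mean(s$logD > -0.3 - 2 * 0.25)
  expect_equal(frac, pnorm(2), tolerance = 0.005)
  expect_error(sample_logD_mixture(n = 1), "n")
})

test_that("FRAP simulator matches its closed-form recovery law", {
  # mobile_fraction = 1, no noise, no acquisition bleaching: plateau at 1
  cv <- simulate_frap_curve(bleach_depth = 0.7, mobile_fraction = 1,
                            tau = 0.4, noise_sd = 0, seed = 1)
  nm <- normalize_frap(cv)
  expect_equal(tail(nm$normalized, 1), 1, tolerance = 1e-6)
  # closed form at the plateau for partial mobility
  cv2 <- simulate_frap_curve(bleach_depth = 0.6, mobile_fraction = 0.8,
                             tau = 0.3, acquisition_bleach_rate = 0.05,
                             noise_sd = 0, seed = 1)
  nm2 <- normalize_frap(cv2)
  t_end <- max(nm2$t)
  expect_equal(tail(nm2$normalized, 1),
               frap_model(t_end, 0.6, 0.8, 0.3), tolerance = 1e-9)
  # time to 80% of the recovery span inverts the exponential: -tau ln(0.2)
  span_level <- function(f) {
    y0 <- frap_model(0, 0.6, 0.8, 0.3)
    yinf <- 1 - 0.6 * (1 - 0.8)
    y0 + f * (yinf - y0)
  }
  tt <- recovery_time(nm2, level = span_level(0.8))
  expect_equal(as.numeric(tt), -0.3 * log(0.2), tolerance = 0.3 * 0.0478 + 1e-9)
  expect_error(simulate_frap_curve(n_pre = 0), "n_pre")
})
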