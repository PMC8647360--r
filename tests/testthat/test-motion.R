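# MSD, diffusion fits, mixture classification, confinement, spring.

test_that("MSD matches hand arithmetic and the brute-force definition", {
  tr <- data.frame(frame = 1:3, x_um = c(0, 1, 2), y_um = 0)
  cu <- compute_msd(tr, dt = 1, max_lag = 2)
  expect_equal(cu$msd, c(1, 4))
  static <- data.frame(frame = 1:10, x_um = 2, y_um = 3)
  expect_true(all(compute_msd(static, 1, 5)$msd == 0))
  expect_error(compute_msd(tr[1, ], 1), "shorter")
  # property: equality with the double-loop oracle on random gapped tracks
  set.seed(61)
  for (i in 1:5) {
    n <- 50
    keep <- sort(sample(1:60, n))
    tr <- data.frame(frame = keep, x_um = cumsum(rnorm(n)),
                     y_um = cumsum(rnorm(n)))
    cu <- compute_msd(tr, dt = 0.5, max_lag = 10)
    expect_equal(cu$msd, brute_msd(tr$frame, tr$x_um, tr$y_um, 10))
  }
})

test_that("linear D fit is exact on its own model and clamps at zero", {
  cu <- structure(data.frame(lag = 1:6, t_s = (1:6) * 0.0333,
                             msd = 4 * 0.1 * (1:6) * 0.0333,
                             n_pairs = 10),
                  class = c("MSDCurve", "data.frame"))
  expect_equal(fit_linear_D(cu)$D, 0.1, tolerance = 1e-12)
  cu$msd <- 0
  f0 <- fit_linear_D(cu)
  expect_identical(f0$D, 0)
  expect_error(fit_linear_D(cu[1:3, ]), "lags")
})

test_that("median per-track D of a Brownian simulation is close to truth", {
  ts <- simulate_fbm_tracks(0.05, 1, dt = 1 / 30, n_steps = 30,
                            n_tracks = 1000, seed = 62)
  dt_tab <- track_diffusion(ts, n_lags = 6)
  expect_equal(stats::median(dt_tab$D), 0.05, tolerance = 0.10)
})

test_that("anomalous fit recovers exact self-model curves", {
  t <- (1:20) * 0.551
  cu <- structure(data.frame(lag = 1:20, t_s = t,
                             msd = 4 * 0.0029 * t^0.69, n_pairs = 50),
                  class = c("MSDCurve", "data.frame"))
  fit <- fit_anomalous(cu, 20)
  expect_equal(fit$D, 0.0029, tolerance = 1e-6)
  expect_equal(fit$alpha, 0.69, tolerance = 1e-6)
  # pure Brownian curve: alpha = 1
  cub <- structure(data.frame(lag = 1:20, t_s = t, msd = 4 * 0.01 * t,
                              n_pairs = 50),
                   class = c("MSDCurve", "data.frame"))
  expect_equal(fit_anomalous(cub, 20)$alpha, 1, tolerance = 1e-6)
  cu0 <- cub; cu0$msd <- 0
  expect_error(fit_anomalous(cu0, 20), "degenerate")
})

test_that("mixture fit recovers well-separated components and D_thr", {
  s <- sample_logD_mixture(mu_slow = -1.8, sd_slow = 0.3, mu_fast = -0.3,
                           sd_fast = 0.25, w_fast = 0.6, n = 1e5, seed = 63)
  mx <- fit_logD_mixture(s$D)
  expect_false(mx$fallback)
  expect_equal(mx$mu_slow, -1.8, tolerance = 0.05 / 1.8)
  expect_equal(mx$mu_fast, -0.3, tolerance = 0.05 / 0.3)
  expect_equal(mx$D_thr, 10^(-0.8), tolerance = 0.05)
  # histogram least-squares route agrees with EM
  mh <- fit_logD_mixture(s$D, method = "hist")
  expect_equal(mh$mu_fast, mx$mu_fast, tolerance = 0.02)
  expect_equal(mh$D_thr, mx$D_thr, tolerance = 0.05)
  # >= 97.5% of true fast-component molecules stay above D_thr
  expect_gte(mean(s$D[s$component == "fast"] > mx$D_thr), 0.975)
  expect_error(fit_logD_mixture(s$D[1:50]), "100")
  expect_error(fit_logD_mixture(c(s$D[1:200], -1)), "> 0")
})

test_that("single-Gaussian input takes the fallback path", {
  s <- sample_logD_mixture(w_fast = 1, n = 5000, seed = 64)
  expect_warning(mx <- fit_logD_mixture(s$D), "fallback")
  expect_true(mx$fallback)
})

test_that("confinement ellipse has the analytic area and 95% coverage", {
  set.seed(65)
  tr <- data.frame(x_um = rnorm(1e4), y_um = rnorm(1e4))
  ca <- confinement_area(tr)
  expect_equal(ca$area_um2, pi * qchisq(0.95, 2), tolerance = 0.05)
  expect_equal(ca$inside_fraction, 0.95, tolerance = 0.01 / 0.95)
  same <- data.frame(x_um = rep(1, 20), y_um = rep(2, 20))
  expect_error(confinement_area(same), "degenerate")
  expect_error(confinement_area(tr[1:5, ]), "10 points")
})

test_that("spring coefficient recovers the simulated relaxation rate", {
  set.seed(66)
  dt <- 1 / 30
  tr <- ou_track(20000, kdt = 0.2, step_sd = 0.05)
  sp <- spring_coefficient(tr, dt = dt)
  expect_equal(sp$slope_per_step, 0.2, tolerance = 0.15)
  expect_equal(sp$k_per_s, 0.2 / dt, tolerance = 0.15)
  expect_error(spring_coefficient(
    data.frame(x_um = rep(0, 20), y_um = rep(0, 20)), dt), "usable")
})

test_that("pure Brownian tracks carry a positive finite-length spring bias", {
  # the centripetal regression is biased upward on finite free tracks; the
  # bias is measured on matched simulations, not assumed away
  set.seed(67)
  ks <- vapply(1:200, function(i) {
    tr <- data.frame(x_um = cumsum(rnorm(50, 0, 0.05)),
                     y_um = cumsum(rnorm(50, 0, 0.05)))
    spring_coefficient(tr, dt = 1)$slope_per_step
  }, numeric(1))
  expect_gt(mean(ks), 0)
})

test_that("classification is stable in sign across the D_thr range", {
  # two bound groups with a true 1.5x mobility difference; the sign of the
  # median difference must not flip anywhere on the threshold grid
  set.seed(68)
  n <- 400
  assoc <- data.frame(
    track_id = 1:(2 * n),
    I_rel = c(runif(n, 0.6, 1), runif(n, 0, 0.4)),
    D = c(10^rnorm(n, log10(0.0225), 0.25), 10^rnorm(n, log10(0.015), 0.25)))
  sw <- threshold_sweep(assoc, d_thr_grid = c(0.045, 0.065, 0.105, 0.169))
  ok <- !is.na(sw$delta_median_D) & sw$n_bound >= 20
  expect_true(all(sw$delta_median_D[ok] > 0))
})
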