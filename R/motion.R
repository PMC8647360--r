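# Motion statistics: MSD, diffusion fits, log10(D) mixture classification,
# confinement ellipse, effective spring coefficient.

#' Time-averaged mean squared displacement of a trajectory
#'
#' `MSD(k dt) = mean_i |r(i+k) - r(i)|^2` over all overlapping pairs whose
#' frames are both present (gapped frames simply contribute no pairs).
#'
#' @param traj data.frame with `frame`, `x_um`, `y_um` (one track).
#' @param dt frame interval, s.
#' @param max_lag maximum lag in frames.
#' @return data.frame of class `MSDCurve`: `lag` (frames), `t_s`, `msd`
#'   (um^2), `n_pairs`.
#' @export
compute_msd <- function(traj, dt, max_lag = 20) {
  if (nrow(traj) < 2) stop("trajectory shorter than 2 points")
  f <- traj$frame
  idx <- rep(NA_integer_, max(f) - min(f) + 1L)
  idx[f - min(f) + 1L] <- seq_len(nrow(traj))
  x <- traj$x_um; y <- traj$y_um
  lags <- seq_len(min(max_lag, max(f) - min(f)))
  msd <- n_pairs <- numeric(length(lags))
  for (li in seq_along(lags)) {
    k <- lags[li]
    i0 <- idx[seq_len(length(idx) - k)]
    i1 <- idx[seq_len(length(idx) - k) + k]
    ok <- !is.na(i0) & !is.na(i1)
    n_pairs[li] <- sum(ok)
    msd[li] <- if (any(ok))
      mean((x[i1[ok]] - x[i0[ok]])^2 + (y[i1[ok]] - y[i0[ok]])^2) else NA_real_
  }
  structure(data.frame(lag = lags, t_s = lags * dt, msd = msd,
                       n_pairs = n_pairs),
            class = c("MSDCurve", "data.frame"), dt = dt)
}

#' Ensemble MSD across tracks
#'
#' Unweighted mean of per-track time-averaged MSDs at each lag, with the
#' SEM across tracks.
#'
#' @param ts a [trajectory_set()].
#' @param max_lag maximum lag in frames.
#' @param min_points only tracks with at least this many points enter.
#' @return data.frame of class `MSDCurve`: `lag`, `t_s`, `msd`, `sem`,
#'   `n_tracks`.
#' @export
ensemble_msd <- function(ts, max_lag = 20, min_points = 2) {
  stopifnot(inherits(ts, "TrajectorySet"))
  per <- lapply(split_tracks(ts), function(tr) {
    if (nrow(tr) < min_points) return(NULL)
    compute_msd(tr, ts$dt, max_lag)
  })
  per <- per[!vapply(per, is.null, logical(1))]
  if (length(per) == 0) stop("no usable tracks")
  m <- matrix(NA_real_, length(per), max_lag)
  for (i in seq_along(per)) {
    cu <- per[[i]]
    m[i, cu$lag] <- cu$msd
  }
  n_tr <- colSums(!is.na(m))
  msd <- colMeans(m, na.rm = TRUE)
  sem <- apply(m, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n_tr, 1))
  keep <- n_tr > 0
  structure(data.frame(lag = which(keep), t_s = which(keep) * ts$dt,
                       msd = msd[keep], sem = sem[keep],
                       n_tracks = n_tr[keep]),
            class = c("MSDCurve", "data.frame"), dt = ts$dt)
}

#' Linear (Brownian) diffusion-coefficient fit
#'
#' Least squares of `MSD = 4 D t` through the origin over the first
#' `n_lags` lags (default 6, i.e. 200 ms at 33-ms frames).
#'
#' @param msd an [compute_msd()] curve.
#' @param n_lags number of initial lags used.
#' @return list of class `DiffusionFit`: `D` (um^2/s), `alpha = 1`,
#'   `clamped` (TRUE when a negative slope was clamped to 0), `n_lags`.
#' @export
fit_linear_D <- function(msd, n_lags = 6) {
  use <- msd[msd$lag <= n_lags & !is.na(msd$msd), , drop = FALSE]
  if (nrow(use) < n_lags) stop("fewer than ", n_lags, " lags available")
  t4 <- 4 * use$t_s
  D <- sum(use$msd * t4) / sum(t4^2)
  clamped <- D < 0
  structure(list(D = max(D, 0), alpha = 1, clamped = clamped,
                 n_lags = n_lags,
                 residual = sqrt(sum((use$msd - 4 * max(D, 0) * use$t_s)^2))),
            class = "DiffusionFit")
}

#' Anomalous-diffusion fit MSD = 4 D t^alpha
#'
#' Nonlinear least squares over `(D, alpha)` with `D > 0` and
#' `0 < alpha < 2`, initialized from the log-log linear regression.
#' Default range: the first 20 lags (11 s at 551-ms frames).
#'
#' @param msd an MSD curve.
#' @param n_lags number of initial lags used.
#' @return list of class `DiffusionFit`: `D` (um^2/s, strictly
#'   um^2/s^alpha), `alpha`, `n_lags`, `residual`.
#' @export
fit_anomalous <- function(msd, n_lags = 20) {
  use <- msd[msd$lag <= n_lags & !is.na(msd$msd), , drop = FALSE]
  if (nrow(use) < n_lags) stop("fewer than ", n_lags, " lags available")
  if (all(use$msd <= 0)) stop("degenerate all-zero MSD")
  t <- use$t_s; y <- use$msd
  pos <- y > 0
  llfit <- stats::lm(log(y[pos]) ~ log(t[pos]))
  a0 <- min(max(unname(stats::coef(llfit)[2]), 0.05), 1.95)
  D0 <- exp(unname(stats::coef(llfit)[1])) / 4
  fit <- minpack.lm::nlsLM(y ~ 4 * D * t^alpha,
                           start = list(D = D0, alpha = a0),
                           lower = c(D = 1e-12, alpha = 1e-6),
                           upper = c(D = Inf, alpha = 2 - 1e-6),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(D = cf[["D"]], alpha = cf[["alpha"]], n_lags = n_lags,
                 residual = sqrt(sum(stats::resid(fit)^2))),
            class = "DiffusionFit")
}

#' @export
print.DiffusionFit <- function(x, ...) {
  cat(sprintf("DiffusionFit: D = %.4g um^2/s, alpha = %.3g (%d lags)\n",
              x$D, x$alpha, x$n_lags))
  invisible(x)
}

#' Per-track diffusion coefficients for a trajectory set
#'
#' @param ts a [trajectory_set()].
#' @param n_lags lags for the per-track linear fit.
#' @return data.frame: `track_id`, `D`, `n_points`.
#' @export
track_diffusion <- function(ts, n_lags = 6) {
  rows <- lapply(split_tracks(ts), function(tr) {
    cu <- try(compute_msd(tr, ts$dt, max_lag = n_lags), silent = TRUE)
    if (inherits(cu, "try-error") || sum(!is.na(cu$msd)) < n_lags) return(NULL)
    data.frame(track_id = tr$track_id[1],
               D = fit_linear_D(cu, n_lags)$D, n_points = nrow(tr))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Two-component Gaussian mixture fit of log10(D) and the bound threshold
#'
#' Fits the distribution of `log10(D)` with a two-component Gaussian
#' mixture and sets the bound/mobile threshold at the fast component's
#' mean minus 2 SD (`D_thr = 10^(mu_fast - 2 sd_fast)`), so that 97.7% of
#' a Gaussian fast component stays above threshold. Default route is EM on
#' the raw values; `method = "hist"` fits the binned histogram (bin width
#' 0.1 log10 units) by least squares instead.
#'
#' When the data do not support two components (model selection prefers
#' one, a component weight collapses below 1%, or a component SD
#' degenerates) the fit falls back to a single Gaussian with a warning.
#'
#' @param D positive diffusion coefficients (>= 100 values).
#' @param method `"em"` or `"hist"`.
#' @param k_sd SDs below the fast mean for the threshold (default 2).
#' @return list of class `MixtureFit`: `mu_slow`, `sd_slow`, `w_slow`,
#'   `mu_fast`, `sd_fast`, `w_fast`, `D_thr`, `bound_fraction`,
#'   `mobile_fraction`, `fallback`.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_logD_mixture <- function(D, method = c("em", "hist"), k_sd = 2) {
  method <- match.arg(method)
  if (length(D) < 100) stop("need >= 100 values")
  if (any(D <= 0)) stop("all D must be > 0")
  x <- log10(D)
  fallback <- FALSE
  if (method == "em") {
    fit <- mclust::Mclust(x, G = 1:2, modelNames = "V", verbose = FALSE)
    if (fit$G == 1L) {
      fallback <- TRUE
    } else {
      p <- fit$parameters
      mu <- p$mean; sd <- sqrt(p$variance$sigmasq); w <- p$pro
      if (min(w) < 0.01 || min(sd) < 1e-4) fallback <- TRUE
    }
  } else {
    bw <- 0.1
    br <- seq(floor(min(x) / bw) * bw, ceiling(max(x) / bw) * bw, by = bw)
    h <- graphics::hist(x, breaks = br, plot = FALSE)
    xc <- h$mids; yc <- h$counts
    n <- length(x)
    st <- list(m1 = stats::quantile(x, 0.2)[[1]], s1 = 0.3,
               m2 = stats::quantile(x, 0.8)[[1]], s2 = 0.3, w = 0.5)
    ft <- try(minpack.lm::nlsLM(
      yc ~ n * bw * (w * stats::dnorm(xc, m1, s1) +
                       (1 - w) * stats::dnorm(xc, m2, s2)),
      start = st,
      lower = c(m1 = min(x), s1 = 1e-3, m2 = min(x), s2 = 1e-3, w = 0),
      upper = c(m1 = max(x), s1 = Inf, m2 = max(x), s2 = Inf, w = 1),
      control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
    if (inherits(ft, "try-error")) {
      fallback <- TRUE
    } else {
      cf <- stats::coef(ft)
      mu <- c(cf[["m1"]], cf[["m2"]]); sd <- c(cf[["s1"]], cf[["s2"]])
      w <- c(cf[["w"]], 1 - cf[["w"]])
      if (min(w) < 0.01 || min(sd) < 1e-4) fallback <- TRUE
    }
  }
  if (fallback) {
    warning("mixture fit collapsed; single-component fallback")
    mu <- rep(mean(x), 2); sd <- rep(stats::sd(x), 2); w <- c(0.5, 0.5)
  }
  o <- order(mu)
  mu <- unname(mu[o]); sd <- unname(sd[o]); w <- unname(w[o])
  D_thr <- 10^(mu[2] - k_sd * sd[2])
  structure(list(mu_slow = mu[1], sd_slow = sd[1], w_slow = w[1],
                 mu_fast = mu[2], sd_fast = sd[2], w_fast = w[2],
                 D_thr = D_thr,
                 bound_fraction = mean(D <= D_thr),
                 mobile_fraction = mean(D > D_thr),
                 fallback = fallback, method = method),
            class = "MixtureFit")
}

#' @export
print.MixtureFit <- function(x, ...) {
  cat(sprintf(paste0("MixtureFit (%s): slow N(%.3f, %.3f) w=%.2f | ",
                     "fast N(%.3f, %.3f) w=%.2f\n  D_thr = %.4g um^2/s, ",
                     "bound %.1f%%\n"),
              x$method, x$mu_slow, x$sd_slow, x$w_slow, x$mu_fast, x$sd_fast,
              x$w_fast, x$D_thr, 100 * x$bound_fraction))
  invisible(x)
}

#' Confinement area from the 95% confidence ellipse
#'
#' Area of the confidence ellipse of the (x, y) point cloud:
#' `pi * q * sqrt(det(Sigma))` with `Sigma` the sample covariance and `q`
#' the chi-square quantile with 2 df at the requested confidence (5.991 at
#' 0.95), i.e. the ellipse expected to contain 95% of the points.
#'
#' @param traj data.frame with `x_um`, `y_um` (>= 10 points).
#' @param confidence coverage level.
#' @return list: `area_um2`, `inside_fraction` (empirical coverage),
#'   `sigma` (covariance matrix).
#' @export
confinement_area <- function(traj, confidence = 0.95) {
  if (nrow(traj) < 10) stop("need >= 10 points")
  xy <- cbind(traj$x_um, traj$y_um)
  S <- stats::cov(xy)
  dt <- det(S)
  if (!is.finite(dt) || dt <= 0) stop("degenerate covariance")
  q <- stats::qchisq(confidence, df = 2)
  ctr <- colMeans(xy)
  d2 <- stats::mahalanobis(xy, ctr, S)
  list(area_um2 = pi * q * sqrt(dt),
       inside_fraction = mean(d2 <= q), sigma = S)
}

#' Effective spring coefficient of a confined trajectory
#'
#' Regression of the centripetal step component on the distance from the
#' trajectory's center of mass. For each step `i`, with `com` the mean
#' position, `d_i = |r_i - com|` and
#' `c_i = (r_{i+1} - r_i) . (com - r_i) / d_i`; the effective spring
#' coefficient is the slope of `c_i ~ d_i` divided by `dt`, so a positive
#' value (1/s) measures centripetal restoring strength.
#'
#' @param traj data.frame with `x_um`, `y_um` (>= 10 points).
#' @param dt frame interval, s.
#' @return list: `k_per_s`, `slope_per_step`, `n_steps`.
#' @export
spring_coefficient <- function(traj, dt) {
  if (nrow(traj) < 10) stop("need >= 10 points")
  x <- traj$x_um; y <- traj$y_um
  com <- c(mean(x), mean(y))
  n <- length(x) - 1L
  dx <- com[1] - x[seq_len(n)]; dy <- com[2] - y[seq_len(n)]
  d <- sqrt(dx^2 + dy^2)
  sx <- diff(x); sy <- diff(y)
  use <- d > 0
  if (sum(use) < 5) stop("fewer than 5 usable steps")
  cvec <- (sx[use] * dx[use] + sy[use] * dy[use]) / d[use]
  if (stats::sd(d[use]) == 0) stop("zero variance in distances")
  slope <- unname(stats::coef(stats::lm(cvec ~ d[use]))[2])
  list(k_per_s = slope / dt, slope_per_step = slope, n_steps = sum(use))
}

#' Per-track motion metrics table
#'
#' Convenience summary: per-track D (6-lag linear fit), confinement area
#' and spring coefficient.
#'
#' @param ts a [trajectory_set()].
#' @param n_lags lags for the linear D fit.
#' @return data.frame: `track_id`, `D`, `area_um2`, `k_per_s`, `n_points`.
#' @export
motion_metrics <- function(ts, n_lags = 6) {
  rows <- lapply(split_tracks(ts), function(tr) {
    cu <- try(compute_msd(tr, ts$dt, max_lag = n_lags), silent = TRUE)
    if (inherits(cu, "try-error") || sum(!is.na(cu$msd)) < n_lags) return(NULL)
    area <- try(confinement_area(tr)$area_um2, silent = TRUE)
    k <- try(spring_coefficient(tr, ts$dt)$k_per_s, silent = TRUE)
    data.frame(track_id = tr$track_id[1],
               D = fit_linear_D(cu, n_lags)$D,
               area_um2 = if (inherits(area, "try-error")) NA_real_ else area,
               k_per_s = if (inherits(k, "try-error")) NA_real_ else k,
               n_points = nrow(tr))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
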