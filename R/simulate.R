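# Synthetic-data generators with known ground truth. Every downstream stage
# of the pipeline is exercised on these; no microscopy data are required.

#' Simulate a two-channel image pair of nuclear foci
#'
#' Renders `n_foci` diffraction-limited Gaussian spots inside a circular
#' "nucleus" in channel A. Channel B reuses `floor(rho * n_foci)` of A's
#' positions (the colocalized subset) and places the remainder
#' independently, so `rho` directly controls the colocalized fraction.
#'
#' @param n_foci number of foci per channel.
#' @param rho colocalized fraction in `[0, 1]`.
#' @param psf_sigma PSF Gaussian sigma in micrometres.
#' @param image_size image side in pixels (square frame).
#' @param pixel_size pixel size in micrometres. Default 0.065 um, typical of
#'   a high-resolution confocal system.
#' @param background diffuse background level in photons/pixel.
#' @param amplitude peak spot intensity in photons/pixel.
#' @param noise apply Poisson noise to `background + signal`?
#' @param amplitude_b peak intensity used for channel B (defaults to
#'   `amplitude`); lets tests check affine invariance of correlation.
#' @param min_separation minimum pairwise focus distance in um (0 = none);
#'   placement is rejection-sampled, so ground truth stays exact.
#' @param seed integer seed; fully determines the output.
#' @return list with `stack` (an [image_stack()] with axes `c,y,x`),
#'   `mask` (logical nucleus mask) and `truth` (positions and the shared
#'   subset).
#' @export
simulate_foci_image_pair <- function(n_foci, rho, psf_sigma = 0.13,
                                     image_size = 256, pixel_size = 0.065,
                                     background = 10, amplitude = 150,
                                     noise = TRUE, amplitude_b = amplitude,
                                     min_separation = 0, seed = 1L) {
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  if (psf_sigma <= 0 || image_size <= 0 || pixel_size <= 0)
    stop("sizes must be positive")
  with_seed(seed, {
    side_um <- image_size * pixel_size
    centre <- side_um / 2
    radius <- 0.4 * side_um
    draw_in_disk <- function(n, avoid = NULL) {
      out <- matrix(NA_real_, 0, 2)
      tries <- 0L
      while (nrow(out) < n) {
        r <- radius * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        p <- c(centre + r * cos(th), centre + r * sin(th))
        ref <- rbind(avoid, out)
        if (min_separation > 0 && nrow(ref) > 0 &&
            min(sqrt((ref[, 1] - p[1])^2 + (ref[, 2] - p[2])^2)) <
              min_separation) {
          tries <- tries + 1L
          if (tries > 10000L) stop("cannot satisfy min_separation")
          next
        }
        out <- rbind(out, p)
      }
      colnames(out) <- c("x", "y")
      out
    }
    pos_a <- draw_in_disk(n_foci)
    n_shared <- floor(rho * n_foci)
    pos_b <- rbind(pos_a[seq_len(n_shared), , drop = FALSE],
                   draw_in_disk(n_foci - n_shared))
    img_a <- background +
      render_spots(image_size, image_size, pos_a[, 1], pos_a[, 2],
                   amplitude, psf_sigma, pixel_size)
    img_b <- background +
      render_spots(image_size, image_size, pos_b[, 1], pos_b[, 2],
                   amplitude_b, psf_sigma, pixel_size)
    if (noise) {
      img_a[] <- stats::rpois(length(img_a), img_a)
      img_b[] <- stats::rpois(length(img_b), img_b)
    }
    cc <- col_to_um(col(img_a), pixel_size)
    rr <- row_to_um(row(img_a), pixel_size)
    mask <- (cc - centre)^2 + (rr - centre)^2 <= radius^2
    arr <- array(0, c(2L, image_size, image_size))
    arr[1, , ] <- img_a; arr[2, , ] <- img_b
    list(stack = image_stack(arr, "cyx", pixel_size = pixel_size),
         mask = mask,
         truth = list(pos_a = pos_a, pos_b = pos_b, n_shared = n_shared,
                      rho = rho, seed = seed, centre_um = centre,
                      radius_um = radius))
  })
}

fgn_covariance <- function(D, alpha, dt, n_steps) {
  # per-axis autocovariance of fractional Gaussian increments scaled so the
  # 2D ensemble MSD is 4*D*t^alpha
  k <- outer(seq_len(n_steps), seq_len(n_steps), function(i, j) abs(i - j))
  D * dt^alpha * (abs(k + 1)^alpha - 2 * abs(k)^alpha + abs(k - 1)^alpha)
}

#' Simulate fractional Brownian motion trajectories
#'
#' Generates 2D tracks whose ensemble mean squared displacement follows the
#' anomalous-diffusion law `MSD(t) = 4 D t^alpha` exactly (plus
#' `4 * loc_error^2` when a localization error is added). Each axis is an
#' independent fractional Gaussian-increment process synthesized by exact
#' covariance factorization (Cholesky), so the law holds at every lag, not
#' only asymptotically.
#'
#' @param D generalized diffusion coefficient (um^2/s^alpha; reported as
#'   um^2/s as is conventional).
#' @param alpha anomalous exponent in `(0, 2)`; 1 recovers Brownian motion.
#' @param dt frame interval in seconds.
#' @param n_steps number of displacement steps per track (track length is
#'   `n_steps + 1` points); limited to 1024 (exact synthesis is O(n^2)).
#' @param n_tracks number of tracks.
#' @param loc_error localization error sigma per axis, micrometres.
#' @param origin_spread tracks start uniformly in a square of this side
#'   (um); 0 starts all tracks at the origin.
#' @param seed integer seed.
#' @return a [trajectory_set()].
#' @export
simulate_fbm_tracks <- function(D, alpha, dt, n_steps, n_tracks,
                                loc_error = 0, origin_spread = 0, seed = 1L) {
  if (alpha <= 0 || alpha >= 2) stop("alpha must be in (0, 2)")
  if (D < 0) stop("D must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  if (n_steps > 1024) stop("n_steps > 1024 not supported by exact synthesis")
  with_seed(seed, {
    n_pts <- n_steps + 1L
    if (D > 0) {
      L <- t(chol(fgn_covariance(D, alpha, dt, n_steps)))
      zx <- matrix(stats::rnorm(n_steps * n_tracks), n_steps)
      zy <- matrix(stats::rnorm(n_steps * n_tracks), n_steps)
      dx <- L %*% zx; dy <- L %*% zy
    } else {
      dx <- dy <- matrix(0, n_steps, n_tracks)
    }
    x0 <- stats::runif(n_tracks, 0, origin_spread)
    y0 <- stats::runif(n_tracks, 0, origin_spread)
    x <- rbind(x0, sweep(apply(dx, 2, cumsum), 2, x0, `+`))
    y <- rbind(y0, sweep(apply(dy, 2, cumsum), 2, y0, `+`))
    if (loc_error > 0) {
      x <- x + stats::rnorm(length(x), 0, loc_error)
      y <- y + stats::rnorm(length(y), 0, loc_error)
    }
    tracks <- data.frame(
      track_id = rep(seq_len(n_tracks), each = n_pts),
      frame = rep(seq_len(n_pts), n_tracks),
      x_um = as.vector(x), y_um = as.vector(y))
    trajectory_set(tracks, dt = dt,
                   provenance = sprintf("fbm D=%g alpha=%g seed=%d",
                                        D, alpha, seed))
  })
}

#' Simulate a two-population single-molecule movie
#'
#' Mobile molecules follow Brownian motion with `D_mobile`; bound molecules
#' follow a discretized mean-reverting (spring) process with relaxation rate
#' `kappa` around a fixed anchor and per-step variance `4 * D_bound * dt`.
#' Anchors are seeded inside enriched pixels of `map` (value > 0.5) with
#' probability `placement_bias`, outside otherwise. Molecules are rendered
#' as pixel-integrated Gaussian spots over a Poisson background.
#'
#' @param n_bound,n_mobile molecules per population.
#' @param D_mobile,D_bound diffusion coefficients, um^2/s.
#' @param kappa spring relaxation rate, 1/s (`kappa * dt` < 1 required for
#'   the explicit discretization).
#' @param map enrichment map matrix in `[0, 1]` defining the field size.
#' @param placement_bias probability that a bound anchor is seeded in an
#'   enriched (`map > 0.5`) pixel.
#' @param dt frame interval, s. Default 1/30 s, typical of HILO
#'   single-molecule acquisition.
#' @param n_frames frames to simulate.
#' @param pixel_size um/pixel (default 0.080, single-molecule camera scale).
#' @param psf_sigma PSF sigma, um.
#' @param amplitude peak molecule intensity, photons/pixel.
#' @param background background level, photons/pixel.
#' @param enriched_D_factor multiply `D_bound` by this factor for bound
#'   molecules whose anchor lies in an enriched pixel (1 = no difference).
#' @param noise apply Poisson noise?
#' @param seed integer seed.
#' @return list with `movie` (ImageStack `t,y,x`), `map`, `truth`
#'   (per-molecule table: id, label, anchor, `in_enriched`, true D) and
#'   `paths` (a [trajectory_set()] of the exact simulated positions).
#' @export
simulate_two_population_movie <- function(n_bound, n_mobile,
                                          D_mobile = 0.5, D_bound = 0.01,
                                          kappa = 2, map,
                                          placement_bias = 0.5,
                                          dt = 1 / 30, n_frames = 50,
                                          pixel_size = 0.080,
                                          psf_sigma = 0.12,
                                          amplitude = 300, background = 20,
                                          enriched_D_factor = 1,
                                          noise = TRUE, seed = 1L) {
  if (length(map) == 0) stop("map is empty")
  if (kappa < 0 || D_mobile < 0 || D_bound < 0) stop("rates must be >= 0")
  if (kappa * dt >= 1) stop("kappa * dt must be < 1")
  with_seed(seed, {
    nr <- nrow(map); nc <- ncol(map)
    w_um <- nc * pixel_size; h_um <- nr * pixel_size
    n <- n_bound + n_mobile
    label <- rep(c("bound", "mobile"), c(n_bound, n_mobile))
    enr <- which(map > 0.5, arr.ind = TRUE)
    non <- which(map <= 0.5, arr.ind = TRUE)
    if (n_bound > 0 && nrow(enr) == 0 && placement_bias > 0)
      stop("map has no enriched pixels but placement_bias > 0")
    pick_px <- function(tab) {
      i <- tab[sample.int(nrow(tab), 1L), ]
      c(x = col_to_um(i[["col"]], pixel_size) +
          stats::runif(1, -0.5, 0.5) * pixel_size,
        y = row_to_um(i[["row"]], pixel_size) +
          stats::runif(1, -0.5, 0.5) * pixel_size)
    }
    anchors <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
    for (i in seq_len(n_bound)) {
      use_enr <- stats::runif(1) < placement_bias && nrow(enr) > 0
      anchors[i, ] <- pick_px(if (use_enr) enr else non)
    }
    if (n_mobile > 0)
      anchors[n_bound + seq_len(n_mobile), ] <-
        cbind(stats::runif(n_mobile, 0, w_um), stats::runif(n_mobile, 0, h_um))
    a_col <- um_to_col(anchors[, "x"], pixel_size)
    a_row <- um_to_row(anchors[, "y"], pixel_size)
    a_col <- pmin(a_col, nc); a_row <- pmin(a_row, nr)
    in_enriched <- map[cbind(a_row, a_col)] > 0.5
    D_true <- ifelse(label == "mobile", D_mobile,
                     D_bound * ifelse(in_enriched, enriched_D_factor, 1))
    # per-axis step sd: MSD per step = 4 D dt => var per axis = 2 D dt
    sd_step <- sqrt(2 * D_true * dt)
    x <- matrix(NA_real_, n_frames, n); y <- matrix(NA_real_, n_frames, n)
    x[1, ] <- anchors[, "x"]; y[1, ] <- anchors[, "y"]
    bound <- label == "bound"
    for (f in 2:n_frames) {
      ex <- stats::rnorm(n, 0, sd_step); ey <- stats::rnorm(n, 0, sd_step)
      px <- x[f - 1, ]; py <- y[f - 1, ]
      px[bound] <- px[bound] - kappa * dt * (px[bound] - anchors[bound, "x"])
      py[bound] <- py[bound] - kappa * dt * (py[bound] - anchors[bound, "y"])
      nx <- px + ex; ny <- py + ey
      # reflect mobile molecules at the field boundary
      nx <- ifelse(nx < 0, -nx, ifelse(nx > w_um, 2 * w_um - nx, nx))
      ny <- ifelse(ny < 0, -ny, ifelse(ny > h_um, 2 * h_um - ny, ny))
      x[f, ] <- nx; y[f, ] <- ny
    }
    arr <- array(0, c(n_frames, nr, nc))
    for (f in seq_len(n_frames)) {
      fr <- background + render_spots(nr, nc, x[f, ], y[f, ],
                                      amplitude, psf_sigma, pixel_size)
      if (noise) fr[] <- stats::rpois(length(fr), fr)
      arr[f, , ] <- fr
    }
    paths <- trajectory_set(
      data.frame(track_id = rep(seq_len(n), each = n_frames),
                 frame = rep(seq_len(n_frames), n),
                 x_um = as.vector(x[, ]), y_um = as.vector(y)),
      dt = dt, pixel_size = pixel_size, provenance = "two-population movie")
    truth <- data.frame(id = seq_len(n), label = label,
                        anchor_x = anchors[, "x"], anchor_y = anchors[, "y"],
                        in_enriched = in_enriched, D_true = D_true)
    list(movie = image_stack(arr, "tyx", pixel_size = pixel_size,
                             frame_interval = dt),
         map = map, truth = truth, paths = paths)
  })
}

#' Sample a labelled two-component log10(D) mixture
#'
#' Draws diffusion coefficients whose `log10` values follow a two-component
#' Gaussian mixture, with the true component label of every sample, for
#' testing bound/mobile classification.
#'
#' @param mu_slow,sd_slow,mu_fast,sd_fast component parameters in
#'   log10(um^2/s).
#' @param w_fast weight of the fast component in `(0, 1)` (0 and 1 allowed
#'   for single-component draws).
#' @param n number of samples (>= 2).
#' @param seed integer seed.
#' @return data.frame with `D`, `logD`, `component` (`"slow"`/`"fast"`).
#' @export
sample_logD_mixture <- function(mu_slow = -1.8, sd_slow = 0.3,
                                mu_fast = -0.3, sd_fast = 0.25,
                                w_fast = 0.6, n = 1e4, seed = 1L) {
  if (n < 2) stop("n must be >= 2")
  if (sd_slow <= 0 || sd_fast <= 0) stop("sds must be > 0")
  if (w_fast < 0 || w_fast > 1) stop("w_fast must be in [0, 1]")
  with_seed(seed, {
    fast <- stats::runif(n) < w_fast
    logD <- ifelse(fast, stats::rnorm(n, mu_fast, sd_fast),
                   stats::rnorm(n, mu_slow, sd_slow))
    data.frame(D = 10^logD, logD = logD,
               component = ifelse(fast, "fast", "slow"))
  })
}

#' Closed-form FRAP recovery model used by the simulator
#'
#' Normalized bleach-spot signal at time `t >= 0` after the bleach:
#' `1 - bleach_depth * (1 - mobile_fraction * (1 - exp(-t / tau)))`.
#'
#' @param t time since bleach, s.
#' @param bleach_depth fraction of signal removed by the bleach.
#' @param mobile_fraction recovering fraction.
#' @param tau recovery time constant, s.
#' @export
frap_model <- function(t, bleach_depth, mobile_fraction, tau) {
  1 - bleach_depth * (1 - mobile_fraction * (1 - exp(-t / tau)))
}

#' Simulate a FRAP bleach/reference/background triplet
#'
#' Single-exponential recovery of a bleached spot with optional
#' acquisition photobleaching that decays both the bleach-spot and the
#' reference series (and therefore cancels under double normalization).
#'
#' @param bleach_depth,mobile_fraction fractions in `[0, 1]`.
#' @param tau recovery time constant, s.
#' @param acquisition_bleach_rate 1/s decay applied to bleach and reference.
#' @param dt frame interval, s (default 0.0478 s).
#' @param n_pre,n_post pre- and post-bleach frame counts (`n_pre >= 1`).
#' @param noise_sd additive Gaussian noise sd, a.u.
#' @param baseline,ref_level,bkg_level raw intensity scales, a.u.
#' @param seed integer seed.
#' @return data.frame of class `FRAPCurve` with columns `t`, `bleach`,
#'   `reference`, `background`; attribute `n_pre`.
#' @export
simulate_frap_curve <- function(bleach_depth = 0.6, mobile_fraction = 1,
                                tau = 0.5, acquisition_bleach_rate = 0,
                                dt = 0.0478, n_pre = 10, n_post = 250,
                                noise_sd = 0, baseline = 100,
                                ref_level = 120, bkg_level = 10, seed = 1L) {
  if (n_pre < 1) stop("n_pre must be >= 1")
  if (bleach_depth < 0 || bleach_depth > 1 ||
      mobile_fraction < 0 || mobile_fraction > 1)
    stop("fractions must be in [0, 1]")
  if (tau <= 0) stop("tau must be > 0")
  with_seed(seed, {
    t <- (seq_len(n_pre + n_post) - n_pre - 1L) * dt  # bleach at t = 0^-
    rec <- ifelse(t < 0, 1, frap_model(t, bleach_depth, mobile_fraction, tau))
    decay <- exp(-acquisition_bleach_rate * (t - t[1]))
    curve <- data.frame(
      t = t,
      bleach = bkg_level + baseline * rec * decay +
        stats::rnorm(length(t), 0, noise_sd),
      reference = bkg_level + ref_level * decay +
        stats::rnorm(length(t), 0, noise_sd),
      background = bkg_level + stats::rnorm(length(t), 0, noise_sd))
    attr(curve, "n_pre") <- n_pre
    class(curve) <- c("FRAPCurve", "data.frame")
    curve
  })
}

#' Make a blob-style enrichment map for simulations
#'
#' Gaussian blobs on a dark field, normalized to `[0, 1]`; pixels well
#' inside a blob exceed 0.5 and count as "enriched".
#'
#' @param nrow,ncol map size in pixels.
#' @param n_blobs number of enriched blobs.
#' @param blob_sigma_px blob Gaussian sigma in pixels.
#' @param seed integer seed.
#' @return matrix in `[0, 1]`.
#' @export
make_blob_map <- function(nrow = 128, ncol = 128, n_blobs = 12,
                          blob_sigma_px = 4, seed = 1L) {
  with_seed(seed, {
    # one blob per randomly chosen cell of a coarse grid (jittered), so
    # blobs never merge and each one's core stays above the 0.5 enrichment
    # level after clipping
    cell <- max(4 * blob_sigma_px, 8)
    gx <- floor(ncol / cell); gy <- floor(nrow / cell)
    if (gx * gy < n_blobs)
      stop("map too small for ", n_blobs, " separated blobs")
    cells <- sample.int(gx * gy, n_blobs)
    cx <- ((cells - 1) %% gx) * cell + cell / 2 +
      stats::runif(n_blobs, -0.15, 0.15) * cell
    cy <- ((cells - 1) %/% gx) * cell + cell / 2 +
      stats::runif(n_blobs, -0.15, 0.15) * cell
    m <- render_spots(nrow, ncol, cx, cy, amplitude = 1,
                      psf_sigma_um = blob_sigma_px, pixel_size = 1)
    pmin(m, 1)
  })
}
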