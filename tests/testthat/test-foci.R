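# Focus detection, 3D counting, FWHM sizing, N/C ratio, area time course.

px <- 0.065

test_that("well-separated bright spots are each detected within 1 px", {
  sim <- simulate_foci_image_pair(10, rho = 1, noise = FALSE,
                                  image_size = 128, amplitude = 200,
                                  min_separation = 1, seed = 31)
  img <- get_frame(sim$stack, c = 1)
  sp <- detect_spots(img, px, typical_diameter = 7, sd_factor = 2,
                     min_contrast = 5)
  expect_identical(nrow(sp), 10L)
  d <- sqrt(outer(sp$x_um, sim$truth$pos_a[, 1], `-`)^2 +
              outer(sp$y_um, sim$truth$pos_a[, 2], `-`)^2)
  expect_lt(max(apply(d, 2, min)), px)  # every true focus found within 1 px
})

test_that("blank noisy fields yield zero spots once contrast is calibrated", {
  set.seed(32)
  blank <- matrix(rpois(128 * 128, 10), 128)
  raw <- detect_spots(blank, px, typical_diameter = 7, sd_factor = 2,
                      min_contrast = 0)
  floor_c <- if (nrow(raw)) max(raw$contrast) * 1.01 else 0.1
  blank2 <- matrix(rpois(128 * 128, 10), 128)
  sp <- detect_spots(blank2, px, typical_diameter = 7, sd_factor = 2,
                     min_contrast = floor_c)
  expect_identical(nrow(sp), 0L)
  expect_error(detect_spots(blank, px, typical_diameter = 2), "diameter")
})

test_that("detection is invariant under affine rescaling with contrast rescaled", {
  sim <- simulate_foci_image_pair(25, rho = 1, noise = FALSE,
                                  image_size = 128, seed = 33)
  img <- get_frame(sim$stack, c = 1)
  s1 <- detect_spots(img, px, min_contrast = 5)
  s2 <- detect_spots(3 * img + 40, px, min_contrast = 15)
  expect_identical(nrow(s1), nrow(s2))
  expect_equal(s1$x_um, s2$x_um, tolerance = 1e-8)
})

test_that("two spots one pixel apart merge into a single detection", {
  img <- matrix(5, 64, 64)
  img <- img + mintdyn:::render_spots(64, 64, c(30, 31) * px, c(30, 30) * px,
                                      200, 1.5 * px, px)
  sp <- detect_spots(img, px, typical_diameter = 7, min_contrast = 5)
  expect_identical(nrow(sp), 1L)
})

test_that("3D counting applies the divide-by-3 correction", {
  # 12 foci, each rendered identically in exactly 3 adjacent sections
  xy <- as.matrix(expand.grid(seq(1.2, 7, by = 1.4),
                              seq(1.2, 4.2, by = 1.4)))[1:12, ]
  frame <- matrix(5, 128, 128) +
    mintdyn:::render_spots(128, 128, xy[, 1], xy[, 2], 200, 2 * px, px)
  blank <- matrix(5, 128, 128)
  zstack <- c(list(blank), rep(list(frame), 3), list(blank))
  res <- count_foci_3d(zstack, px, min_contrast = 5)
  expect_identical(res$raw, 36L)
  expect_identical(res$corrected, 12L)
  # empty stack counts zero
  expect_identical(count_foci_3d(rep(list(blank), 3), px,
                                 min_contrast = 5)$corrected, 0L)
  # foci spanning only 2 sections are undercounted by 1/3 by construction
  res2 <- count_foci_3d(c(list(blank), rep(list(frame), 2)), px,
                        min_contrast = 5)
  expect_identical(res2$corrected, 8L)
  expect_warning(count_foci_3d(list(frame), px, min_contrast = 5),
                 "single-section")
})

test_that("FWHM fit recovers the analytic width on noiseless spots", {
  d_px <- 1.5
  centre <- 32.5 * px   # a pixel-center position
  img <- point_gauss_image(64, 64, 32.5, 32.5, 100, d_px, bg = 7)
  fit <- fit_line_fwhm(img, c(centre - 1, centre), c(centre + 1, centre),
                       thickness = 1, pixel_size = px)
  expect_equal(fit$fwhm_um, 2 * sqrt(2 * log(2)) * d_px * px,
               tolerance = 0.01)
  expect_equal(fit$c, 1, tolerance = 0.02)  # center at mid-line
  expect_error(fit_line_fwhm(matrix(5, 64, 64), c(1, 1), c(2, 1),
                             pixel_size = px), "peak")
  expect_error(fit_line_fwhm(img, c(1, 1), c(1.1, 1), pixel_size = px),
               "shorter")
})

test_that("FWHM is robust to Poisson noise at amplitude 10x background", {
  d_px <- 1.5
  true_fwhm <- 2 * sqrt(2 * log(2)) * d_px * px
  set.seed(35)
  errs <- vapply(1:40, function(i) {
    img <- point_gauss_image(64, 64, 32.5, 32.5, 100, d_px, bg = 10)
    img[] <- rpois(length(img), img)
    fit <- fit_line_fwhm(img, c(32.5 * px - 1, 32.5 * px),
                         c(32.5 * px + 1, 32.5 * px),
                         thickness = 3, pixel_size = px)
    abs(fit$fwhm_um - true_fwhm) / true_fwhm
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("N/C ratio arithmetic and recovery under noise", {
  img <- matrix(0.5, 60, 60)
  nuc <- matrix(FALSE, 60, 60); nuc[20:40, 20:40] <- TRUE
  cell <- matrix(FALSE, 60, 60); cell[10:50, 10:50] <- TRUE
  bkg <- matrix(FALSE, 60, 60); bkg[1:5, 1:5] <- TRUE
  img[cell] <- 1.5; img[nuc] <- 3
  expect_equal(nc_ratio(img, nuc, cell, bkg), 2.5 / 1.0)
  # uniform cell: ratio 1
  img2 <- matrix(0.2, 60, 60); img2[cell] <- 2
  expect_equal(nc_ratio(img2, nuc, cell, bkg), 1)
  # Poisson noise, true ratio 4: recovered within 5%
  set.seed(36)
  img3 <- matrix(10, 60, 60); img3[cell] <- 60; img3[nuc] <- 210
  img3[] <- rpois(length(img3), img3)
  expect_equal(nc_ratio(img3, nuc, cell, bkg), 4, tolerance = 0.05)
  expect_error(nc_ratio(img, nuc, nuc, bkg), "area")
  expect_error(nc_ratio(img, cell, nuc, bkg), "inside")
})

test_that("relative foci area tracks amplitude decay and spot count", {
  set.seed(37)
  mask <- matrix(TRUE, 128, 128)
  xy <- cbind(runif(20, 1, 7), runif(20, 1, 7))
  mk_frame <- function(amp, n = 20) {
    matrix(rpois(128 * 128, 10), 128) +
      mintdyn:::render_spots(128, 128, xy[seq_len(n), 1], xy[seq_len(n), 2],
                             amp, 2 * px, px)
  }
  f0 <- mk_frame(300)
  same <- foci_area_series(list(f0, f0), mask)
  expect_equal(same$relative, c(1, 1))
  # amplitudes decaying to background: relative area goes to ~0
  dec <- foci_area_series(lapply(c(300, 150, 60, 20, 0), mk_frame), mask)
  expect_lt(tail(dec$relative, 1), 0.25)
  expect_true(all(diff(dec$relative) < 0.15))
  # doubling the spot count roughly doubles the area
  dbl <- foci_area_series(list(mk_frame(300, 10), mk_frame(300, 20)), mask)
  expect_equal(dbl$relative[2], 2, tolerance = 0.35)
  expect_error(foci_area_series(list(f0), mask), "2 time points")
})
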