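# Colocalization: rotation-averaged shifted-Pearson cross-correlation and
# normalized line profiles.

rotate90_about <- function(img, mask, angle, centre_rc) {
  # nearest-neighbour rotation of img (and mask) by a multiple of 90 degrees
  # about centre_rc = c(row, col); pixels mapped from outside become NA/FALSE
  if (angle %% 360 == 0) return(list(img = img, mask = mask))
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  nr <- nrow(img); nc <- ncol(img)
  rr <- row(img) - centre_rc[1]; cc <- col(img) - centre_rc[2]
  # inverse rotation: source = R(-th) * target
  sr <- round(ct * rr + st * cc + centre_rc[1])
  sc <- round(-st * rr + ct * cc + centre_rc[2])
  ok <- sr >= 1 & sr <= nr & sc >= 1 & sc <= nc
  out <- matrix(NA_real_, nr, nc)
  mout <- matrix(FALSE, nr, nc)
  out[ok] <- img[cbind(sr[ok], sc[ok])]
  mout[ok] <- mask[cbind(sr[ok], sc[ok])]
  list(img = out, mask = mout)
}

shift_x <- function(img, mask, dx) {
  # shift image content by dx columns (positive = content moves right),
  # no wrap-around
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(NA_real_, nr, nc); mout <- matrix(FALSE, nr, nc)
  if (dx >= 0) {
    if (dx < nc) {
      out[, (1 + dx):nc] <- img[, 1:(nc - dx)]
      mout[, (1 + dx):nc] <- mask[, 1:(nc - dx)]
    }
  } else {
    if (-dx < nc) {
      out[, 1:(nc + dx)] <- img[, (1 - dx):nc]
      mout[, 1:(nc + dx)] <- mask[, (1 - dx):nc]
    }
  }
  list(img = out, mask = mout)
}

#' Shifted-Pearson cross-correlation function between two channels
#'
#' Both channels are Gaussian-filtered (sigma `gauss_radius` px, suppressing
#' pixel-to-pixel sensitivity variation), the within-mask mean of each is
#' subtracted, and Pearson correlation is computed between channel A and
#' channel B shifted laterally by x pixels over the overlap of both masks
#' (no wrap-around). The procedure is repeated with channel B rotated by
#' 90/180/270 degrees about the mask centroid and the four r(x) curves are
#' averaged; rotations destroy true colocalization but keep the intensity
#' statistics, so they act as an internal randomization control.
#'
#' @param image_a,image_b co-registered 2D matrices of equal shape.
#' @param mask logical nucleus mask.
#' @param pixel_size um/pixel (for the shift axis in um).
#' @param max_shift maximum |x| shift in pixels (default 100).
#' @param gauss_radius Gaussian prefilter sigma in pixels (default 2).
#' @param rotations angles (degrees, multiples of 90) averaged over.
#' @param report_range shifts reported, default -50..50 px.
#' @param min_overlap minimum mask-overlap pixel count per shift.
#' @return data.frame of class `CCFProfile`: `shift_px`, `shift_um`,
#'   `r_mean`, plus one `r_<angle>` column per rotation.
#' @export
compute_ccf <- function(image_a, image_b, mask, pixel_size,
                        max_shift = 100, gauss_radius = 2,
                        rotations = c(0, 90, 180, 270),
                        report_range = 50, min_overlap = 100) {
  stopifnot(all(dim(image_a) == dim(image_b)),
            all(dim(image_a) == dim(mask)))
  if (!any(mask)) stop("mask is empty")
  a <- gauss_blur(image_a, gauss_radius)
  b <- gauss_blur(image_b, gauss_radius)
  a <- a - mean(a[mask])
  b <- b - mean(b[mask])
  ij <- which(mask, arr.ind = TRUE)
  centre <- c(mean(ij[, 1]), mean(ij[, 2]))
  shifts <- -max_shift:max_shift
  rcols <- list()
  for (ang in rotations) {
    rb <- rotate90_about(b, mask, ang, centre)
    # shift x samples channel B at +x, so a copy translated by +k px in x
    # produces a correlation peak at x = +k
    r <- vapply(shifts, function(dx) {
      sb <- shift_x(rb$img, rb$mask, -dx)
      ov <- mask & sb$mask
      n <- sum(ov)
      if (n < min_overlap)
        stop("mask overlap < ", min_overlap, " px at shift ", dx)
      va <- a[ov]; vb <- sb$img[ov]
      if (stats::sd(va) == 0 || stats::sd(vb) == 0)
        stop("constant channel within overlap at shift ", dx)
      stats::cor(va, vb)
    }, numeric(1))
    rcols[[paste0("r_", ang)]] <- r
  }
  r_mean <- Reduce(`+`, rcols) / length(rcols)
  out <- data.frame(shift_px = shifts, shift_um = shifts * pixel_size,
                    r_mean = r_mean)
  for (nm in names(rcols)) out[[nm]] <- rcols[[nm]]
  keep <- abs(out$shift_px) <= report_range
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("CCFProfile", "data.frame"),
            gauss_radius = gauss_radius, rotations = rotations)
}

#' Normalized line intensity profiles across one or two channels
#'
#' Profiles are the mean across `thickness` pixels perpendicular to the
#' line, sampled at one-pixel steps. Two normalization modes: `"minmax"`
#' rescales each channel's profile so its minimum is 0 and maximum is 1;
#' `"nuclear_mean"` expresses intensity relative to the average nuclear
#' intensity after subtracting a cytoplasmic baseline:
#' `(I - cyto) / (nuclear_mean - cyto)`.
#'
#' @param images a single matrix or list of channel matrices.
#' @param p0_um,p1_um line endpoints in um (`c(x, y)`).
#' @param thickness perpendicular averaging thickness, pixels.
#' @param mode `"minmax"` or `"nuclear_mean"`.
#' @param pixel_size um/pixel.
#' @param nuclear_mean per-channel average nuclear intensity (required for
#'   `"nuclear_mean"`).
#' @param cyto per-channel cytoplasmic baseline subtracted first (default 0).
#' @return data.frame: `s_um` plus one normalized column per channel.
#' @export
line_profile <- function(images, p0_um, p1_um, thickness = 3,
                         mode = c("minmax", "nuclear_mean"),
                         pixel_size, nuclear_mean = NULL, cyto = 0) {
  mode <- match.arg(mode)
  if (is.matrix(images)) images <- list(images)
  len <- sqrt(sum((p1_um - p0_um)^2))
  if (len <= 0) stop("zero-length line")
  if (thickness < 1) stop("thickness must be >= 1")
  out <- NULL
  for (i in seq_along(images)) {
    sl <- sample_line(images[[i]], p0_um, p1_um, thickness, pixel_size)
    p <- sl$profile
    if (mode == "minmax") {
      rng <- range(p)
      if (rng[1] == rng[2]) stop("flat profile in minmax mode")
      p <- (p - rng[1]) / (rng[2] - rng[1])
    } else {
      if (is.null(nuclear_mean)) stop("nuclear_mean required")
      nm <- rep_len(nuclear_mean, length(images))[i]
      cy <- rep_len(cyto, length(images))[i]
      p <- (p - cy) / (nm - cy)
    }
    if (is.null(out)) out <- data.frame(s_um = sl$s)
    out[[paste0("ch", i)]] <- p
  }
  out
}
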