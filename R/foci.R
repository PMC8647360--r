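# Detection and quantification of sub-diffraction nuclear foci.

#' Detect bright foci in a single frame
#'
#' Band-pass enhancement (difference of Gaussians matched to the typical
#' spot diameter), local maxima, and two gates: the enhanced value must
#' exceed the local mean by `sd_factor` local SDs, and the raw contrast
#' (peak minus local background) must reach `min_contrast`. Sub-pixel
#' positions by intensity centroid of the 3x3 neighbourhood. Defaults mirror
#' a typical spot-detector parameterization (7-pixel diameter, 2 SD).
#'
#' Two maxima closer than about one spot radius merge into a single
#' detection; that is the documented behaviour, not an error.
#'
#' @param image 2D matrix.
#' @param pixel_size um/pixel.
#' @param typical_diameter expected spot diameter in pixels (>= 3).
#' @param sd_factor SD multiplication factor for the local threshold.
#' @param min_contrast raw-intensity contrast floor (a.u.); calibrate on a
#'   blank field so noise-only images yield zero detections.
#' @param mask optional logical mask restricting detections.
#' @return data.frame: `x_um`, `y_um`, `row`, `col`, `peak` (raw),
#'   `enhanced`, `contrast`, `diameter_um`.
#' @export
detect_spots <- function(image, pixel_size, typical_diameter = 7,
                         sd_factor = 2, min_contrast = 0, mask = NULL) {
  stopifnot(is.matrix(image))
  if (typical_diameter < 3) stop("typical_diameter must be >= 3 px")
  s1 <- typical_diameter / (2 * 2.355)        # sigma ~ FWHM/2.355, FWHM ~ d/2
  s2 <- 2 * s1
  dog <- gauss_blur(image, s1) - gauss_blur(image, s2)
  stats_loc <- local_mean_sd(dog, halfwidth = 2L * as.integer(typical_diameter))
  bg_loc <- box_filter(image, 2L * as.integer(typical_diameter))
  mx <- local_maxima(dog)
  if (nrow(mx) == 0)
    return(data.frame(x_um = numeric(0), y_um = numeric(0), row = integer(0),
                      col = integer(0), peak = numeric(0),
                      enhanced = numeric(0), contrast = numeric(0),
                      diameter_um = numeric(0)))
  idx <- cbind(mx[, 1], mx[, 2])
  enh <- dog[idx]
  thr <- stats_loc$mean[idx] + sd_factor * stats_loc$sd[idx]
  contrast <- image[idx] - bg_loc[idx]
  keep <- enh > thr & contrast >= min_contrast
  if (!is.null(mask)) keep <- keep & mask[idx]
  mx <- mx[keep, , drop = FALSE]
  if (nrow(mx) == 0)
    return(data.frame(x_um = numeric(0), y_um = numeric(0), row = integer(0),
                      col = integer(0), peak = numeric(0),
                      enhanced = numeric(0), contrast = numeric(0),
                      diameter_um = numeric(0)))
  # sub-pixel centroid on the background-subtracted 3x3 neighbourhood
  nr <- nrow(image); nc <- ncol(image)
  sub_r <- sub_c <- numeric(nrow(mx))
  for (i in seq_len(nrow(mx))) {
    r <- mx[i, 1]; c <- mx[i, 2]
    rr <- max(1, r - 1):min(nr, r + 1); cc <- max(1, c - 1):min(nc, c + 1)
    w <- pmax(dog[rr, cc, drop = FALSE], 0)
    if (sum(w) == 0) { sub_r[i] <- r; sub_c[i] <- c; next }
    sub_r[i] <- sum(outer(rr, rep(1, length(cc))) * w) / sum(w)
    sub_c[i] <- sum(outer(rep(1, length(rr)), cc) * w) / sum(w)
  }
  o <- order(mx[, 1], mx[, 2])   # deterministic (row, col) order
  data.frame(x_um = col_to_um(sub_c, pixel_size)[o],
             y_um = row_to_um(sub_r, pixel_size)[o],
             row = mx[o, 1], col = mx[o, 2],
             peak = image[cbind(mx[o, 1], mx[o, 2])],
             enhanced = dog[cbind(mx[o, 1], mx[o, 2])],
             contrast = contrast[keep][o],
             diameter_um = typical_diameter * pixel_size)
}

#' Count foci in a z-stack with the divide-by-3 correction
#'
#' Runs [detect_spots()] in every z-section and sums the counts. Because a
#' single sub-diffraction focus is detected in at most three consecutive
#' 0.2-um sections, the summed count is divided by 3 and rounded. Foci
#' spanning fewer sections are under-counted by the same rule — a
#' documented bias of the correction, not of this implementation.
#'
#' @param zstack list of 2D matrices (one per z-section) or an
#'   [image_stack()] with a `z` axis.
#' @param pixel_size um/pixel.
#' @param ... passed to [detect_spots()].
#' @return list: `corrected` (integer), `raw` (total detections),
#'   `per_section` (integer vector).
#' @export
count_foci_3d <- function(zstack, pixel_size, ...) {
  if (inherits(zstack, "ImageStack")) {
    iz <- match("z", zstack$axes)
    nz <- if (is.na(iz)) 1L else dim(zstack$data)[iz]
    zstack <- lapply(seq_len(nz), function(z) get_frame(zstack, z = z))
  }
  per <- vapply(zstack, function(im)
    nrow(detect_spots(im, pixel_size, ...)), integer(1))
  raw <- sum(per)
  div <- 3
  if (length(zstack) == 1L) {
    warning("single-section input: divide-by-3 correction not applicable")
    div <- 1
  }
  list(corrected = as.integer(round(raw / div)), raw = raw,
       per_section = per)
}

sample_line <- function(image, p0_um, p1_um, thickness, pixel_size) {
  # mean-across-thickness profile sampled at one-pixel steps along the line
  len <- sqrt(sum((p1_um - p0_um)^2))
  n <- max(2L, floor(len / pixel_size) + 1L)
  s <- seq(0, len, length.out = n)
  u <- (p1_um - p0_um) / len                # unit vector along the line
  v <- c(-u[2], u[1])                       # unit normal
  offs <- (seq_len(thickness) - (thickness + 1) / 2) * pixel_size
  prof <- numeric(n)
  nr <- nrow(image); nc <- ncol(image)
  for (i in seq_len(n)) {
    pts <- t(vapply(offs, function(o) p0_um + s[i] * u + o * v, numeric(2)))
    # bilinear interpolation at physical points
    cx <- pts[, 1] / pixel_size - 0.5 + 1   # fractional column
    cy <- pts[, 2] / pixel_size - 0.5 + 1
    c0 <- pmin(pmax(floor(cx), 1), nc - 1); r0 <- pmin(pmax(floor(cy), 1), nr - 1)
    fx <- pmin(pmax(cx - c0, 0), 1); fy <- pmin(pmax(cy - r0, 0), 1)
    vals <- (1 - fy) * ((1 - fx) * image[cbind(r0, c0)] +
                          fx * image[cbind(r0, c0 + 1)]) +
      fy * ((1 - fx) * image[cbind(r0 + 1, c0)] +
              fx * image[cbind(r0 + 1, c0 + 1)])
    prof[i] <- mean(vals)
  }
  list(s = s, profile = prof)
}

#' Fit a Gaussian to a line profile and report the FWHM
#'
#' The intensity profile along a line through a focus is fit with
#' `Y = a + b * exp(-(x - c)^2 / (2 d^2))` by nonlinear least squares;
#' the full width at half maximum is `2 * sqrt(2 * ln 2) * d`.
#'
#' @param image 2D matrix.
#' @param p0_um,p1_um line endpoints, um (`c(x, y)`).
#' @param thickness averaging thickness in pixels.
#' @param pixel_size um/pixel.
#' @return list of class `LineProfileFit`: `a`, `b`, `c`, `d` (um),
#'   `fwhm_um`, plus the sampled profile.
#' @export
fit_line_fwhm <- function(image, p0_um, p1_um, thickness = 1,
                          pixel_size) {
  len <- sqrt(sum((p1_um - p0_um)^2))
  if (len < 6 * pixel_size) stop("line shorter than 6 pixels")
  sl <- sample_line(image, p0_um, p1_um, thickness, pixel_size)
  x <- sl$s; y <- sl$profile
  if (max(y) - min(y) < sqrt(.Machine$double.eps) * max(abs(y), 1))
    stop("no peak: flat profile")
  st <- list(a = min(y), b = max(y) - min(y), c = x[which.max(y)],
             d = len / 8)
  fit <- try(minpack.lm::nlsLM(
    y ~ a + b * exp(-(x - c)^2 / (2 * d^2)),
    start = st,
    lower = c(a = -Inf, b = 0, c = min(x), d = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) stop("Gaussian fit did not converge")
  cf <- stats::coef(fit)
  if (cf[["b"]] <= 0) stop("no peak: b <= 0 at optimum")
  structure(list(a = cf[["a"]], b = cf[["b"]], c = cf[["c"]],
                 d = abs(cf[["d"]]),
                 fwhm_um = 2 * sqrt(2 * log(2)) * abs(cf[["d"]]),
                 x = x, profile = y),
            class = "LineProfileFit")
}

#' Nuclear-to-cytoplasmic intensity ratio
#'
#' Background-subtracted mean nuclear intensity over background-subtracted
#' mean cytoplasmic intensity. The cytoplasmic mean is reconstructed from
#' whole-cell and nuclear regions:
#' `(cell_mean * cell_area - nuc_mean * nuc_area) / (cell_area - nuc_area)`.
#' Reported as nucleus/cytoplasm, the convention under which
#' nuclear-enriched probes score above 1 (the conventional N/C reading).
#'
#' @param image 2D matrix.
#' @param nuc_mask,cell_mask,bkg_mask logical masks; nucleus must lie
#'   inside the cell, background outside it.
#' @return positive scalar ratio.
#' @export
nc_ratio <- function(image, nuc_mask, cell_mask, bkg_mask) {
  stopifnot(all(dim(image) == dim(nuc_mask)),
            all(dim(image) == dim(cell_mask)),
            all(dim(image) == dim(bkg_mask)))
  if (any(nuc_mask & !cell_mask)) stop("nucleus mask must lie inside the cell")
  if (any(bkg_mask & cell_mask)) stop("background overlaps the cell")
  nuc_area <- sum(nuc_mask); cell_area <- sum(cell_mask)
  cyto_area <- cell_area - nuc_area
  if (cyto_area <= 0) stop("cytoplasmic area is zero")
  bkg <- mean(image[bkg_mask])
  nuc <- mean(image[nuc_mask])
  cell <- mean(image[cell_mask])
  cyto <- (cell * cell_area - nuc * nuc_area) / cyto_area
  if (bkg >= nuc) stop("background >= nuclear mean")
  (nuc - bkg) / (cyto - bkg)
}

#' Relative total foci area over time
#'
#' Per frame, Otsu autothreshold within the nucleus selects the foci; the
#' total supra-threshold area is divided by the frame-1 area, giving the
#' relative-area time course used to follow inhibitor responses. The Otsu
#' threshold is floored at median + 3 MAD of the within-mask intensities,
#' so a frame that has lost its foci reports a near-zero area instead of a
#' noise split.
#'
#' @param frames list of 2D matrices (or an [image_stack()] with `t`).
#' @param mask logical nucleus mask (single mask or list per frame).
#' @return data.frame: `frame`, `area_px`, `relative`.
#' @export
foci_area_series <- function(frames, mask) {
  if (inherits(frames, "ImageStack"))
    frames <- lapply(seq_len(n_frames(frames)),
                     function(t) get_frame(frames, t = t))
  if (length(frames) < 2) stop("need at least 2 time points")
  masks <- if (is.list(mask)) mask else rep(list(mask), length(frames))
  area <- vapply(seq_along(frames), function(i) {
    im <- frames[[i]]; mk <- masks[[i]]
    v <- im[mk]
    rng <- range(v)
    if (rng[1] == rng[2]) return(0)
    thr <- EBImage::otsu(EBImage::Image(matrix((v - rng[1]) /
                                                 (rng[2] - rng[1]))),
                         range = c(0, 1))
    thr_abs <- max(rng[1] + thr * (rng[2] - rng[1]),
                   stats::median(v) + 3 * stats::mad(v))
    sum(v > thr_abs)
  }, numeric(1))
  if (area[1] == 0) stop("frame-1 area is zero")
  data.frame(frame = seq_along(frames), area_px = area,
             relative = area / area[1])
}
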