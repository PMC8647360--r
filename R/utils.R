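# Internal helpers shared across modules.

# Physical <-> pixel coordinate convention: pixel centers. Column c (1-based)
# spans x in [(c-1)*px, c*px]; its center is (c - 0.5)*px. Same for rows/y.
um_to_col <- function(x_um, pixel_size) pmax(1L, as.integer(floor(x_um / pixel_size)) + 1L)
um_to_row <- function(y_um, pixel_size) pmax(1L, as.integer(floor(y_um / pixel_size)) + 1L)
col_to_um <- function(col, pixel_size) (col - 0.5) * pixel_size
row_to_um <- function(row, pixel_size) (row - 0.5) * pixel_size

#' @importFrom stats pnorm
render_spots <- function(nrow, ncol, x_um, y_um, amplitude, psf_sigma_um,
                         pixel_size) {
  # Pixel-integrated symmetric 2D Gaussian spots (error-function differences).
  # `amplitude` is the peak intensity of the continuous Gaussian in
  # photons/pixel-area; the pixel value is the Gaussian integrated over the
  # pixel footprint.
  img <- matrix(0, nrow, ncol)
  if (length(x_um) == 0L) return(img)
  amplitude <- rep_len(amplitude, length(x_um))
  s_px <- psf_sigma_um / pixel_size
  halfw <- max(3L, ceiling(5 * s_px))
  norm1d <- s_px * sqrt(2 * pi)   # integral of unit-peak 1D Gaussian, px units
  for (i in seq_along(x_um)) {
    cx <- x_um[i] / pixel_size    # position in pixel units from image corner
    cy <- y_um[i] / pixel_size
    c0 <- max(1L, floor(cx) - halfw); c1 <- min(ncol, ceiling(cx) + halfw)
    r0 <- max(1L, floor(cy) - halfw); r1 <- min(nrow, ceiling(cy) + halfw)
    if (c0 > c1 || r0 > r1) next
    cols <- c0:c1; rows <- r0:r1
    fx <- pnorm((cols - cx) / s_px) - pnorm((cols - 1 - cx) / s_px)
    fy <- pnorm((rows - cy) / s_px) - pnorm((rows - 1 - cy) / s_px)
    img[rows, cols] <- img[rows, cols] +
      amplitude[i] * norm1d^2 * outer(fy, fx)
  }
  img
}

local_maxima <- function(img, min_value = -Inf) {
  # 8-neighbourhood local maxima. Plateau ties are broken so that only the
  # lexicographically first (row, col) pixel of a flat plateau survives:
  # strictly greater than neighbours that precede it in (row, col) order is
  # not required, strictly greater than those that follow is.
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 3L || nc < 3L) return(matrix(integer(0), 0, 2))
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- img
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  ok <- ctr > min_value
  for (dd in list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L))) {
    nb <- pad[2:(nr + 1L) + dd[1], 2:(nc + 1L) + dd[2]]
    ok <- ok & (ctr > nb)              # earlier neighbours must be beaten
  }
  for (dd in list(c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))) {
    nb <- pad[2:(nr + 1L) + dd[1], 2:(nc + 1L) + dd[2]]
    ok <- ok & (ctr >= nb)             # later neighbours may tie
  }
  which(ok, arr.ind = TRUE)
}

box_filter <- function(img, halfwidth) {
  # Mean filter with replicated borders (box of side 2*halfwidth+1).
  k <- matrix(1, 2 * halfwidth + 1, 2 * halfwidth + 1)
  k <- k / sum(k)
  EBImage::filter2(img, k, boundary = "replicate")
}

local_mean_sd <- function(img, halfwidth) {
  m <- box_filter(img, halfwidth)
  m2 <- box_filter(img * img, halfwidth)
  v <- pmax(m2 - m * m, 0)
  list(mean = m, sd = sqrt(v))
}

gauss_blur <- function(img, sigma_px) {
  # replicate-padded Gaussian blur; padding both avoids wrap-around at the
  # image edge and lets the kernel exceed small images (2-um cutoffs on
  # 128-px nuclei)
  if (sigma_px <= 0) return(img)
  p <- ceiling(3 * sigma_px) + 1L
  ri <- c(rep(1L, p), seq_len(nrow(img)), rep(nrow(img), p))
  ci <- c(rep(1L, p), seq_len(ncol(img)), rep(ncol(img), p))
  padded <- img[ri, ci]
  out <- as.matrix(EBImage::gblur(padded, sigma = sigma_px))
  out[p + seq_len(nrow(img)), p + seq_len(ncol(img))]
}

# restore RNG state on exit so generators do not perturb callers' streams
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
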