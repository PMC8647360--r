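# Image I/O, masking, filtering and the shared intensity normalizations.

#' Read a multi-page TIFF into an ImageStack
#'
#' Calibration (pixel size, frame interval, axis layout) is supplied via a
#' config list, since plain TIFF tags rarely carry it; without a pixel size
#' the read refuses rather than guessing.
#'
#' @param path TIFF file.
#' @param config list with `pixel_size` (um, required), optional
#'   `frame_interval` (s) and `n_channels` (channel-interleaved pages).
#' @return an [image_stack()].
#' @export
read_stack <- function(path, config = NULL) {
  if (!file.exists(path)) stop("cannot read ", path)
  if (is.null(config) || is.null(config$pixel_size))
    stop("missing calibration: config$pixel_size is required")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nch <- config$n_channels %||% 1L
  if (length(pages) %% nch != 0)
    stop("page count ", length(pages), " not divisible by n_channels ", nch)
  nt <- length(pages) %/% nch
  nr <- nrow(pages[[1]]); nc <- ncol(pages[[1]])
  if (nt > 1L || nch > 1L) {
    arr <- array(0, c(nt, nch, nr, nc))
    for (t in seq_len(nt)) for (ch in seq_len(nch))
      arr[t, ch, , ] <- pages[[(t - 1L) * nch + ch]]
    image_stack(arr, "tcyx", pixel_size = config$pixel_size,
                frame_interval = config$frame_interval %||% NA_real_)
  } else {
    image_stack(pages[[1]], pixel_size = config$pixel_size)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an ImageStack as a multi-page TIFF
#'
#' Integer data are written as 16-bit, floating data as 32-bit float;
#' 16-bit round trips are lossless.
#'
#' @param stack an [image_stack()].
#' @param path output file.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  nt <- n_frames(stack)
  nch <- { i <- match("c", stack$axes); if (is.na(i)) 1L else dim(stack$data)[i] }
  pages <- list()
  for (t in seq_len(nt)) for (ch in seq_len(nch))
    pages[[length(pages) + 1L]] <- get_frame(stack, t = t, c = ch)
  vals <- unlist(pages, use.names = FALSE)
  is_int <- all(vals == round(vals)) && max(vals) <= 65535 && min(vals) >= 0
  if (is_int) {
    tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                    bits.per.sample = 16L)
  } else {
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Average frames of a time series
#'
#' @param stack an [image_stack()] with a `t` axis.
#' @param frame_range integer vector of frame indices to average.
#' @param channel channel index when a `c` axis is present.
#' @return a numeric matrix (floating point per-pixel mean).
#' @export
time_average <- function(stack, frame_range = seq_len(n_frames(stack)),
                         channel = 1L) {
  stopifnot(inherits(stack, "ImageStack"))
  if (length(frame_range) == 0) stop("empty frame range")
  if (any(frame_range < 1 | frame_range > n_frames(stack)))
    stop("frame_range outside stack")
  acc <- 0
  for (t in frame_range) acc <- acc + get_frame(stack, t = t, c = channel)
  acc / length(frame_range)
}

#' Normalized local-enrichment map of a nuclear image
#'
#' High-pass filters the image (subtraction of a Gaussian blur whose sigma
#' equals the cutoff, default 2 um, converted to pixels) to remove
#' non-uniform illumination, then maps the within-mask intensity range
#' mean - k_sd*SD .. mean + k_sd*SD onto 0..1 (clipped). The result is the
#' map against which single-molecule trajectories are scored.
#'
#' @param image single 2D frame (matrix).
#' @param mask logical nucleus mask (non-empty).
#' @param pixel_size um per pixel.
#' @param highpass_cutoff high-pass length scale in um (default 2).
#' @param k_sd half-range in SD units (default 2).
#' @return matrix in `[0, 1]` of class `EnrichmentMap`; 0 outside the mask.
#'   Attributes record the cutoff and normalization statistics.
#' @export
make_enrichment_map <- function(image, mask, pixel_size,
                                highpass_cutoff = 2.0, k_sd = 2) {
  stopifnot(is.matrix(image), is.logical(mask),
            all(dim(image) == dim(mask)))
  if (!any(mask)) stop("mask is empty")
  hp <- image - gauss_blur(image, highpass_cutoff / pixel_size)
  mu <- mean(hp[mask]); sd <- stats::sd(hp[mask])
  if (sd == 0) stop("constant image within mask: SD = 0")
  map <- (hp - (mu - k_sd * sd)) / (2 * k_sd * sd)
  map <- pmin(pmax(map, 0), 1)
  map[!mask] <- 0
  structure(map, class = c("EnrichmentMap", class(map)),
            cutoff_um = highpass_cutoff, mean_hp = mu, sd_hp = sd)
}

#' Automatic nucleus mask by Otsu threshold
#'
#' Global Otsu threshold, then the largest connected foreground component
#' with holes filled. A stand-in for the manual region drawing used in
#' interactive analysis.
#'
#' @param image 2D matrix with a bright nucleus over dark background.
#' @return logical matrix mask.
#' @export
nucleus_mask_auto <- function(image) {
  stopifnot(is.matrix(image))
  rng <- range(image)
  if (rng[1] == rng[2]) stop("no foreground found (constant image)")
  norm <- (image - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(norm))
  fg <- norm > thr
  if (!any(fg)) stop("no foreground found")
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  tab <- tabulate(as.integer(lab)[as.integer(lab) > 0])
  keep <- which.max(tab)
  mask <- EBImage::fillHull(EBImage::Image((lab == keep) * 1))
  matrix(as.integer(mask) > 0, nrow(image), ncol(image))
}
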