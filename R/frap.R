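# FRAP curve processing: double normalization and recovery metrics.

#' Double-normalize a FRAP curve
#'
#' Step 1 ratios the background-subtracted bleach-spot intensity to the
#' background-subtracted nuclear reference at every time point (cancelling
#' acquisition photobleaching); step 2 divides by the pre-bleach mean of
#' the step-1 values, so the normalized pre-bleach level is exactly 1.
#'
#' @param curve data.frame with `t`, `bleach`, `reference`, `background`
#'   (e.g. from [simulate_frap_curve()]), or a `FRAPCurve`.
#' @param n_pre number of pre-bleach frames (taken from the `n_pre`
#'   attribute when present).
#' @return data.frame: `t`, `normalized`.
#' @export
normalize_frap <- function(curve, n_pre = attr(curve, "n_pre")) {
  stopifnot(all(c("t", "bleach", "reference", "background") %in% names(curve)))
  if (is.null(n_pre) || n_pre < 1) stop("n_pre must be >= 1")
  ref <- curve$reference - curve$background
  if (any(ref <= 0)) stop("reference <= background")
  step1 <- (curve$bleach - curve$background) / ref
  pre <- mean(step1[seq_len(n_pre)])
  if (pre == 0) stop("zero prebleach mean")
  data.frame(t = curve$t, normalized = step1 / pre)
}

#' Time to recover to a given level
#'
#' First time after the bleach at which the normalized curve crosses
#' `level`, linearly interpolated between frames.
#'
#' @param norm data.frame from [normalize_frap()].
#' @param level recovery level (default 0.8).
#' @return crossing time in seconds, or `NA` (with attribute
#'   `reached = FALSE`) when the curve never crosses.
#' @export
recovery_time <- function(norm, level = 0.8) {
  post <- norm[norm$t >= 0, , drop = FALSE]
  above <- post$normalized >= level
  if (!any(above)) return(structure(NA_real_, reached = FALSE))
  i <- which(above)[1]
  if (i == 1) return(structure(post$t[1], reached = TRUE))
  t0 <- post$t[i - 1]; t1 <- post$t[i]
  y0 <- post$normalized[i - 1]; y1 <- post$normalized[i]
  structure(t0 + (level - y0) / (y1 - y0) * (t1 - t0), reached = TRUE)
}
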