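# Association of bound-molecule mobility with local enrichment of the
# transcription-elongation mark.

#' Per-trajectory enrichment statistics
#'
#' Reads the enrichment map at the nearest pixel under every trajectory
#' point. The trajectory's relative enrichment `I_rel` is the mean of the
#' two largest map values along the track (a 2-point track uses both
#' points; ties contribute duplicates); `freq_gt_0.5` is the fraction of
#' points whose map value exceeds 0.5.
#'
#' @param traj data.frame with `x_um`, `y_um` (>= 2 points).
#' @param map matrix in `[0, 1]` (an enrichment map).
#' @param pixel_size um/pixel of the map.
#' @return list: `I_rel`, `freq_gt_0.5`, `values` (per-point map reads).
#' @export
trajectory_intensity_stats <- function(traj, map, pixel_size) {
  if (nrow(traj) < 2) stop("track with < 2 points")
  col <- pmin(um_to_col(traj$x_um, pixel_size), ncol(map))
  row <- pmin(um_to_row(traj$y_um, pixel_size), nrow(map))
  if (any(col < 1) || any(row < 1)) stop("track points outside map")
  v <- map[cbind(row, col)]
  top2 <- sort(v, decreasing = TRUE)[1:2]
  list(I_rel = mean(top2), freq_gt_0.5 = mean(v > 0.5), values = v)
}

#' Enrichment-association table for a trajectory set
#'
#' @param ts a [trajectory_set()].
#' @param map enrichment map matrix.
#' @param pixel_size um/pixel of the map.
#' @param d_table optional data.frame `track_id`, `D` (from
#'   [track_diffusion()]); merged when given.
#' @return data.frame: `track_id`, `I_rel`, `freq_gt_0.5`, `n_points`
#'   (+ `D` if supplied).
#' @export
associate_tracks <- function(ts, map, pixel_size = ts$pixel_size,
                             d_table = NULL) {
  rows <- lapply(split_tracks(ts), function(tr) {
    st <- trajectory_intensity_stats(tr, map, pixel_size)
    data.frame(track_id = tr$track_id[1], I_rel = st$I_rel,
               freq_gt_0.5 = st$freq_gt_0.5, n_points = nrow(tr))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(d_table)) out <- merge(out, d_table[, c("track_id", "D")],
                                      by = "track_id", sort = TRUE)
  out
}

#' Classify tracks into top/bottom enrichment quantiles
#'
#' Sorts by `I_rel` (ties broken by `track_id` for determinism); the top
#' `quantile` fraction is labelled `"top"`, the bottom fraction
#' `"bottom"`, everything else `"middle"`. `quantile = 0.5` yields two
#' halves and no middle.
#'
#' @param assoc association table with `track_id` and `I_rel`.
#' @param quantile fraction in `(0, 0.5]` (default 0.25).
#' @return `assoc` with an added `group` factor.
#' @export
classify_by_enrichment <- function(assoc, quantile = 0.25) {
  if (quantile <= 0 || quantile > 0.5) stop("quantile must be in (0, 0.5]")
  if (nrow(assoc) < 8) stop("need >= 8 tracks")
  n <- nrow(assoc)
  k <- floor(n * quantile + 1e-9)
  o <- order(-assoc$I_rel, assoc$track_id)
  group <- rep("middle", n)
  group[o[seq_len(k)]] <- "top"
  group[o[seq.int(n, n - k + 1L)]] <- "bottom"
  assoc$group <- factor(group, levels = c("top", "middle", "bottom"))
  assoc
}

#' Compare mobility between enrichment groups (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test between the D values
#' of two groups, exact for small tie-free samples, normal approximation
#' with tie correction otherwise.
#'
#' @param d_top,d_bottom diffusion coefficients of the two groups.
#' @return list: `median_top`, `median_bottom`, `delta_median`, `U`,
#'   `p_value`, `n_top`, `n_bottom`.
#' @export
compare_bound_mobility <- function(d_top, d_bottom) {
  if (length(d_top) == 0 || length(d_bottom) == 0) stop("empty group")
  ties <- anyDuplicated(c(d_top, d_bottom)) > 0
  exact <- !ties && max(length(d_top), length(d_bottom)) <= 20
  wt <- stats::wilcox.test(d_top, d_bottom, alternative = "two.sided",
                           exact = exact, correct = TRUE)
  list(median_top = stats::median(d_top),
       median_bottom = stats::median(d_bottom),
       delta_median = stats::median(d_top) - stats::median(d_bottom),
       U = unname(wt$statistic), p_value = wt$p.value,
       n_top = length(d_top), n_bottom = length(d_bottom))
}

#' Robustness sweep over quantile and D threshold
#'
#' Re-runs the bound-molecule association analysis over a grid of
#' top/bottom quantiles (default 5-45%) and bound thresholds `D_thr`
#' (default 0.025-0.169 um^2/s): each cell filters to `D <= D_thr`,
#' splits by `I_rel` quantile and compares the top and bottom groups.
#' Cells with too few molecules are reported with `NA`, not errors.
#'
#' @param assoc association table with `track_id`, `I_rel`, `D` (all
#'   tracks, unfiltered).
#' @param quantiles vector of quantile fractions.
#' @param d_thr_grid vector of bound thresholds, um^2/s.
#' @param min_group minimum group size for a cell to be evaluated.
#' @return data.frame: `quantile`, `D_thr`, `delta_median_D`, `p_value`,
#'   `n_bound`, `n_top`, `n_bottom`.
#' @export
threshold_sweep <- function(assoc,
                            quantiles = seq(0.05, 0.45, by = 0.05),
                            d_thr_grid = c(0.025, 0.045, 0.065, 0.085,
                                           0.105, 0.127, 0.147, 0.169),
                            min_group = 3) {
  stopifnot(all(c("I_rel", "D") %in% names(assoc)))
  grid <- expand.grid(quantile = quantiles, D_thr = d_thr_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    q <- grid$quantile[i]; thr <- grid$D_thr[i]
    bound <- assoc[assoc$D <= thr, , drop = FALSE]
    out <- data.frame(quantile = q, D_thr = thr,
                      delta_median_D = NA_real_, p_value = NA_real_,
                      n_bound = nrow(bound), n_top = 0L, n_bottom = 0L)
    if (nrow(bound) < 8) return(out)
    cls <- classify_by_enrichment(bound, q)
    dt <- cls$D[cls$group == "top"]; db <- cls$D[cls$group == "bottom"]
    out$n_top <- length(dt); out$n_bottom <- length(db)
    if (length(dt) < min_group || length(db) < min_group) return(out)
    cmp <- compare_bound_mobility(dt, db)
    out$delta_median_D <- cmp$delta_median
    out$p_value <- cmp$p_value
    out
  })
  do.call(rbind, res)
}
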