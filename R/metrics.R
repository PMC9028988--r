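## Evaluation statistics: eroded-mask summaries, Bland-Altman agreement,
## MAE-by-slice curves, transmural layer profiles and ROI SNR.

#' Binary erosion of a 3D mask (6-connected structuring element)
#'
#' @param mask logical 3D array.
#' @param n_vox number of erosion passes (voxels).
#' @return logical 3D array.
#' @export
erode_mask <- function(mask, n_vox = 1) {
  m <- mask
  d <- dim(m)
  shift <- function(x, axis, by) {
    out <- array(FALSE, d)
    src <- lapply(d, seq_len); dst <- src
    n <- d[axis]
    if (by >= n) return(out)
    src[[axis]] <- seq_len(n - by)
    dst[[axis]] <- seq_len(n - by) + by
    if (by < 0) { src[[axis]] <- seq_len(n + by) - by; dst[[axis]] <- seq_len(n + by) }
    out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (i in seq_len(n_vox)) {
    m <- m & shift(m, 1, 1) & shift(m, 1, -1) &
      shift(m, 2, 1) & shift(m, 2, -1) &
      shift(m, 3, 1) & shift(m, 3, -1)
  }
  m
}

#' Summary statistics of a map over an eroded mask
#'
#' Erodes the mask (to suppress partial-volume boundary voxels) and returns
#' mean, SD, median and interquartile range of the map over the remainder.
#'
#' @param map numeric 3D array (or vector matching `mask`).
#' @param mask logical 3D array.
#' @param erosion_vox erosion amount in voxels (default 1).
#' @return list with `mean`, `sd`, `median`, `iqr`, `n`, `erosion_vox`.
#' @export
eroded_mask_stats <- function(map, mask, erosion_vox = 1) {
  em <- if (erosion_vox > 0) erode_mask(mask, erosion_vox) else mask
  if (!any(em)) stop("mask is empty after erosion")
  v <- if (is.array(map) && length(map) == length(mask)) map[em]
       else map[em[mask]]
  v <- v[is.finite(v)]
  list(mean = mean(v), sd = stats::sd(v), median = stats::median(v),
       iqr = stats::IQR(v), n = length(v), erosion_vox = erosion_vox)
}

#' Mean absolute error per slice along an axis
#'
#' @param map,reference numeric 3D arrays on the same grid.
#' @param mask logical 3D array restricting the comparison.
#' @param axis slice axis (default 3: apex-to-base for the LV phantom).
#' @return list with `slice` (1-based index), `mae` (NA for empty slices),
#'   `n` (voxels per slice) and the mask-weighted `global_mae`.
#' @export
mae_by_slice <- function(map, reference, mask, axis = 3) {
  stopifnot(all(dim(map) == dim(reference)), all(dim(map) == dim(mask)))
  err <- abs(map - reference)
  err[!mask] <- NA
  mae <- apply(err, axis, function(s) mean(s, na.rm = TRUE))
  n <- apply(!is.na(err), axis, sum)
  mae[n == 0] <- NA
  ok <- is.finite(err)
  list(slice = seq_len(dim(map)[axis]), mae = mae, n = n,
       global_mae = mean(err[ok]))
}

#' Bland-Altman agreement between a map and a reference
#'
#' @param map,reference numeric arrays/vectors of paired values.
#' @param mask optional logical array selecting the paired voxels.
#' @return Object of class `bland_altman` with `bias`, `loa` (bias +/-
#'   1.96 SD), `sd`, `n`, and the paired `means`/`diffs`.
#' @export
bland_altman <- function(map, reference, mask = NULL) {
  if (!is.null(mask)) { map <- map[mask]; reference <- reference[mask] }
  ok <- is.finite(map) & is.finite(reference)
  map <- map[ok]; reference <- reference[ok]
  if (length(map) < 2) stop("need at least 2 paired values")
  d <- map - reference
  bias <- mean(d); s <- stats::sd(d)
  structure(list(bias = bias, sd = s, loa = bias + c(-1, 1) * 1.96 * s,
                 n = length(d), means = (map + reference) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4g, limits [%.4g, %.4g], n = %d\n",
              x$bias, x$loa[1], x$loa[2], x$n))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, pch = ".", xlab = "mean",
                 ylab = "difference", ...)
  graphics::abline(h = c(x$bias, x$loa), lty = c(1, 2, 2))
  invisible(x)
}

#' Transmural profile in five wall layers with the linear HA slope
#'
#' Pools samples into equal-width wall-depth layers (`[0,20)`, ...,
#' `[80,100]` percent by default) and fits the helix-angle slope in
#' degrees per percent wall depth by ordinary least squares over all
#' voxels (Theil-Sen available as a robust option).
#'
#' @param values per-voxel metric samples (e.g. HA in degrees).
#' @param wall_depth_pct per-voxel wall depth, percent (0 endo, 100 epi).
#' @param n_layers number of layers (default 5).
#' @param slope_method `"ols"` or `"theil-sen"`.
#' @return Object of class `transmural_profile` with a per-layer summary
#'   data.frame and `slope` (units of `values` per percent).
#' @export
transmural_profile <- function(values, wall_depth_pct, n_layers = 5,
                               slope_method = c("ols", "theil-sen")) {
  slope_method <- match.arg(slope_method)
  ok <- is.finite(values) & is.finite(wall_depth_pct)
  values <- values[ok]; wd <- wall_depth_pct[ok]
  stopifnot(all(wd >= 0 & wd <= 100))
  br <- seq(0, 100, length.out = n_layers + 1)
  layer <- pmin(findInterval(wd, br, rightmost.closed = TRUE), n_layers)
  lay <- lapply(seq_len(n_layers), function(l) values[layer == l])
  empty <- vapply(lay, length, 1L) == 0
  if (any(empty)) warning(sprintf("%d empty layer(s)", sum(empty)))
  tab <- data.frame(
    layer = seq_len(n_layers),
    depth_lo = br[-length(br)], depth_hi = br[-1],
    n = vapply(lay, length, 1L),
    median = vapply(lay, function(v) if (length(v)) stats::median(v) else NA_real_, 1),
    iqr = vapply(lay, function(v) if (length(v) > 1) stats::IQR(v) else NA_real_, 1),
    mean = vapply(lay, function(v) if (length(v)) mean(v) else NA_real_, 1),
    sd = vapply(lay, function(v) if (length(v) > 1) stats::sd(v) else NA_real_, 1))
  slope <- if (slope_method == "ols") {
    unname(stats::coef(stats::lm(values ~ wd))[2])
  } else {
    theil_sen_slope(wd, values)
  }
  structure(list(layers = tab, slope = slope, slope_method = slope_method),
            class = "transmural_profile")
}

## Theil-Sen slope (median of pairwise slopes); subsampled above 2000 pts.
theil_sen_slope <- function(x, y, max_n = 2000) {
  n <- length(x)
  if (n > max_n) {
    i <- round(seq(1, n, length.out = max_n))
    x <- x[i]; y <- y[i]; n <- max_n
  }
  dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
  keep <- upper.tri(dx) & dx != 0
  stats::median(dy[keep] / dx[keep])
}

#' @export
print.transmural_profile <- function(x, ...) {
  cat(sprintf("Transmural profile (%d layers), slope %.4g per %% (%s)\n",
              nrow(x$layers), x$slope, x$slope_method))
  print(x$layers, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.transmural_profile <- function(x, ...) {
  mid <- (x$layers$depth_lo + x$layers$depth_hi) / 2
  graphics::plot(mid, x$layers$median, type = "b",
                 ylim = range(c(x$layers$median - x$layers$iqr / 2,
                                x$layers$median + x$layers$iqr / 2),
                              na.rm = TRUE),
                 xlab = "wall depth (%)", ylab = "median", ...)
  graphics::arrows(mid, x$layers$median - x$layers$iqr / 2, mid,
                   x$layers$median + x$layers$iqr / 2, angle = 90,
                   code = 3, length = 0.03)
  invisible(x)
}

#' Region-of-interest SNR
#'
#' Mean signal over the signal ROI divided by the standard deviation over
#' the (background) noise ROI.
#'
#' @param volume numeric array.
#' @param signal_roi,noise_roi logical arrays.
#' @return scalar SNR.
#' @export
roi_snr <- function(volume, signal_roi, noise_roi) {
  s <- stats::sd(volume[noise_roi])
  if (!is.finite(s) || s == 0) stop("noise ROI has zero variance")
  mean(volume[signal_roi]) / s
}
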