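#' Percentile-clip and rescale intensities to [0, 1]
#'
#' The normalization applied before mixture fitting: masked intensities are
#' clipped at the `low_pct` / `high_pct` percentiles (default 1 and 99) to
#' remove extreme values, then affinely mapped so that the low percentile
#' lands on 0 and the high percentile on 1. Percentiles are computed over
#' masked voxels only, with linear interpolation; background voxels stay 0.
#'
#' @param vol an [intensity_volume()].
#' @param low_pct,high_pct clipping percentiles, `0 <= low_pct < high_pct <= 100`.
#' @return An [intensity_volume()] whose masked values lie in `[0, 1]`.
#' @export
prepare_for_gmm <- function(vol, low_pct = 1, high_pct = 99) {
  stopifnot(inherits(vol, "intensity_volume"))
  if (low_pct >= high_pct) stop_gmmaug("'low_pct' must be < 'high_pct'")
  v <- vol$data[vol$mask]
  if (length(v) == 0L) stop_gmmaug("mask is empty")
  p <- stats::quantile(v, c(low_pct, high_pct) / 100, names = FALSE, type = 7)
  if (p[1] == p[2]) stop_gmmaug("degenerate input: P%g == P%g", low_pct, high_pct)
  out <- pmin(pmax(vol$data, p[1]), p[2])
  out <- (out - p[1]) / (p[2] - p[1])
  out[!vol$mask] <- 0
  intensity_volume(out, vol$mask)
}

#' Robust z-score normalization
#'
#' Outlier-robust standardization: centre by the median of the masked
#' intensities, scale by the standard deviation of the masked values
#' restricted to the 10th-90th percentile window. Background stays 0.
#' Statistics are computed within the brain mask only.
#'
#' @param vol an [intensity_volume()].
#' @return An [intensity_volume()] (masked values may be negative).
#' @export
robust_zscore <- function(vol) {
  stopifnot(inherits(vol, "intensity_volume"))
  v <- vol$data[vol$mask]
  if (length(v) == 0L) stop_gmmaug("mask is empty")
  med <- stats::median(v)
  p <- stats::quantile(v, c(0.1, 0.9), names = FALSE, type = 7)
  trimmed <- v[v >= p[1] & v <= p[2]]
  if (length(unique(trimmed)) < 2L) {
    stop_gmmaug("degenerate input: fewer than 2 distinct values within [P10, P90]")
  }
  s <- stats::sd(trimmed)
  if (s == 0) stop_gmmaug("degenerate input: zero trimmed standard deviation")
  out <- (vol$data - med) / s
  out[!vol$mask] <- 0
  intensity_volume(out, vol$mask)
}
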