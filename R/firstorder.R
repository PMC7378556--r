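#' First-order (intensity histogram) features
#'
#' The 18 first-order statistics of the ROI intensity distribution:
#' Energy, TotalEnergy, Entropy, Minimum, P10, P90, Maximum, Mean, Median,
#' InterquartileRange, Range, MeanAbsoluteDeviation,
#' RobustMeanAbsoluteDeviation, RootMeanSquared, Skewness, Kurtosis,
#' Variance and Uniformity.  Entropy and Uniformity are computed on the
#' discretized levels of the experiment's active discretization; all other
#' statistics use the raw ROI intensities.  Moments use the population
#' convention; Kurtosis is the non-excess (Pearson) form.  Degenerate
#' (constant) input yields Skewness 0 and Kurtosis 0, documented fallbacks
#' keeping every feature finite.
#'
#' @param roi_values Numeric vector of ROI intensities.
#' @param voxel_volume Voxel volume in mm^3 (TotalEnergy scaling).
#' @param disc A `discretized_roi` of the same ROI (for Entropy/Uniformity).
#' @return Named numeric vector of 18 features, names prefixed
#'   `firstorder.`.
#' @export
first_order_features <- function(roi_values, voxel_volume = 1, disc) {
  x <- as.numeric(roi_values)
  n <- length(x)
  if (n == 0L) stop("empty ROI")
  if (!inherits(disc, "discretized_roi"))
    stop("'disc' must be a discretized_roi")
  if (length(disc$levels) != n)
    stop("'disc' does not match the ROI (different voxel counts)")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7,
                       names = FALSE)
  inrob <- x >= q[1] & x <= q[5]
  xr <- x[inrob]
  p <- tabulate(disc$levels, nbins = max(disc$levels)) / n
  p <- p[p > 0]
  c(firstorder.Energy = sum(x^2),
    firstorder.TotalEnergy = voxel_volume * sum(x^2),
    firstorder.Entropy = -sum(p * log2(p)),
    firstorder.Minimum = min(x),
    firstorder.P10 = q[1],
    firstorder.P90 = q[5],
    firstorder.Maximum = max(x),
    firstorder.Mean = mu,
    firstorder.Median = q[3],
    firstorder.InterquartileRange = q[4] - q[2],
    firstorder.Range = max(x) - min(x),
    firstorder.MeanAbsoluteDeviation = mean(abs(x - mu)),
    firstorder.RobustMeanAbsoluteDeviation =
      if (length(xr)) mean(abs(xr - mean(xr))) else 0,
    firstorder.RootMeanSquared = sqrt(mean(x^2)),
    firstorder.Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    firstorder.Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    firstorder.Variance = m2,
    firstorder.Uniformity = sum(p^2))
}
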