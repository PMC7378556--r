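#' Grey-level discretization of ROI intensities
#'
#' Two schemes are supported before texture-matrix computation:
#'
#' * **FBS** (fixed bin size, absolute): `X_d = floor(X / w_b) -
#'   floor(X_min / w_b) + 1`.  The number of realized levels varies with the
#'   ROI intensity range.
#' * **FBN** (fixed bin number, relative): `X_d = floor(N_g * (X - X_min) /
#'   (X_max - X_min)) + 1`, with the maximum mapped to `N_g`.  Both level 1
#'   and level `N_g` are attained, and the levels are invariant under any
#'   positive affine transform of the intensities.
#'
#' To compare FBS across images whose intensity ranges differ (e.g., after
#' different normalizations), the bin width is derived from a nominal bin
#' count and the cohort mean ROI intensity range:
#' `w_b = mean_range / nominal_bins`.
#'
#' A relative epsilon guard (`1e-12`-scale) is applied before each `floor`
#' so that levels are reproducible across platforms when a value lands a
#' rounding error below a bin edge.
#'
#' @name discretization
NULL

#' The nominal bin grid used across the experiments
#' @return `c(8, 16, 32, 64, 128, 256, 512, 1024)`.
#' @export
bin_grid <- function() c(8L, 16L, 32L, 64L, 128L, 256L, 512L, 1024L)

guarded_floor <- function(f) floor(f + 1e-12 * pmax(1, abs(f)))

#' Mean ROI intensity range over a cohort
#'
#' The cohort quantity from which the FBS bin width is derived: the mean
#' over cases of `max - min` of the ROI intensities, for one
#' sequence/normalization condition.
#'
#' @param roi_values_list List of numeric vectors, one per case.
#' @return The mean range (intensity units).
#' @export
mean_roi_range <- function(roi_values_list) {
  if (length(roi_values_list) == 0L) stop("empty cohort")
  ranges <- vapply(seq_along(roi_values_list), function(i) {
    v <- roi_values_list[[i]]
    if (length(v) < 2L || diff(range(v)) <= 0)
      stop("ROI of case ", i, " is constant; its intensity range is degenerate")
    diff(range(v))
  }, numeric(1))
  mean(ranges)
}

#' Bin width for FBS from a nominal bin count
#'
#' `w_b = mean_range / nominal_bins`, the scaling rule that makes absolute
#' discretization comparable across differently scaled conditions.
#'
#' @param nominal_bins Nominal bin count (>= 2).
#' @param mean_range Cohort mean ROI range (> 0).
#' @return The bin width (intensity units).
#' @export
fbs_bin_width <- function(nominal_bins, mean_range) {
  if (!is.finite(nominal_bins) || nominal_bins < 2)
    stop("'nominal_bins' must be >= 2")
  if (!is.finite(mean_range) || mean_range <= 0)
    stop("'mean_range' must be > 0")
  mean_range / nominal_bins
}

new_discretized_roi <- function(levels, mode, n_levels, gl_min, gl_max,
                                w_b = NA_real_, N_g = NA_integer_) {
  structure(list(levels = as.integer(levels), mode = mode,
                 n_levels = as.integer(n_levels),
                 gl_min = gl_min, gl_max = gl_max,
                 w_b = w_b, N_g = N_g),
            class = "discretized_roi")
}

#' Fixed-bin-size (absolute) discretization
#'
#' @param roi_values Numeric vector of ROI intensities.
#' @param w_b Bin width (> 0).
#' @return A `discretized_roi`: integer levels starting at 1, realized
#'   level count in `n_levels`.
#' @export
discretize_fbs <- function(roi_values, w_b) {
  if (length(roi_values) == 0L) stop("empty ROI")
  if (!is.finite(w_b) || w_b <= 0) stop("'w_b' must be > 0")
  mn <- min(roi_values)
  lev <- guarded_floor(roi_values / w_b) - guarded_floor(mn / w_b) + 1L
  new_discretized_roi(lev, "FBS", max(lev), mn, max(roi_values), w_b = w_b)
}

#' Fixed-bin-number (relative) discretization
#'
#' @param roi_values Numeric vector with at least 2 distinct values.
#' @param N_g Number of grey levels (>= 2).
#' @return A `discretized_roi`; the maximum level is exactly `N_g`.
#' @export
discretize_fbn <- function(roi_values, N_g) {
  if (length(roi_values) == 0L) stop("empty ROI")
  if (!is.finite(N_g) || N_g < 2) stop("'N_g' must be >= 2")
  N_g <- as.integer(N_g)
  mn <- min(roi_values)
  mx <- max(roi_values)
  if (mx <= mn)
    stop("constant ROI: fixed-bin-number discretization undefined")
  lev <- ifelse(roi_values >= mx, N_g,
                guarded_floor(N_g * (roi_values - mn) / (mx - mn)) + 1L)
  new_discretized_roi(lev, "FBN", N_g, mn, mx, N_g = N_g)
}

#' Discretize by specification
#'
#' @param roi_values Numeric vector of ROI intensities.
#' @param mode `"FBS"` or `"FBN"`.
#' @param bins Nominal bin count from [bin_grid()].
#' @param mean_range Cohort mean ROI range, required for FBS.
#' @return A `discretized_roi`.
#' @export
discretize_roi <- function(roi_values, mode = c("FBN", "FBS"), bins,
                           mean_range = NULL) {
  mode <- match.arg(mode)
  if (mode == "FBN") return(discretize_fbn(roi_values, bins))
  if (is.null(mean_range))
    stop("FBS discretization needs the cohort 'mean_range'")
  discretize_fbs(roi_values, fbs_bin_width(bins, mean_range))
}
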