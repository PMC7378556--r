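#' Intensity normalization of brain MR volumes
#'
#' Three normalization methods commonly used before radiomic feature
#' extraction from brain MRI:
#'
#' * **Z-Score**: `(I - mu_brain) / sigma_brain`, statistics over the brain
#'   mask (tumour voxels included; the tumour is small relative to the
#'   brain, so no tumour exclusion is applied).
#' * **WhiteStripe**: `(I - mu_ws) / sigma_ws`, statistics over an
#'   automatically estimated band of normal-appearing white matter (NAWM).
#' * **Nyul**: piecewise-linear mapping of the image's intensity landmarks
#'   (percentiles) onto a standard histogram learned from a training set.
#'
#' All statistics are computed on brain-mask voxels only, but the transform
#' is applied to every voxel.  Standard deviations use the population
#' (divide by N) convention throughout.
#'
#' @name normalization
NULL

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Z-Score normalization
#'
#' @param img A `volume_image`.
#' @param brain Brain `binary_mask` on the same grid.
#' @return `list(image =, params =)` where `params` records the method and
#'   the brain mean/sd used.  The output's brain-mask voxels have mean 0 and
#'   population sd 1.
#' @export
zscore_normalize <- function(img, brain) {
  vals <- mask_values(img, brain)
  if (length(vals) == 0L) stop("brain mask is empty")
  mu <- mean(vals)
  sigma <- pop_sd(vals)
  if (sigma <= 0)
    stop("image is constant inside the brain mask; Z-Score undefined")
  out <- volume_image((img$voxels - mu) / sigma, img$spacing)
  list(image = out,
       params = list(method = "zscore", mu = mu, sigma = sigma))
}

#' Automated white-stripe estimation
#'
#' Locates the normal-appearing white matter (NAWM) intensity mode from a
#' smoothed histogram of brain-mask voxels and takes the "white stripe" as
#' the voxels within +/- 5% (on the intensity axis) of the mode.  Bins use
#' a Freedman-Diaconis-like width; counts are Gaussian-smoothed; local
#' maxima with height at least `prominence` of the global maximum are
#' candidate modes, and for a T1-like contrast the last (highest-intensity)
#' prominent mode is selected (`mode = "last"`); `mode = "largest"` selects
#' the global mode instead (T2-like contrast).
#'
#' @param img A `volume_image`.
#' @param brain Brain `binary_mask`.
#' @param prominence Minimum smoothed-peak height as a fraction of the
#'   global maximum (default 0.1).
#' @param smooth_bins Gaussian smoothing sd in bins (default 2).
#' @param mode `"last"` (T1-like, default) or `"largest"`.
#' @return `list(mu_ws =, sigma_ws =, stripe =)` with `stripe` a
#'   `binary_mask` subset of the brain.
#' @export
estimate_white_stripe <- function(img, brain, prominence = 0.1,
                                  smooth_bins = 2, mode = c("last", "largest")) {
  mode <- match.arg(mode)
  vals <- mask_values(img, brain)
  if (length(vals) == 0L) stop("brain mask is empty")
  rng <- range(vals)
  if (diff(rng) <= 0)
    stop("white-stripe estimation failed: constant image inside the brain")
  n <- length(vals)
  bw <- 2 * stats::IQR(vals) / n^(1 / 3)
  if (bw <= 0) bw <- diff(rng) / 256
  nb <- max(16L, min(2048L, ceiling(diff(rng) / bw)))
  edges <- seq(rng[1], rng[2], length.out = nb + 1L)
  counts <- tabulate(pmin(findInterval(vals, edges, rightmost.closed = TRUE),
                          nb), nbins = nb)
  # Gaussian smoothing of the counts
  r <- max(1L, ceiling(3 * smooth_bins))
  w <- stats::dnorm(-r:r, sd = smooth_bins)
  w <- w / sum(w)
  padded <- c(rep(0, r), counts, rep(0, r))
  sm <- stats::filter(padded, w, sides = 2)[(r + 1L):(r + nb)]
  sm <- as.numeric(sm)
  # local maxima of the smoothed histogram (boundary bins included)
  smp <- c(-Inf, sm, -Inf)
  is_peak <- logical(nb)
  for (i in seq_len(nb))
    is_peak[i] <- sm[i] >= smp[i] && sm[i] >= smp[i + 2L] &&
      (sm[i] > smp[i] || sm[i] > smp[i + 2L])
  peaks <- which(is_peak & sm >= prominence * max(sm))
  if (length(peaks) == 0L)
    stop("white-stripe estimation failed: no prominent histogram mode found")
  pk <- if (mode == "last") max(peaks) else peaks[which.max(sm[peaks])]
  mu_mode <- (edges[pk] + edges[pk + 1L]) / 2
  bw_actual <- edges[2] - edges[1]
  # +/- 5% of the mode on the intensity axis; for a non-positive mode a
  # symmetric absolute band is used instead, and the half-width is never
  # narrower than one histogram bin (the proportional band degenerates
  # when the mode sits near zero)
  half <- if (mu_mode > 0) 0.05 * mu_mode else 0.025 * diff(rng)
  half <- max(half, bw_actual)
  band <- c(mu_mode - half, mu_mode + half)
  inb <- brain$voxels == 1L & img$voxels >= band[1] & img$voxels <= band[2]
  if (!any(inb))
    stop("white-stripe estimation failed: empty stripe around the mode")
  sv <- img$voxels[inb]
  list(mu_ws = mean(sv), sigma_ws = pop_sd(sv),
       stripe = binary_mask(inb * 1L, img$spacing))
}

#' WhiteStripe normalization
#'
#' @inheritParams estimate_white_stripe
#' @param ... Passed to [estimate_white_stripe()].
#' @return `list(image =, params =, stripe =)`; stripe voxels of the output
#'   have mean 0 and population sd 1.
#' @export
whitestripe_normalize <- function(img, brain, ...) {
  ws <- estimate_white_stripe(img, brain, ...)
  if (ws$sigma_ws <= 0)
    stop("white stripe has zero intensity spread; normalization undefined")
  out <- volume_image((img$voxels - ws$mu_ws) / ws$sigma_ws, img$spacing)
  list(image = out,
       params = list(method = "whitestripe", mu = ws$mu_ws,
                     sigma = ws$sigma_ws),
       stripe = ws$stripe)
}

#' Standard histogram for piecewise-linear (Nyul) normalization
#'
#' @param landmarks_pct Strictly increasing percentiles in (0, 100], the
#'   landmark configuration (default `c(1,10,...,90,99)`).
#' @param landmarks_std Strictly increasing landmark intensities on the
#'   standard scale.
#' @param scale Two-element `(s_min, s_max)` bounds of the standard scale.
#' @return An object of class `standard_histogram`.
#' @export
standard_histogram <- function(landmarks_pct, landmarks_std, scale) {
  landmarks_pct <- as.numeric(landmarks_pct)
  landmarks_std <- as.numeric(landmarks_std)
  if (length(landmarks_pct) != length(landmarks_std))
    stop("landmark percentile and intensity vectors must have equal length")
  if (any(diff(landmarks_pct) <= 0) || any(landmarks_pct <= 0) ||
      any(landmarks_pct > 100))
    stop("'landmarks_pct' must be strictly increasing in (0, 100]")
  if (any(diff(landmarks_std) <= 0))
    stop("'landmarks_std' must be strictly increasing")
  structure(list(landmarks_pct = landmarks_pct,
                 landmarks_std = landmarks_std,
                 scale = as.numeric(scale)),
            class = "standard_histogram")
}

default_landmarks <- function() c(1, 10, 20, 30, 40, 50, 60, 70, 80, 90, 99)

#' Landmark percentiles of the in-brain intensities
#'
#' Landmarks are exact order statistics (inverse empirical CDF,
#' `x_(ceil(n p / 100))`), not interpolated quantiles: a landmark must be an
#' attained intensity so that the piecewise-linear map's node sits exactly
#' on an order statistic and the transformed image's recomputed landmark
#' percentiles reproduce the standard landmarks exactly.
#'
#' @param img A `volume_image`.
#' @param brain Brain `binary_mask`.
#' @param landmarks_pct Percentiles in (0, 100].
#' @return Numeric vector of landmark intensities.
#' @export
image_landmarks <- function(img, brain, landmarks_pct) {
  vals <- mask_values(img, brain)
  if (length(vals) == 0L) stop("brain mask is empty")
  as.numeric(stats::quantile(vals, probs = landmarks_pct / 100,
                             type = 1, names = FALSE))
}

#' Learn a standard histogram from training images
#'
#' Per training image, landmark percentiles are computed over brain voxels;
#' each image's `[p_first, p_last]` interval is affinely mapped onto
#' `scale`, and the mapped landmarks are averaged across images.
#'
#' @param images List of `volume_image`s.
#' @param brains List of matching brain `binary_mask`s.
#' @param landmarks_pct Landmark percentiles (default `c(1,10,...,90,99)`).
#' @param scale Standard scale bounds (default `c(0, 100)`).
#' @return A `standard_histogram`.
#' @export
learn_standard_histogram <- function(images, brains,
                                     landmarks_pct = default_landmarks(),
                                     scale = c(0, 100)) {
  if (length(images) < 1L) stop("at least one training image is required")
  if (length(images) != length(brains))
    stop("'images' and 'brains' must have the same length")
  if (any(diff(landmarks_pct) <= 0))
    stop("'landmarks_pct' must be strictly increasing")
  mapped <- vapply(seq_along(images), function(i) {
    lm <- image_landmarks(images[[i]], brains[[i]], landmarks_pct)
    span <- lm[length(lm)] - lm[1]
    if (span <= 0)
      stop("training image ", i, " has a degenerate landmark range")
    scale[1] + (lm - lm[1]) / span * (scale[2] - scale[1])
  }, numeric(length(landmarks_pct)))
  std <- rowMeans(mapped)
  standard_histogram(landmarks_pct, std, scale)
}

#' Nyul piecewise-linear intensity transform
#'
#' Maps the image's landmark percentiles (computed over brain voxels)
#' exactly onto the standard landmarks, linearly interpolating between
#' landmarks and extending the end segments' slopes beyond the outer
#' landmarks.  The map is monotone non-decreasing.
#'
#' @param img A `volume_image`.
#' @param brain Brain `binary_mask`.
#' @param std A `standard_histogram`.
#' @return `list(image =, params =)`; `params` records the image landmarks
#'   and the standard used.
#' @export
nyul_transform <- function(img, brain, std) {
  if (!inherits(std, "standard_histogram"))
    stop("'std' must be a standard_histogram")
  lm <- image_landmarks(img, brain, std$landmarks_pct)
  if (any(diff(lm) <= 0))
    stop("image landmarks are not strictly increasing (tied percentiles); ",
         "Nyul transform undefined")
  out <- piecewise_linear_map(img$voxels, lm, std$landmarks_std)
  list(image = volume_image(out, img$spacing),
       params = list(method = "nyul", landmarks_img = lm, standard = std))
}

# Piecewise-linear map through nodes (xs, ys), end segments extended.
piecewise_linear_map <- function(v, xs, ys) {
  k <- length(xs)
  seg <- findInterval(v, xs, all.inside = TRUE) # 1..k-1
  x0 <- xs[seg]; y0 <- ys[seg]
  slope <- (ys[seg + 1L] - y0) / (xs[seg + 1L] - x0)
  out <- y0 + (v - x0) * slope
  array(out, dim = dim(v))
}

#' Apply a normalization method by name
#'
#' Dispatch helper used by the experiment drivers: `"none"` returns the
#' image unchanged, otherwise one of the three methods is applied.
#'
#' @param img A `volume_image`.
#' @param brain Brain `binary_mask`.
#' @param method One of `"none"`, `"zscore"`, `"whitestripe"`, `"nyul"`.
#' @param standard A `standard_histogram`, required for `"nyul"`.
#' @return `list(image =, params =)`.
#' @export
normalize_image <- function(img, brain,
                            method = c("none", "zscore", "whitestripe", "nyul"),
                            standard = NULL) {
  method <- match.arg(method)
  switch(method,
         none = list(image = img, params = list(method = "none")),
         zscore = zscore_normalize(img, brain),
         whitestripe = whitestripe_normalize(img, brain),
         nyul = {
           if (is.null(standard))
             stop("'nyul' normalization requires a standard_histogram")
           nyul_transform(img, brain, standard)
         })
}

#' Persist / load a standard histogram as JSON
#'
#' @param std A `standard_histogram`.
#' @param path JSON file path.
#' @return `write_standard_histogram` returns `path` invisibly;
#'   `read_standard_histogram` the reconstructed object.
#' @export
write_standard_histogram <- function(std, path) {
  jsonlite::write_json(unclass(std), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_standard_histogram
#' @export
read_standard_histogram <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  standard_histogram(x$landmarks_pct, x$landmarks_std, x$scale)
}
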