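#' Configuration for synthetic phantom cohorts
#'
#' Bundles every tunable of the synthetic-data generator: cohort sizes, grid
#' geometry, tissue intensity statistics for a T1-like contrast, tumour
#' geometry, the grade effect sizes (tumour mean shift, texture field
#' variance and correlation length) and the scanner-effect parameter ranges
#' for the paired (test-retest) and graded (multi-site) cohorts.
#'
#' Defaults emulate the study conditions the pipeline is designed for: a
#' 20-subject paired cohort scanned twice under different intensity
#' gain/offset, and a 108 low-grade / 135 high-grade cohort acquired on
#' heterogeneous scanners.  The tumour occupies on average 7.5% (sd 3.7%) of
#' the brain.  The default paired scanner effect is affine (gain in
#' \[0.6, 1.8\], offset in \[-20, 20\]) plus Gaussian noise with sd equal to
#' 2% of the white-matter mean.  In the graded cohort the `confound_gain`
#' knob (default 0.2) shifts low-grade scanner gains upward, so that the
#' scanner effect opposes the tumour-intensity grade signal and intensity
#' normalization genuinely matters for classification.
#'
#' @param n_paired Number of paired subjects (default 20).
#' @param n_low_grade,n_high_grade Graded-cohort class sizes (defaults 108
#'   and 135).
#' @param grid Integer length-3 grid shape (default 64^3).
#' @param spacing Voxel spacing in mm (default 1 mm isotropic).
#' @param tissue Named list of CSF/GM/WM means and sds (T1-like ordering
#'   CSF < GM < WM; WM is the largest compartment so a white-matter mode is
#'   detectable).
#' @param tumour_fraction_mean,tumour_fraction_sd,tumour_fraction_bounds
#'   Tumour volume as a fraction of brain volume: normal with these moments,
#'   truncated to the bounds.
#' @param tumour_mean Named vector `c(low=, high=)`: tumour mean intensity
#'   per grade (intensity units).
#' @param tumour_mean_jitter_sd Between-subject sd of the tumour mean.
#' @param field_sd Named vector `c(low=, high=)`: sd of the stationary
#'   correlated random field inside the tumour (the texture signal).
#' @param field_sd_jitter Multiplicative uniform jitter range for `field_sd`.
#' @param corr_length Named vector `c(low=, high=)`: Gaussian correlation
#'   length of the tumour field, voxels (high grade: shorter).
#' @param tumour_noise_sd Additional iid noise inside the tumour.
#' @param paired_scanner,graded_scanner Scanner-effect parameter ranges;
#'   lists with two-element ranges `gain`, `offset`, `bias_amplitude`,
#'   `noise_sd`, `gamma` from which per-acquisition effects are drawn
#'   uniformly.
#' @param confound_gain Amount added to the low-grade gain draw in the
#'   graded cohort (0 disables the scanner-grade confound).
#' @param seed Master seed; all per-case seeds are spawned from it by fixed
#'   arithmetic and recorded in each emitted case.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_paired = 20L,
                          n_low_grade = 108L,
                          n_high_grade = 135L,
                          grid = c(64L, 64L, 64L),
                          spacing = c(1, 1, 1),
                          tissue = list(csf_mean = 40, csf_sd = 4,
                                        gm_mean = 80, gm_sd = 6,
                                        wm_mean = 120, wm_sd = 5),
                          tumour_fraction_mean = 0.075,
                          tumour_fraction_sd = 0.037,
                          tumour_fraction_bounds = c(0.02, 0.18),
                          tumour_mean = c(low = 140, high = 150),
                          tumour_mean_jitter_sd = 4,
                          field_sd = c(low = 8, high = 14),
                          field_sd_jitter = c(0.85, 1.18),
                          corr_length = c(low = 3.0, high = 1.6),
                          tumour_noise_sd = 2,
                          paired_scanner = scanner_ranges(gain = c(0.6, 1.8),
                                                          offset = c(-20, 20),
                                                          noise_sd = c(2.4, 2.4)),
                          graded_scanner = scanner_ranges(gain = c(0.5, 1.5),
                                                          offset = c(-30, 30),
                                                          noise_sd = c(2.4, 2.4)),
                          confound_gain = 0.2,
                          seed = 20200723L) {
  if (n_paired < 2L || n_low_grade < 2L || n_high_grade < 2L)
    stop("all cohort counts must be >= 2")
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid < 8L))
    stop("'grid' must be 3 integers >= 8")
  stopifnot(tissue$csf_mean < tissue$gm_mean, tissue$gm_mean < tissue$wm_mean,
            tumour_fraction_mean > 0, tumour_fraction_sd >= 0,
            all(is.finite(unlist(tumour_mean))),
            all(is.finite(unlist(field_sd))), all(unlist(corr_length) > 0))
  structure(list(n_paired = as.integer(n_paired),
                 n_low_grade = as.integer(n_low_grade),
                 n_high_grade = as.integer(n_high_grade),
                 grid = grid, spacing = as.numeric(spacing),
                 tissue = tissue,
                 tumour_fraction_mean = tumour_fraction_mean,
                 tumour_fraction_sd = tumour_fraction_sd,
                 tumour_fraction_bounds = tumour_fraction_bounds,
                 tumour_mean = tumour_mean,
                 tumour_mean_jitter_sd = tumour_mean_jitter_sd,
                 field_sd = field_sd,
                 field_sd_jitter = field_sd_jitter,
                 corr_length = corr_length,
                 tumour_noise_sd = tumour_noise_sd,
                 paired_scanner = paired_scanner,
                 graded_scanner = graded_scanner,
                 confound_gain = confound_gain,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Scanner-effect parameter ranges
#'
#' Each element is a two-element range from which one value is drawn
#' uniformly per acquisition.
#'
#' @param gain,offset,bias_amplitude,noise_sd,gamma Two-element numeric
#'   ranges.
#' @return A named list of ranges.
#' @export
scanner_ranges <- function(gain = c(1, 1), offset = c(0, 0),
                           bias_amplitude = c(0, 0), noise_sd = c(0, 0),
                           gamma = c(1, 1)) {
  rng <- list(gain = gain, offset = offset, bias_amplitude = bias_amplitude,
              noise_sd = noise_sd, gamma = gamma)
  for (nm in names(rng)) {
    r <- rng[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      stop("range '", nm, "' must be a non-decreasing pair of finite numbers")
  }
  if (rng$gain[1] <= 0) stop("gain range must be strictly positive")
  if (rng$gamma[1] <= 0) stop("gamma range must be strictly positive")
  if (rng$noise_sd[1] < 0 || rng$bias_amplitude[1] < 0)
    stop("noise_sd and bias_amplitude must be >= 0")
  rng
}

#' Ranges describing a disabled scanner effect (exact identity map)
#' @return Ranges usable as `paired_scanner` / `graded_scanner`.
#' @export
zero_scanner_ranges <- function() scanner_ranges()

#' A single scanner effect
#'
#' The acquisition model is `a * I(x)^gamma * bias(x) + b + noise`, where
#' `bias` is a smooth low-order multiplicative field with mean 1 over the
#' brain.  With `gamma = 1`, `bias_amplitude = 0` and `noise_sd = 0` the map
#' is exactly affine.
#'
#' @param gain Multiplicative gain `a` (> 0).
#' @param offset Additive offset `b` (intensity units).
#' @param bias_amplitude Fractional sd of the multiplicative bias field over
#'   the brain (>= 0; 0 disables it).
#' @param noise_sd Additive Gaussian noise sd (>= 0).
#' @param gamma Intensity exponent (> 0; 1 = purely affine).
#' @return An object of class `scanner_effect`.
#' @export
scanner_effect <- function(gain = 1, offset = 0, bias_amplitude = 0,
                           noise_sd = 0, gamma = 1) {
  if (!is.finite(gain) || gain <= 0) stop("'gain' must be > 0")
  if (!is.finite(gamma) || gamma <= 0) stop("'gamma' must be > 0")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (!is.finite(bias_amplitude) || bias_amplitude < 0)
    stop("'bias_amplitude' must be >= 0")
  structure(list(gain = gain, offset = offset,
                 bias_amplitude = bias_amplitude,
                 noise_sd = noise_sd, gamma = gamma),
            class = "scanner_effect")
}

draw_scanner_effect <- function(ranges, seed) {
  with_local_seed(seed, {
    scanner_effect(gain = stats::runif(1, ranges$gain[1], ranges$gain[2]),
                   offset = stats::runif(1, ranges$offset[1], ranges$offset[2]),
                   bias_amplitude = stats::runif(1, ranges$bias_amplitude[1],
                                                 ranges$bias_amplitude[2]),
                   noise_sd = stats::runif(1, ranges$noise_sd[1],
                                           ranges$noise_sd[2]),
                   gamma = stats::runif(1, ranges$gamma[1], ranges$gamma[2]))
  })
}

# Separable Gaussian smoothing of a 3D array with edge renormalization.
smooth3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  norm <- array(1, dim = dim(arr))
  conv_axis <- function(a, axis) {
    out <- array(0, dim = dim(a))
    n <- dim(a)[axis]
    for (k in seq_along(w)) {
      off <- k - r - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      idx_dst <- which(ok)
      idx_src <- src[ok]
      if (axis == 1L) out[idx_dst, , ] <- out[idx_dst, , ] + w[k] * a[idx_src, , ]
      else if (axis == 2L) out[, idx_dst, ] <- out[, idx_dst, ] + w[k] * a[, idx_src, ]
      else out[, , idx_dst] <- out[, , idx_dst] + w[k] * a[, , idx_src]
    }
    out
  }
  for (axis in 1:3) {
    arr <- conv_axis(arr, axis)
    norm <- conv_axis(norm, axis)
  }
  arr / norm
}

# Ellipsoidal "distance" of every grid voxel from a centre, per semi-axes.
ellipsoid_dist <- function(grid, centre, axes) {
  x <- (seq_len(grid[1]) - centre[1]) / axes[1]
  y <- (seq_len(grid[2]) - centre[2]) / axes[2]
  z <- (seq_len(grid[3]) - centre[3]) / axes[3]
  sqrt(outer(outer(x^2, y^2, `+`), z^2, `+`))
}

#' Generate one brain phantom
#'
#' Builds an ellipsoidal brain with three nested tissue compartments
#' (CSF ventricle < GM shell < WM bulk for a T1-like contrast, with WM the
#' largest so a white-matter histogram mode is detectable) and a
#' spherical-ish tumour whose texture is a stationary correlated Gaussian
#' field.  High-grade tumours get a larger field variance and a shorter
#' correlation length; their mean intensity is also shifted.  The output is
#' the "true" anatomy: no scanner effect is applied.
#'
#' @param config A [cohort_config()].
#' @param grade `"low"` or `"high"`.
#' @param seed Integer seed; the phantom is a pure function of
#'   `(config, grade, seed)`.
#' @return An object of class `phantom_case` with fields `image`, `brain`,
#'   `tumour`, `grade`, `scanner_id`, `case_id`, `seed`, `effect`.
#' @export
make_brain_phantom <- function(config, grade = c("low", "high"), seed) {
  grade <- match.arg(grade)
  grid <- config$grid
  if (any(grid < 16L))
    stop("grid too small to fit brain and tumour (need >= 16 voxels per axis)")
  ts <- config$tissue
  with_local_seed(seed, {
    centre <- (grid + 1) / 2
    axes <- c(0.42, 0.36, 0.33) * grid + stats::runif(3, -1.5, 1.5)
    e <- ellipsoid_dist(grid, centre, axes)
    brain <- e <= 1
    gm <- brain & e > 0.87
    vent <- ellipsoid_dist(grid, centre, 0.22 * axes) <= 1
    wm <- brain & !gm & !vent
    csf <- brain & !gm & vent

    vox <- array(0, dim = grid)
    vox[csf] <- stats::rnorm(sum(csf), ts$csf_mean, ts$csf_sd)
    vox[gm] <- stats::rnorm(sum(gm), ts$gm_mean, ts$gm_sd)
    vox[wm] <- stats::rnorm(sum(wm), ts$wm_mean, ts$wm_sd)

    # tumour volume as a truncated-normal fraction of the brain
    bnd <- config$tumour_fraction_bounds
    f <- NA_real_
    for (i in 1:200) {
      cand <- stats::rnorm(1, config$tumour_fraction_mean,
                           config$tumour_fraction_sd)
      if (cand >= bnd[1] && cand <= bnd[2]) { f <- cand; break }
    }
    if (is.na(f)) f <- config$tumour_fraction_mean
    v_brain <- sum(brain)
    r <- (3 * f * v_brain / (4 * pi))^(1 / 3)
    u <- stats::runif(3, 0.85, 1.2)
    t_axes <- r * u / prod(u)^(1 / 3)
    s_max <- 0.97 - max(t_axes) / min(axes)
    if (s_max <= 0.05)
      stop("grid too small to fit brain and tumour at the requested fraction")
    # uniform centre inside the shrunken brain ellipsoid
    repeat {
      p <- stats::runif(3, -1, 1)
      if (sum(p^2) <= 1) break
    }
    t_centre <- centre + p * s_max * axes
    tum <- ellipsoid_dist(grid, t_centre, t_axes) <= 1 & brain
    if (sum(tum) < 8L)
      stop("grid too small to fit brain and tumour (tumour under 8 voxels)")

    t_mean <- config$tumour_mean[[grade]] +
      stats::rnorm(1, 0, config$tumour_mean_jitter_sd)
    f_sd <- config$field_sd[[grade]] *
      stats::runif(1, config$field_sd_jitter[1], config$field_sd_jitter[2])
    # correlated field on the tumour bounding box
    bb <- apply(which(tum, arr.ind = TRUE), 2, range)
    bdim <- bb[2, ] - bb[1, ] + 1L
    field <- smooth3d(array(stats::rnorm(prod(bdim)), dim = bdim),
                      config$corr_length[[grade]])
    sub <- tum[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2], bb[1, 3]:bb[2, 3]]
    fv <- field[sub]
    fv <- (fv - mean(fv)) / max(stats::sd(fv), 1e-12) * f_sd
    vox[tum] <- t_mean + fv + stats::rnorm(sum(tum), 0, config$tumour_noise_sd)

    structure(list(image = volume_image(vox, config$spacing),
                   brain = binary_mask(brain * 1L, config$spacing),
                   tumour = binary_mask(tum * 1L, config$spacing),
                   grade = grade, scanner_id = "truth",
                   case_id = NA_character_, seed = as.integer(seed),
                   effect = NULL),
              class = "phantom_case")
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat("<phantom_case> id=", x$case_id, " grade=", x$grade,
      " scanner=", x$scanner_id,
      " tumour fraction=", round(mask_volume(x$tumour) / mask_volume(x$brain), 4),
      " seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Apply a scanner effect to a volume
#'
#' `out = gain * I^gamma * bias(x) + offset + noise`, where `bias` is a sum
#' of low-order separable polynomials renormalized to mean 1 over the brain
#' mask (sd = `bias_amplitude`).  Deterministic given `seed`.  With
#' `gamma = 1`, `bias_amplitude = 0` and `noise_sd = 0` the map is exactly
#' affine and, at gain 1 / offset 0, voxel-identical to the input.
#'
#' @param img A `volume_image`.
#' @param brain Brain `binary_mask` (bias-field normalization support).
#' @param eff A [scanner_effect()].
#' @param seed Integer seed for bias coefficients and noise.
#' @return A `volume_image`.
#' @export
apply_scanner_effect <- function(img, brain, eff, seed) {
  stopifnot_same_grid(img, brain)
  if (!inherits(eff, "scanner_effect")) stop("'eff' must be a scanner_effect")
  if (eff$gain <= 0) stop("'gain' must be > 0")
  v <- img$voxels
  with_local_seed(seed, {
    if (eff$gamma != 1) {
      if (any(v < 0))
        stop("gamma != 1 requires non-negative intensities")
      v <- v^eff$gamma
    }
    if (eff$bias_amplitude > 0) {
      d <- dim(v)
      nx <- (seq_len(d[1]) - (d[1] + 1) / 2) / (d[1] / 2)
      ny <- (seq_len(d[2]) - (d[2] + 1) / 2) / (d[2] / 2)
      nz <- (seq_len(d[3]) - (d[3] + 1) / 2) / (d[3] / 2)
      co <- stats::rnorm(9)
      fx <- outer(outer(nx, rep(1, d[2])), rep(1, d[3]))
      fy <- outer(outer(rep(1, d[1]), ny), rep(1, d[3]))
      fz <- outer(outer(rep(1, d[1]), rep(1, d[2])), nz)
      raw <- co[1] * fx + co[2] * fy + co[3] * fz +
        co[4] * fx^2 + co[5] * fy^2 + co[6] * fz^2 +
        co[7] * fx * fy + co[8] * fx * fz + co[9] * fy * fz
      inb <- brain$voxels == 1L
      s <- stats::sd(raw[inb])
      raw <- (raw - mean(raw[inb])) / max(s, 1e-12) * eff$bias_amplitude
      bias <- pmax(1 + raw, 0.05)
      v <- v * bias
    }
    if (eff$gain != 1) v <- eff$gain * v
    if (eff$offset != 0) v <- v + eff$offset
    if (eff$noise_sd > 0)
      v <- v + array(stats::rnorm(length(v), 0, eff$noise_sd), dim = dim(v))
  })
  volume_image(v, img$spacing)
}

acquire_case <- function(anatomy, eff, seed, scanner_id, case_id) {
  img <- apply_scanner_effect(anatomy$image, anatomy$brain, eff, seed)
  out <- anatomy
  out$image <- img
  out$scanner_id <- scanner_id
  out$case_id <- case_id
  out$effect <- eff
  out$seed <- as.integer(seed)
  out
}

#' Generate the paired two-scanner cohort
#'
#' One anatomy per subject, acquired under two independently drawn scanner
#' effects.  Brain and tumour masks are identical across the two members of
#' a pair (the analysis intersects masks across acquisitions, so a single
#' shared mask is the intended structure).
#'
#' @param config A [cohort_config()].
#' @return A list of `n_paired` elements, each `list(A =, B =)` of
#'   `phantom_case`s.
#' @export
generate_paired_cohort <- function(config) {
  if (config$n_paired < 2L) stop("n_paired must be >= 2")
  lapply(seq_len(config$n_paired), function(i) {
    anat <- make_brain_phantom(config, grade = "low",
                               seed = spawn_seed(config$seed, i, 1L))
    effA <- draw_scanner_effect(config$paired_scanner,
                                spawn_seed(config$seed, i, 2L))
    effB <- draw_scanner_effect(config$paired_scanner,
                                spawn_seed(config$seed, i, 3L))
    id <- sprintf("pair%03d", i)
    list(A = acquire_case(anat, effA, spawn_seed(config$seed, i, 4L), "A", id),
         B = acquire_case(anat, effB, spawn_seed(config$seed, i, 5L), "B", id))
  })
}

#' Generate the two-grade multi-scanner cohort
#'
#' `n_low_grade + n_high_grade` cases, each with its own anatomy and its own
#' scanner effect drawn from `graded_scanner` ranges.  When
#' `config$confound_gain > 0`, low-grade acquisitions receive that much
#' extra gain, so the scanner effect works against the (higher) intrinsic
#' tumour intensity of high-grade cases and masks the grade signal in raw
#' intensities.
#'
#' @param config A [cohort_config()].
#' @return A list of `phantom_case`s (low-grade cases first).
#' @export
generate_graded_cohort <- function(config) {
  if (config$n_low_grade < 2L || config$n_high_grade < 2L)
    stop("graded cohort needs >= 2 cases per grade")
  grades <- c(rep("low", config$n_low_grade), rep("high", config$n_high_grade))
  lapply(seq_along(grades), function(i) {
    g <- grades[i]
    anat <- make_brain_phantom(config, grade = g,
                               seed = spawn_seed(config$seed, 1000L + i, 1L))
    eff <- draw_scanner_effect(config$graded_scanner,
                               spawn_seed(config$seed, 1000L + i, 2L))
    if (g == "low" && config$confound_gain != 0)
      eff$gain <- eff$gain + config$confound_gain
    acquire_case(anat, eff, spawn_seed(config$seed, 1000L + i, 3L),
                 sprintf("site%02d", 1L + (i %% 7L)), sprintf("case%03d", i))
  })
}

#' Write / read a phantom case as NIfTI plus a JSON manifest
#'
#' Writes `image.nii.gz`, `brain.nii.gz`, `tumour.nii.gz` and
#' `manifest.json` (grade, scanner id, seed, effect parameters) to `dir`.
#'
#' @param case A `phantom_case`.
#' @param dir Output directory (created if missing).
#' @return `write_phantom_case` returns `dir` invisibly;
#'   `read_phantom_case` returns the reconstructed `phantom_case`.
#' @export
write_phantom_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_nifti(case$image, file.path(dir, "image.nii.gz"))
  write_nifti(case$brain, file.path(dir, "brain.nii.gz"))
  write_nifti(case$tumour, file.path(dir, "tumour.nii.gz"))
  manifest <- list(case_id = case$case_id, grade = case$grade,
                   scanner_id = case$scanner_id, seed = case$seed,
                   effect = if (is.null(case$effect)) NULL
                            else unclass(case$effect))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_phantom_case
#' @export
read_phantom_case <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  eff <- if (is.null(man$effect)) NULL else do.call(scanner_effect, man$effect)
  structure(list(image = read_volume(file.path(dir, "image.nii.gz")),
                 brain = read_mask(file.path(dir, "brain.nii.gz")),
                 tumour = read_mask(file.path(dir, "tumour.nii.gz")),
                 grade = man$grade, scanner_id = man$scanner_id,
                 case_id = man$case_id, seed = man$seed, effect = eff),
            class = "phantom_case")
}
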