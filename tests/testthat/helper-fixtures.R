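# Shared small fixtures: desk-scale cohort configurations and ad hoc
# volumes used across test files.

small_config <- function(seed = 11L, ...) {
  cohort_config(grid = c(32L, 32L, 32L), n_paired = 4L,
                n_low_grade = 6L, n_high_grade = 8L, seed = seed, ...)
}

# a volume whose brain mask selects exactly the given values
vol_with_mask_values <- function(values, dims = c(8L, 8L, 8L)) {
  v <- array(0, dim = dims)
  m <- array(0L, dim = dims)
  v[seq_along(values)] <- values
  m[seq_along(values)] <- 1L
  list(img = volume_image(v), mask = binary_mask(m))
}

# bimodal "brain": GM fraction at gm_mean, rest (larger) at wm_mean
bimodal_brain <- function(gm_mean = 80, wm_mean = 120, gm_sd = 2, wm_sd = 2,
                          n_gm = 1200L, n_wm = 2000L, dims = c(16L, 16L, 16L),
                          seed = 5L) {
  set.seed(seed)
  v <- array(0, dim = dims)
  m <- array(0L, dim = dims)
  idx <- seq_len(n_gm + n_wm)
  m[idx] <- 1L
  vals <- c(rnorm(n_gm, gm_mean, gm_sd), rnorm(n_wm, wm_mean, wm_sd))
  v[idx] <- vals
  list(img = volume_image(v), mask = binary_mask(m))
}
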