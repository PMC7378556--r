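test_that("phantom generation is a pure function of (config, grade, seed)", {
  cfg <- small_config()
  a <- make_brain_phantom(cfg, "low", seed = 7L)
  b <- make_brain_phantom(cfg, "low", seed = 7L)
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$tumour$voxels, b$tumour$voxels)
  c <- make_brain_phantom(cfg, "low", seed = 8L)
  expect_false(identical(a$image$voxels, c$image$voxels))
})

test_that("high-grade tumours are more heterogeneous than low-grade ones", {
  cfg <- small_config()
  for (s in 1:5) {
    lo <- make_brain_phantom(cfg, "low", seed = s)
    hi <- make_brain_phantom(cfg, "high", seed = s)
    expect_gt(var(mask_values(hi$image, hi$tumour)),
              var(mask_values(lo$image, lo$tumour)))
  }
})

test_that("tumour is inside the brain with the configured volume fraction", {
  cfg <- small_config()
  fr <- vapply(1:100, function(s) {
    ph <- make_brain_phantom(cfg, if (s %% 2) "low" else "high", seed = s)
    expect_true(all(ph$brain$voxels[ph$tumour$voxels == 1L] == 1L))
    mask_volume(ph$tumour) / mask_volume(ph$brain)
  }, numeric(1))
  expect_true(all(fr >= cfg$tumour_fraction_bounds[1] - 0.005))
  expect_true(all(fr <= cfg$tumour_fraction_bounds[2] + 0.005))
  expect_lt(abs(mean(fr) - cfg$tumour_fraction_mean), 0.02)
})

test_that("phantom tissue compartments are ordered CSF < GM < WM", {
  ph <- make_brain_phantom(cohort_config(), "low", seed = 2L)
  v <- mask_values(ph$image, ph$brain)
  # three tissue modes present: substantial mass near each tissue mean
  expect_gt(mean(v > 100 & v < 140), 0.3)  # WM bulk
  expect_gt(mean(v > 60 & v < 100), 0.1)   # GM shell
})

test_that("a too-small grid is rejected explicitly", {
  cfg <- small_config()
  cfg$grid <- c(12L, 12L, 12L)
  expect_error(make_brain_phantom(cfg, "low", seed = 1L), "too small")
})

test_that("scanner effect identity, affine map and seeded noise contracts", {
  cfg <- small_config()
  ph <- make_brain_phantom(cfg, "low", seed = 3L)
  idn <- apply_scanner_effect(ph$image, ph$brain, scanner_effect(), seed = 1L)
  expect_identical(idn$voxels, ph$image$voxels)
  aff <- apply_scanner_effect(ph$image, ph$brain,
                              scanner_effect(gain = 2, offset = 5), seed = 1L)
  expect_equal(aff$voxels, 2 * ph$image$voxels + 5)
  eff <- scanner_effect(noise_sd = 3)
  n1 <- apply_scanner_effect(ph$image, ph$brain, eff, seed = 10L)
  n2 <- apply_scanner_effect(ph$image, ph$brain, eff, seed = 10L)
  n3 <- apply_scanner_effect(ph$image, ph$brain, eff, seed = 11L)
  expect_identical(n1$voxels, n2$voxels)
  expect_false(identical(n1$voxels, n3$voxels))
  expect_error(scanner_effect(gain = 0), "gain")
})

test_that("bias field is smooth, multiplicative and mean 1 over the brain", {
  cfg <- small_config()
  ph <- make_brain_phantom(cfg, "low", seed = 4L)
  eff <- scanner_effect(bias_amplitude = 0.2)
  out <- apply_scanner_effect(ph$image, ph$brain, eff, seed = 9L)
  ratio <- out$voxels[ph$brain$voxels == 1L] /
    ph$image$voxels[ph$brain$voxels == 1L]
  expect_equal(mean(ratio), 1, tolerance = 1e-6)
  expect_gt(sd(ratio), 0.1) # field genuinely varies
})

test_that("paired cohort shares masks within pairs and honours the count", {
  cfg <- small_config()
  pairs <- generate_paired_cohort(cfg)
  expect_length(pairs, cfg$n_paired)
  for (p in pairs) {
    expect_identical(p$A$brain$voxels, p$B$brain$voxels)
    expect_identical(p$A$tumour$voxels, p$B$tumour$voxels)
    expect_false(identical(p$A$image$voxels, p$B$image$voxels))
  }
  expect_identical(cohort_config()$n_paired, 20L)
  # disabled scanner effects make the pair bit-identical
  cfg0 <- small_config(paired_scanner = zero_scanner_ranges())
  p0 <- generate_paired_cohort(cfg0)[[1]]
  expect_identical(p0$A$image$voxels, p0$B$image$voxels)
})

test_that("graded cohort has the configured class composition", {
  cfg <- small_config()
  cohort <- generate_graded_cohort(cfg)
  grades <- vapply(cohort, `[[`, character(1), "grade")
  expect_length(cohort, cfg$n_low_grade + cfg$n_high_grade)
  expect_identical(sum(grades == "low"), as.integer(cfg$n_low_grade))
  expect_identical(sum(grades == "high"), as.integer(cfg$n_high_grade))
  dflt <- cohort_config()
  expect_identical(dflt$n_low_grade + dflt$n_high_grade, 243L)
})

test_that("phantom cases round-trip through NIfTI + JSON manifests", {
  cfg <- small_config()
  pairs <- generate_paired_cohort(cfg)
  dir <- withr::local_tempdir()
  write_phantom_case(pairs[[1]]$A, dir)
  back <- read_phantom_case(dir)
  expect_equal(back$image$voxels, pairs[[1]]$A$image$voxels,
               tolerance = 1e-6)
  expect_identical(back$brain$voxels, pairs[[1]]$A$brain$voxels)
  expect_identical(back$grade, pairs[[1]]$A$grade)
  expect_equal(back$effect$gain, pairs[[1]]$A$effect$gain)
})
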