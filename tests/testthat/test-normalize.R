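test_that("Z-Score normalization matches the two-point hand case", {
  f <- vol_with_mask_values(c(0, 2))
  res <- zscore_normalize(f$img, f$mask)
  expect_equal(mask_values(res$image, f$mask), c(-1, 1))
  expect_equal(res$params$mu, 1)
  expect_equal(res$params$sigma, 1)
})

test_that("Z-Score output has brain mean 0 and population sd 1", {
  ph <- make_brain_phantom(small_config(), "low", seed = 21L)
  res <- zscore_normalize(ph$image, ph$brain)
  v <- mask_values(res$image, ph$brain)
  expect_lt(abs(mean(v)), 1e-9)
  expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-9)
  # idempotence: re-normalizing a standardized image changes nothing
  res2 <- zscore_normalize(res$image, ph$brain)
  expect_equal(res2$image$voxels, res$image$voxels, tolerance = 1e-12)
})

test_that("Z-Score rejects constant images and erases affine scanner maps", {
  f <- vol_with_mask_values(rep(5, 10))
  expect_error(zscore_normalize(f$img, f$mask), "constant")
  ph <- make_brain_phantom(small_config(), "low", seed = 22L)
  aff <- volume_image(3.1 * ph$image$voxels - 40, ph$image$spacing)
  z1 <- zscore_normalize(ph$image, ph$brain)$image
  z2 <- zscore_normalize(aff, ph$brain)$image
  expect_lt(max(abs(z1$voxels - z2$voxels)), 1e-9)
})

test_that("white-stripe estimation finds the white-matter mode", {
  f <- bimodal_brain()
  ws <- estimate_white_stripe(f$img, f$mask)
  expect_lt(abs(ws$mu_ws - 120), 2)
  # stripe is inside the brain and inside the +/- 5% intensity band
  expect_true(all(f$mask$voxels[ws$stripe$voxels == 1L] == 1L))
  sv <- mask_values(f$img, ws$stripe)
  expect_true(all(sv >= 0.95 * 0.95 * 120 & sv <= 1.05 * 1.05 * 120))
})

test_that("white-stripe on an exactly constant WM recovers it exactly", {
  set.seed(1)
  v <- array(0, dim = c(16, 16, 16))
  m <- array(0L, dim = c(16, 16, 16))
  m[seq_len(3000)] <- 1L
  v[seq_len(1000)] <- rnorm(1000, 80, 1.5)
  v[1001:3000] <- 120 # noise-free white matter
  img <- volume_image(v); msk <- binary_mask(m)
  ws <- estimate_white_stripe(img, msk)
  expect_identical(ws$mu_ws, 120)
  expect_identical(ws$sigma_ws, 0)
  expect_error(whitestripe_normalize(img, msk), "zero")
})

test_that("WhiteStripe normalization standardizes the stripe and is affine", {
  f <- bimodal_brain()
  res <- whitestripe_normalize(f$img, f$mask)
  sv <- mask_values(res$image, res$stripe)
  expect_lt(abs(mean(sv)), 1e-9)
  expect_lt(abs(sqrt(mean((sv - mean(sv))^2)) - 1), 1e-9)
  expect_equal(cor(as.numeric(f$img$voxels), as.numeric(res$image$voxels)), 1)
  # second application is near-identity on the stripe statistics; the
  # re-detected mode is only bin-centre accurate, so the check is coarse
  ws2 <- estimate_white_stripe(res$image, f$mask)
  expect_lt(abs(ws2$mu_ws), 1)
  expect_gt(ws2$sigma_ws, 0.5); expect_lt(ws2$sigma_ws, 2)
})

test_that("standard histogram learning averages affinely mapped landmarks", {
  ph <- make_brain_phantom(small_config(), "low", seed = 23L)
  one <- learn_standard_histogram(list(ph$image), list(ph$brain))
  expect_true(all(diff(one$landmarks_std) > 0))
  expect_equal(one$landmarks_std[1], 0)
  expect_equal(one$landmarks_std[length(one$landmarks_std)], 100)
  # two identical training images give the same model as one
  two <- learn_standard_histogram(list(ph$image, ph$image),
                                  list(ph$brain, ph$brain))
  expect_equal(two$landmarks_std, one$landmarks_std)
  # percentiles are equivariant under positive affine maps
  aff <- volume_image(2.5 * ph$image$voxels + 30, ph$image$spacing)
  froma <- learn_standard_histogram(list(aff), list(ph$brain))
  expect_equal(froma$landmarks_std, one$landmarks_std, tolerance = 1e-9)
})

test_that("Nyul transform lands the landmark percentiles on the standard", {
  cfg <- small_config()
  imgs <- lapply(31:33, function(s) make_brain_phantom(cfg, "low", seed = s))
  std <- learn_standard_histogram(lapply(imgs, `[[`, "image"),
                                  lapply(imgs, `[[`, "brain"))
  ph <- make_brain_phantom(cfg, "high", seed = 40L)
  res <- nyul_transform(ph$image, ph$brain, std)
  got <- as.numeric(quantile(mask_values(res$image, ph$brain),
                             std$landmarks_pct / 100, type = 1,
                             names = FALSE))
  expect_equal(got, std$landmarks_std, tolerance = 1e-12)
  # monotone: voxel ordering is preserved
  o_in <- order(ph$image$voxels[1:500])
  expect_true(all(diff(res$image$voxels[1:500][o_in]) >= 0))
  # a voxel exactly at the median landmark maps to the median standard
  lmk <- res$params$landmarks_img
  med <- volume_image(array(lmk[6], dim = c(8, 8, 8)))
  medres <- piecewise_linear_map(med$voxels, lmk, std$landmarks_std)
  expect_equal(medres[1], std$landmarks_std[6])
})

test_that("Nyul is the identity when landmarks already match the standard", {
  ph <- make_brain_phantom(small_config(), "low", seed = 41L)
  lmk <- image_landmarks(ph$image, ph$brain, default_landmarks())
  std <- standard_histogram(default_landmarks(), lmk, range(lmk))
  res <- nyul_transform(ph$image, ph$brain, std)
  expect_equal(res$image$voxels, ph$image$voxels, tolerance = 1e-12)
})

test_that("standard histograms persist to JSON and back", {
  ph <- make_brain_phantom(small_config(), "low", seed = 42L)
  std <- learn_standard_histogram(list(ph$image), list(ph$brain))
  path <- withr::local_tempfile(fileext = ".json")
  write_standard_histogram(std, path)
  back <- read_standard_histogram(path)
  expect_equal(back$landmarks_std, std$landmarks_std)
  expect_equal(back$landmarks_pct, std$landmarks_pct)
})

test_that("normalize_image dispatches and validates", {
  ph <- make_brain_phantom(small_config(), "low", seed = 43L)
  expect_identical(normalize_image(ph$image, ph$brain, "none")$image$voxels,
                   ph$image$voxels)
  expect_error(normalize_image(ph$image, ph$brain, "nyul"), "standard")
})
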