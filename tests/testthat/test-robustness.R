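test_that("masked histograms count correctly and clip to the end bins", {
  f <- vol_with_mask_values(rep(5, 10))
  h <- histogram_of(f$img, f$mask, edges = c(0, 4, 6, 10))
  expect_equal(h$probabilities, c(0, 1, 0))
  f2 <- vol_with_mask_values(c(rep(1.5, 5), rep(3.5, 5)))
  h2 <- histogram_of(f2$img, f2$mask, edges = c(1, 2, 3, 4))
  expect_equal(h2$probabilities, c(0.5, 0, 0.5))
  # out-of-range values fall into the end bins
  f3 <- vol_with_mask_values(c(-10, 50))
  h3 <- histogram_of(f3$img, f3$mask, edges = c(0, 1, 2))
  expect_equal(h3$probabilities, c(0.5, 0.5))
  # random counting oracle
  set.seed(20)
  v <- runif(400, 0, 8)
  fv <- vol_with_mask_values(v)
  edges <- seq(0, 8, by = 1)
  h4 <- histogram_of(fv$img, fv$mask, edges)
  want <- as.numeric(table(cut(v, edges, include.lowest = TRUE))) / 400
  expect_equal(h4$probabilities, want)
})

test_that("Jensen-Shannon divergence hits its closed-form identities", {
  set.seed(21)
  p <- runif(16); p <- p / sum(p)
  expect_equal(jensen_shannon_divergence(p, p), 0)
  expect_equal(jensen_shannon_divergence(c(1, 0), c(0, 1)), 1)
  # hand evaluation of the defining sum for p=(1,0), q=(.5,.5)
  m <- c(0.75, 0.25)
  want <- 0.5 * (1 * log2(1 / 0.75)) +
    0.5 * (0.5 * log2(0.5 / 0.75) + 0.5 * log2(0.5 / 0.25))
  expect_equal(jensen_shannon_divergence(c(1, 0), c(0.5, 0.5)), want)
  q <- runif(16); q <- q / sum(q)
  expect_lt(abs(jensen_shannon_divergence(p, q) -
                  jensen_shannon_divergence(q, p)), 1e-15)
  expect_gte(jensen_shannon_divergence(p, q), 0)
  expect_lte(jensen_shannon_divergence(p, q), 1)
  h1 <- histogram_of(vol_with_mask_values(1:4)$img,
                     vol_with_mask_values(1:4)$mask, c(0, 2, 4))
  h2 <- histogram_of(vol_with_mask_values(1:4)$img,
                     vol_with_mask_values(1:4)$mask, c(0, 2, 5))
  expect_error(jensen_shannon_divergence(h1, h2), "edges")
})

test_that("ICC(2,1) matches the independent ANOVA oracle", {
  m <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(icc(m), 1)
  # a pure offset is penalized below the Pearson correlation
  off <- cbind(c(1, 2, 3, 4), c(101, 102, 103, 104))
  expect_lt(icc(off), cor(off[, 1], off[, 2]))
  expect_equal(icc(off), icc_oracle(off), tolerance = 1e-12)
  set.seed(22)
  for (r in 1:25) {
    x <- matrix(rnorm(40, sd = runif(1, 0.5, 5)), ncol = 2)
    expect_equal(icc(x), icc_oracle(x), tolerance = 1e-12)
  }
  expect_equal(icc(matrix(3, 5, 2)), 1) # zero total variance convention
  expect_error(icc(matrix(1:4, 2, 2)), "3 subjects")
})

test_that("CCC matches Lin's formula with population moments", {
  expect_equal(ccc(cbind(1:3, 1:3)), 1)
  expect_equal(ccc(cbind(1:3, 2:4)), 4 / 7)
  expect_equal(ccc(matrix(2, 4, 2)), 1)
  set.seed(23)
  for (r in 1:25) {
    x <- matrix(rnorm(30, sd = runif(1, 0.5, 4)), ncol = 2)
    expect_equal(ccc(x), ccc_oracle(x), tolerance = 1e-12)
    expect_lte(abs(ccc(x)), abs(cor(x[, 1], x[, 2])) + 1e-12)
  }
})

test_that("ICC and CCC are invariant when both columns share an affine map", {
  set.seed(24)
  x <- matrix(rnorm(40, 10, 3), ncol = 2)
  y <- 2.5 * x - 7
  expect_equal(icc(x), icc(y), tolerance = 1e-12)
  expect_equal(ccc(x), ccc(y), tolerance = 1e-12)
})

test_that("robustness reports apply the strict dual threshold", {
  cfg <- small_config()
  pairs <- generate_paired_cohort(cfg)
  tabA <- extract_feature_table(lapply(pairs, `[[`, "A"), "zscore",
                                mode = "FBN", bins = 8,
                                which = "firstorder")
  # identical tables: everything robust
  repAA <- robustness_report(tabA, tabA)
  expect_true(all(repAA$features$robust))
  expect_identical(repAA$summary$n_robust[repAA$summary$class == "firstorder"],
                   18L)
  # heavy independent noise: essentially nothing robust
  tabN <- tabA
  set.seed(25)
  for (f in feature_columns(tabN))
    tabN[[f]] <- rnorm(nrow(tabN), sd = max(1, sd(tabA[[f]])) * 100)
  repN <- robustness_report(tabA, tabN)
  expect_lte(sum(repN$features$robust), 2L)
  # unattainable threshold
  rep1 <- robustness_report(tabA, tabA, threshold = 1.01)
  expect_identical(sum(rep1$features$robust), 0L)
  # unpaired ids are rejected
  tabB <- tabA
  tabB$case_id[1] <- "nope"
  expect_error(robustness_report(tabA, tabB), "pair")
})
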