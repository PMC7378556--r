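test_that("balanced accuracy averages the per-class recalls", {
  m <- rbind(c(30, 20), c(10, 40)) # rows = truth
  expect_equal(balanced_accuracy(m), 0.7)
  expect_equal(balanced_accuracy(rbind(c(50, 0), c(0, 30))), 1)
  # majority-class-only prediction on any imbalance
  expect_equal(balanced_accuracy(rbind(c(70, 0), c(30, 0))), 0.5)
  expect_error(balanced_accuracy(rbind(c(0, 0), c(1, 2))), "present")
})

test_that("ROC-AUC follows the Mann-Whitney formulation with ties", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(5, 10), rep(0:1, 5)), 0.5)
  set.seed(30)
  s <- rnorm(50); y <- rbinom(50, 1, 0.4)
  expect_equal(roc_auc(s, y), as.numeric(suppressMessages(
    pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))))
  # label-independent scores converge to 0.5
  s2 <- rnorm(4000); y2 <- rbinom(4000, 1, 0.5)
  expect_lt(abs(roc_auc(s2, y2) - 0.5), 0.05)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("bootstrap intervals are percentile, seeded and degenerate-safe", {
  expect_equal(bootstrap_ci(rep(0.7, 10), seed = 1), c(0.7, 0.7))
  ci <- bootstrap_ci(rep(c(0, 1), 50), n_boot = 2000, seed = 2)
  expect_lt(ci[1], 0.5); expect_gt(ci[2], 0.5)
  v <- rnorm(20)
  expect_identical(bootstrap_ci(v, seed = 3), bootstrap_ci(v, seed = 3))
  expect_error(bootstrap_ci(numeric(0)), "2 values")
})

test_that("stratified folds balance classes and are deterministic", {
  y <- rep(c("low", "high"), c(40, 25))
  f1 <- stratified_folds(y, k = 5, seed = 4)
  f2 <- stratified_folds(y, k = 5, seed = 4)
  expect_identical(f1, f2)
  for (k in 1:5) {
    expect_identical(sum(y[f1 == k] == "low"), 8L)
    expect_identical(sum(y[f1 == k] == "high"), 5L)
  }
  expect_error(stratified_folds(rep(c("a", "b"), c(3, 40)), k = 5), "k cases")
})

make_toy_table <- function(n_low, n_high, signal = 0, n_feat = 4L,
                           seed = 1L) {
  set.seed(seed)
  grade <- rep(c("low", "high"), c(n_low, n_high))
  x <- matrix(rnorm((n_low + n_high) * n_feat), ncol = n_feat)
  x[, 1] <- x[, 1] + signal * (grade == "high")
  tab <- data.frame(case_id = sprintf("c%03d", seq_along(grade)),
                    grade = grade, scanner_id = "s",
                    normalization = "none", mode = "FBN", bins = 32L,
                    stringsAsFactors = FALSE)
  colnames(x) <- paste0("firstorder.F", seq_len(n_feat))
  cbind(tab, as.data.frame(x))
}

test_that("a perfectly separable feature yields near-perfect accuracy", {
  tab <- make_toy_table(30, 30, signal = 20, seed = 5)
  cv <- cross_validate_models(tab, feature_set_model(1), seed = 6)
  expect_gt(cv$mean_bac, 0.95)
  expect_gt(cv$mean_auc, 0.98)
  expect_identical(dim(cv$bac), c(5L, 5L))
  expect_true(cv$ci95_bac[1] <= cv$mean_bac && cv$mean_bac <= cv$ci95_bac[2])
})

test_that("cross-validation is deterministic given the seed", {
  tab <- make_toy_table(20, 20, signal = 1, seed = 7)
  a <- cross_validate_models(tab, feature_set_model(1), seed = 8)
  b <- cross_validate_models(tab, feature_set_model(1), seed = 8)
  expect_identical(a$bac, b$bac)
  expect_identical(a$auc, b$auc)
  c <- cross_validate_models(tab, feature_set_model(1), seed = 9)
  expect_false(identical(a$bac, c$bac))
})

test_that("label-permuted cohorts score near chance", {
  set.seed(10)
  means <- vapply(1:8, function(r) {
    tab <- make_toy_table(25, 25, signal = 1.5, seed = 100 + r)
    tab$grade <- sample(tab$grade)
    cross_validate_models(tab, feature_set_model(1),
                          seed = 200 + r, n_boot = 50)$mean_bac
  }, numeric(1))
  expect_gt(mean(means), 0.40)
  expect_lt(mean(means), 0.60)
})

test_that("feature-set models select the advertised columns", {
  cfg <- small_config()
  ph <- lapply(1:6, function(s)
    make_brain_phantom(cfg, if (s %% 2) "low" else "high", seed = 60 + s))
  for (i in seq_along(ph)) ph[[i]]$case_id <- sprintf("c%d", i)
  tab <- extract_feature_table(ph, "none", mode = "FBN", bins = 8)
  expect_length(select_model_columns(tab, feature_set_model(1)), 18L)
  expect_length(select_model_columns(tab, feature_set_model(2)), 73L)
  expect_length(select_model_columns(tab, feature_set_model(3)), 91L)
  rep_ <- robustness_report(tab, tab)
  fs4 <- feature_set_model(4, rep_)
  expect_length(select_model_columns(tab, fs4), 91L)
  expect_error(feature_set_model(4), "robustness_report")
  expect_error(feature_set_model(5), "model id")
})

test_that("one-way ANOVA reduces to the squared two-sample t statistic", {
  set.seed(11)
  d <- data.frame(y = c(rnorm(12, 0), rnorm(15, 0.8)),
                  g = rep(c("a", "b"), c(12, 15)))
  at <- anova_tukey(d, "y", "g")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(at$anova$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(at$anova$P, tt$p.value, tolerance = 1e-10)
})

test_that("a strong group shift is flagged by ANOVA and Tukey", {
  set.seed(12)
  d <- data.frame(y = c(rnorm(20), rnorm(20), rnorm(20, 5)),
                  g = rep(c("a", "b", "c"), each = 20))
  at <- anova_tukey(d, "y", "g")
  expect_lt(at$anova$P, 0.001)
  tk <- at$tukey$g
  expect_true(all(tk$p_adj[grepl("c", tk$pair)] < 0.01))
  expect_gt(tk$p_adj[tk$pair == "b-a"], 0.05)
  expect_error(anova_tukey(data.frame(y = 1:5, g = "a"), "y", "g"), "levels")
})

test_that("two-way ANOVA separates the factor effects (type II)", {
  set.seed(13)
  d <- expand.grid(f1 = c("a", "b"), f2 = c("u", "v", "w"), rep = 1:15)
  d$y <- rnorm(nrow(d)) + 2 * (d$f1 == "b")
  at <- anova_tukey(d, "y", c("f1", "f2"))
  expect_lt(at$anova$P[at$anova$factor == "f1"], 1e-6)
  expect_gt(at$anova$P[at$anova$factor == "f2"], 0.01)
})
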