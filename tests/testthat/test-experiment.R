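test_that("feature tables carry one row per case with all 91 features", {
  cfg <- small_config()
  pairs <- generate_paired_cohort(cfg)
  cases <- c(lapply(pairs, `[[`, "A"), lapply(pairs, `[[`, "B"))
  tab <- extract_feature_table(cases, "zscore", mode = "FBN", bins = 8)
  expect_identical(nrow(tab), 2L * cfg$n_paired)
  expect_length(feature_columns(tab), 91L)
  expect_false(anyNA(tab))
  tab2 <- extract_feature_table(cases, "zscore", mode = "FBN", bins = 8)
  expect_identical(tab, tab2)
})

test_that("per-case positive affine maps leave FBN texture columns fixed", {
  cfg <- small_config()
  cases <- generate_graded_cohort(cfg)[1:5]
  t0 <- extract_feature_table(cases, "none", mode = "FBN", bins = 16,
                              which = "texture")
  warped <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    cs$image <- volume_image((0.5 + 0.3 * i) * cs$image$voxels + 11 * i,
                             cs$image$spacing)
    cs
  })
  t1 <- extract_feature_table(warped, "none", mode = "FBN", bins = 16,
                              which = "texture")
  for (f in feature_columns(t1))
    expect_equal(t1[[f]], t0[[f]], tolerance = 1e-12)
})

small_experiment <- function(seed = 77L) {
  experiment_config(
    cohort = small_config(seed = seed),
    methods = c("none", "zscore"),
    modes = "FBN", bins = 32L, models = c(1L, 2L, 4L), seed = seed)
}

test_that("the robustness experiment orders methods as expected", {
  cfg <- small_experiment()
  rob <- run_robustness_experiment(cfg, which = "firstorder")
  # affine scanner effects: normalization shrinks the histogram divergence
  m_jsd <- tapply(rob$jsd$jsd, rob$jsd$method, mean)
  expect_gt(m_jsd[["none"]], m_jsd[["zscore"]])
  counts <- rob$robust_counts
  cn <- counts[counts$method == "none" & counts$class == "firstorder", ]
  cz <- counts[counts$method == "zscore" & counts$class == "firstorder", ]
  expect_gte(cz$n_robust, cn$n_robust)
})

test_that("zero scanner effects make every feature robust and JSD zero", {
  cfg <- small_experiment()
  cfg$cohort$paired_scanner <- zero_scanner_ranges()
  cfg$methods <- "none"
  rob <- run_robustness_experiment(cfg, which = "firstorder")
  expect_true(all(rob$jsd$jsd == 0))
  expect_true(all(rob$robust_counts$n_robust ==
                    rob$robust_counts$n_total))
})

test_that("run_experiment writes a byte-reproducible artifact tree", {
  cfg <- small_experiment()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  res1 <- run_experiment(cfg, d1)
  res2 <- run_experiment(cfg, d2)
  files <- c("config.json", "robustness/jsd.csv",
             "robustness/robust_counts.csv", "robustness/icc_ccc.csv",
             "classification/results.csv", "classification/scores.csv")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)), info = f)
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))), )
  }
  # grid size: methods x modes x bins x models (model 4 may be skipped)
  res <- res1$classification$results
  expect_true(nrow(res) + length(res1$classification$skipped) ==
                2L * 1L * 1L * 3L)
  expect_true(all(res$mean_bac >= 0 & res$mean_bac <= 1))
})

test_that("the CLI front end round-trips a simulate/extract cycle", {
  dir <- withr::local_tempdir()
  cfgf <- file.path(dir, "cohort.json")
  jsonlite::write_json(list(n_paired = 2L, n_low_grade = 2L,
                            n_high_grade = 3L, grid = c(32L, 32L, 32L),
                            seed = 5L),
                       cfgf, auto_unbox = TRUE)
  out <- file.path(dir, "cohort")
  suppressMessages(
    radiomr:::cli_main(c("simulate", "--config", cfgf, "--out", out,
                         "--cohort", "graded")))
  dirs <- list.dirs(out, recursive = FALSE)
  expect_length(dirs, 5L)
  expect_true(file.exists(file.path(dirs[1], "manifest.json")))
  tabf <- file.path(dir, "features.csv")
  radiomr:::cli_main(c("extract", "--cases", out, "--norm", "zscore",
                       "--mode", "fbn", "--bins", "8", "--out", tabf))
  tab <- utils::read.csv(tabf, check.names = FALSE)
  expect_identical(nrow(tab), 5L)
  expect_length(feature_columns(tab), 91L)
})
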