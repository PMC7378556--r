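#' Configuration of a full study run
#'
#' Bundles the cohort configuration with the experimental grid: which
#' normalization methods, discretization modes, nominal bin counts and
#' feature-set models to evaluate, the robustness threshold and the master
#' seed.
#'
#' @param cohort A [cohort_config()].
#' @param methods Subset of `c("none", "zscore", "whitestripe", "nyul")`.
#' @param modes Subset of `c("FBN", "FBS")`.
#' @param bins Subset of [bin_grid()].
#' @param models Subset of `1:4`.
#' @param threshold Robustness dual threshold (default 0.8).
#' @param seed Master seed for fold assignment, classifiers and bootstrap.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              methods = c("none", "zscore", "whitestripe",
                                          "nyul"),
                              modes = c("FBN", "FBS"),
                              bins = bin_grid(),
                              models = 1:4,
                              threshold = 0.8,
                              seed = 42L) {
  methods <- match.arg(methods, several.ok = TRUE)
  modes <- match.arg(modes, several.ok = TRUE)
  bins <- as.integer(bins)
  if (length(bins) == 0L || !all(bins %in% bin_grid()))
    stop("'bins' must be a non-empty subset of bin_grid()")
  models <- as.integer(models)
  if (length(models) == 0L || !all(models %in% 1:4))
    stop("'models' must be a non-empty subset of 1:4")
  structure(list(cohort = cohort, methods = methods, modes = modes,
                 bins = bins, models = models, threshold = threshold,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# deterministic fingerprint of a serialized config (order-sensitive)
config_fingerprint <- function(cfg) {
  s <- jsonlite::toJSON(unclass_deep(cfg), auto_unbox = TRUE, digits = NA)
  b <- utf8ToInt(as.character(s))
  sprintf("%08x", sum(b * (seq_along(b) %% 997)) %% 4294967291)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

# replace a cohort's images by their method-normalized versions
normalize_cases <- function(cases, method, standard = NULL) {
  lapply(cases, function(cs) {
    cs$image <- normalize_image(cs$image, cs$brain, method,
                                standard = standard)$image
    cs
  })
}

#' Paired-cohort robustness experiment
#'
#' Generates the paired two-scanner cohort, then for every requested
#' normalization method: (i) the Jensen-Shannon divergence between the two
#' brain-mask intensity histograms of each pair (256 shared equal-width
#' bins), compared across methods by one-way ANOVA + Tukey; (ii) for every
#' (mode, bins) condition, per-feature ICC/CCC across the pair of
#' acquisitions and the robust-feature counts per feature class.
#'
#' @param cfg An [experiment_config()].
#' @param which Feature families to analyse (default `"all"`).
#' @return List with `jsd` (pair x method table), `jsd_anova`,
#'   `robust_counts` (method x mode x bins x class counts), `reports`
#'   (named list of `robustness_report`s keyed `method/mode/bins`) and the
#'   learned Nyul `standard`.
#' @export
run_robustness_experiment <- function(cfg, which = "all") {
  pairs <- generate_paired_cohort(cfg$cohort)
  std <- NULL
  if ("nyul" %in% cfg$methods) {
    imgs <- c(lapply(pairs, function(p) p$A$image),
              lapply(pairs, function(p) p$B$image))
    brs <- c(lapply(pairs, function(p) p$A$brain),
             lapply(pairs, function(p) p$B$brain))
    std <- learn_standard_histogram(imgs, brs)
  }
  jsd_rows <- list(); counts_rows <- list(); reports <- list()
  for (method in cfg$methods) {
    nA <- normalize_cases(lapply(pairs, `[[`, "A"), method, std)
    nB <- normalize_cases(lapply(pairs, `[[`, "B"), method, std)
    jsd <- vapply(seq_along(pairs), function(i) {
      edges <- shared_histogram_edges(nA[[i]]$image, nB[[i]]$image,
                                      nA[[i]]$brain)
      jensen_shannon_divergence(
        histogram_of(nA[[i]]$image, nA[[i]]$brain, edges),
        histogram_of(nB[[i]]$image, nB[[i]]$brain, edges))
    }, numeric(1))
    jsd_rows[[method]] <- data.frame(
      pair_id = vapply(pairs, function(p) p$A$case_id, character(1)),
      method = method, jsd = jsd, stringsAsFactors = FALSE)
    for (mode in cfg$modes) for (bins in cfg$bins) {
      tab <- extract_feature_table(c(nA, nB), "none", mode = mode,
                                   bins = bins, which = which)
      tab$normalization <- method
      A <- tab[tab$scanner_id == "A", , drop = FALSE]
      B <- tab[tab$scanner_id == "B", , drop = FALSE]
      rep_ <- robustness_report(A, B, threshold = cfg$threshold)
      key <- paste(method, mode, bins, sep = "/")
      reports[[key]] <- rep_
      cr <- rep_$summary
      cr$method <- method; cr$mode <- mode; cr$bins <- bins
      counts_rows[[key]] <- cr
    }
  }
  jsd_df <- do.call(rbind, jsd_rows); rownames(jsd_df) <- NULL
  jsd_anova <- if (length(cfg$methods) >= 2L)
    anova_tukey(jsd_df, "jsd", "method") else NULL
  counts <- do.call(rbind, counts_rows); rownames(counts) <- NULL
  counts <- counts[, c("method", "mode", "bins", "class", "n_robust",
                       "n_total")]
  list(jsd = jsd_df, jsd_anova = jsd_anova, robust_counts = counts,
       reports = reports, standard = std)
}

#' Graded-cohort classification experiment
#'
#' Generates the two-grade multi-scanner cohort and evaluates the
#' classification grid (normalization x mode x bins x feature-set model)
#' with [cross_validate_models()].  The cross-validation seed depends on
#' (mode, bins, model) but not on the normalization method, so conditions
#' whose feature tables are identical produce identical score vectors.
#' Per (mode, model), a two-way ANOVA (normalization x bins) with Tukey
#' post hoc compares the pooled fold-by-family scores when both factors
#' have at least two levels.
#'
#' @param cfg An [experiment_config()].
#' @param robustness Optional output of [run_robustness_experiment()];
#'   required when model 4 is in `cfg$models`.  Conditions whose robust
#'   set is empty are skipped with a recorded warning.
#' @return List with `results` (one row per evaluated condition), `scores`
#'   (long table of fold x family scores), `anova` (per mode/model),
#'   `skipped` (character vector of skipped conditions) and `standard`.
#' @export
run_classification_experiment <- function(cfg, robustness = NULL) {
  if (4L %in% cfg$models && is.null(robustness))
    stop("model 4 requested but no robustness results supplied")
  cohort <- generate_graded_cohort(cfg$cohort)
  std <- NULL
  if ("nyul" %in% cfg$methods)
    std <- learn_standard_histogram(lapply(cohort, `[[`, "image"),
                                    lapply(cohort, `[[`, "brain"))
  res_rows <- list(); score_rows <- list(); skipped <- character()
  for (method in cfg$methods) {
    cases_n <- normalize_cases(cohort, method, std)
    for (mode in cfg$modes) for (bins in cfg$bins) {
      need_texture <- any(cfg$models != 1L)
      tab <- extract_feature_table(cases_n, "none", mode = mode, bins = bins,
                                   which = if (need_texture) "all"
                                           else "firstorder")
      tab$normalization <- method
      for (model in cfg$models) {
        key <- paste(method, mode, bins, "model", model, sep = "/")
        fs <- if (model == 4L) {
          rep_ <- robustness$reports[[paste(method, mode, bins, sep = "/")]]
          if (is.null(rep_) || length(robust_features(rep_)) == 0L) {
            skipped <- c(skipped, key)
            next
          }
          feature_set_model(4L, rep_)
        } else feature_set_model(model)
        cv_seed <- spawn_seed(cfg$seed, match(mode, c("FBN", "FBS")) * 100L +
                                match(bins, bin_grid()), model)
        cv <- cross_validate_models(tab, fs, k = 5L, seed = cv_seed)
        res_rows[[key]] <- data.frame(
          method = method, mode = mode, bins = bins, model = model,
          n_features = cv$n_features,
          mean_bac = cv$mean_bac, bac_lo = cv$ci95_bac[1],
          bac_hi = cv$ci95_bac[2],
          mean_auc = cv$mean_auc, auc_lo = cv$ci95_auc[1],
          auc_hi = cv$ci95_auc[2], stringsAsFactors = FALSE)
        sc <- expand.grid(fold = seq_len(nrow(cv$bac)),
                          family = classifier_families(),
                          stringsAsFactors = FALSE)
        sc$bac <- as.numeric(cv$bac); sc$auc <- as.numeric(cv$auc)
        sc$method <- method; sc$mode <- mode; sc$bins <- bins
        sc$model <- model
        score_rows[[key]] <- sc
      }
    }
  }
  results <- do.call(rbind, res_rows); rownames(results) <- NULL
  scores <- do.call(rbind, score_rows); rownames(scores) <- NULL
  anovas <- list()
  for (mode in cfg$modes) for (model in cfg$models) {
    d <- scores[scores$mode == mode & scores$model == model, , drop = FALSE]
    if (nrow(d) == 0L) next
    facs <- c("method", "bins")[c(length(unique(d$method)) > 1L,
                                  length(unique(d$bins)) > 1L)]
    if (length(facs) >= 1L)
      anovas[[paste(mode, "model", model, sep = "/")]] <-
        anova_tukey(d, "bac", facs)
  }
  list(results = results, scores = scores, anova = anovas,
       skipped = skipped, standard = std)
}

#' Run the full study design and write its artifacts
#'
#' Runs the robustness experiment, then the classification experiment (the
#' robustness reports feed feature-set model 4), and writes all tables to
#' `out_dir` as CSV/JSON together with the verbatim configuration, its
#' fingerprint and the master seed.  Re-running with the same configuration
#' reproduces every output byte for byte.
#'
#' @param cfg An [experiment_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, `list(robustness =, classification =)`.
#' @export
run_experiment <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(unclass_deep(cfg), list(fingerprint = config_fingerprint(cfg)))
  jsonlite::write_json(meta, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  rob <- run_robustness_experiment(cfg)
  rdir <- file.path(out_dir, "robustness")
  dir.create(rdir, showWarnings = FALSE)
  utils::write.csv(rob$jsd, file.path(rdir, "jsd.csv"), row.names = FALSE)
  utils::write.csv(rob$robust_counts, file.path(rdir, "robust_counts.csv"),
                   row.names = FALSE)
  icc_ccc <- do.call(rbind, lapply(names(rob$reports), function(k) {
    d <- rob$reports[[k]]$features
    parts <- strsplit(k, "/", fixed = TRUE)[[1]]
    cbind(data.frame(method = parts[1], mode = parts[2],
                     bins = as.integer(parts[3]), stringsAsFactors = FALSE),
          d)
  }))
  utils::write.csv(icc_ccc, file.path(rdir, "icc_ccc.csv"), row.names = FALSE)
  if (!is.null(rob$jsd_anova))
    jsonlite::write_json(unclass_deep(unclass(rob$jsd_anova)),
                         file.path(rdir, "jsd_anova.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  cls <- run_classification_experiment(cfg, robustness = rob)
  cdir <- file.path(out_dir, "classification")
  dir.create(cdir, showWarnings = FALSE)
  utils::write.csv(cls$results, file.path(cdir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(cls$scores, file.path(cdir, "scores.csv"),
                   row.names = FALSE)
  jsonlite::write_json(lapply(cls$anova, function(a) unclass_deep(unclass(a))),
                       file.path(cdir, "anova.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (length(cls$skipped))
    writeLines(cls$skipped, file.path(cdir, "skipped.txt"))
  invisible(list(robustness = rob, classification = cls))
}
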