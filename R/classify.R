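#' Tumour-grade classification harness
#'
#' Five classifier families (logistic regression, naive Bayes, support
#' vector machine, random forest, multi-layer perceptron) evaluated with
#' stratified k-fold cross-validation.  Within each fold, feature columns
#' are standardized (mean 0 / sd 1) using training rows only, then every
#' family is trained at its fixed default configuration and scored on the
#' held-out fold by balanced accuracy and ROC-AUC.  Bootstrap percentile
#' intervals summarize the pooled fold-by-model scores.
#'
#' @name classification_doc
NULL

#' Balanced accuracy from a 2x2 confusion matrix
#'
#' `(sensitivity + specificity) / 2`: the mean of the per-true-class recall,
#' with truth in rows and predictions in columns.
#'
#' @param confusion 2x2 count matrix, rows = truth, columns = prediction,
#'   classes in the same order on both axes.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(confusion) {
  m <- as.matrix(confusion)
  if (!all(dim(m) == 2L)) stop("'confusion' must be a 2x2 count matrix")
  rs <- rowSums(m)
  if (any(rs == 0)) stop("both true classes must be present")
  mean(diag(m) / rs)
}

#' ROC-AUC by the Mann-Whitney formulation
#'
#' The probability that a random positive case receives a higher score than
#' a random negative one, with ties counted 1/2.
#'
#' @param scores Numeric prediction scores.
#' @param labels Logical/0-1/factor labels; `TRUE` (or the second factor
#'   level) is the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  pos <- as.logical(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores) # midranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap percentile interval of the mean
#'
#' @param values Numeric vector (>= 2 values).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed (deterministic interval).
#' @return `c(lower, upper)`.
#' @export
bootstrap_ci <- function(values, n_boot = 1000L, level = 0.95, seed = 1L) {
  if (length(values) < 2L) stop("need at least 2 values")
  with_local_seed(seed, {
    means <- vapply(seq_len(n_boot), function(i)
      mean(sample(values, replace = TRUE)), numeric(1))
    as.numeric(stats::quantile(means, c((1 - level) / 2, (1 + level) / 2),
                               type = 7, names = FALSE))
  })
}

#' Stratified fold assignment
#'
#' Shuffles each class separately (seeded) and deals its members to folds
#' round-robin, so fold class proportions track the cohort's.
#'
#' @param labels Vector of class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id per case (1..k).
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.factor(labels)
  if (any(table(labels) < k))
    stop("every class needs at least k cases for stratified k-fold CV")
  fold <- integer(length(labels))
  with_local_seed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' The five classifier families
#' @return Character vector of family names.
#' @export
classifier_families <- function()
  c("logistic", "naive_bayes", "svm", "random_forest", "mlp")

#' Fixed default configuration of each classifier family
#'
#' Recorded in run manifests; these are the settings used by
#' [cross_validate_models()].
#'
#' @return Named list of parameter lists.
#' @export
classifier_defaults <- function() {
  list(logistic = list(model = "glm", family = "binomial"),
       naive_bayes = list(model = "e1071::naiveBayes", laplace = 0),
       svm = list(model = "e1071::svm", kernel = "radial", cost = 1,
                  probability = TRUE),
       random_forest = list(model = "randomForest", ntree = 500),
       mlp = list(model = "nnet", size = 8, decay = 0.01, maxit = 200))
}

# Each fitter returns a function(newdata) -> probability of the positive
# class.  'x' is a standardized numeric matrix, 'y' a 2-level factor whose
# second level is positive.
fit_classifier <- function(family, x, y, seed) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  df$.y <- y
  pos <- levels(y)[2]
  keep <- apply(x, 2, function(col) stats::sd(col) > 0)
  with_local_seed(seed, {
    switch(family,
      logistic = {
        fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                           family = stats::binomial()))
        function(nx) {
          nd <- as.data.frame(nx); names(nd) <- paste0("f", seq_len(ncol(nx)))
          suppressWarnings(as.numeric(stats::predict(fit, nd,
                                                     type = "response")))
        }
      },
      naive_bayes = {
        # drop zero-variance columns (degenerate Gaussian densities)
        cols <- which(keep)
        if (length(cols) == 0L) cols <- 1L
        fit <- e1071::naiveBayes(x[, cols, drop = FALSE], y)
        function(nx) as.numeric(stats::predict(fit, nx[, cols, drop = FALSE],
                                               type = "raw")[, pos])
      },
      svm = {
        fit <- e1071::svm(x, y, probability = TRUE, kernel = "radial")
        function(nx) {
          pr <- stats::predict(fit, nx, probability = TRUE)
          as.numeric(attr(pr, "probabilities")[, pos])
        }
      },
      random_forest = {
        fit <- randomForest::randomForest(x, y, ntree = 500)
        function(nx) as.numeric(stats::predict(fit, nx, type = "prob")[, pos])
      },
      mlp = {
        fit <- nnet::nnet(x, stats::model.matrix(~ y - 1)[, 2, drop = FALSE],
                          size = 8, decay = 0.01, maxit = 200,
                          trace = FALSE, entropy = TRUE)
        function(nx) as.numeric(stats::predict(fit, nx))
      },
      stop("unknown classifier family '", family, "'"))
  })
}

#' Feature-set model definitions
#'
#' Model 1: first-order features only; model 2: textural features only;
#' model 3: both; model 4: the robust subset from a paired-acquisition
#' [robustness_report()].
#'
#' @param id 1, 2, 3 or 4.
#' @param report A `robustness_report`, required for model 4 (with at least
#'   one robust feature).
#' @return An object of class `feature_set_model`.
#' @export
feature_set_model <- function(id, report = NULL) {
  id <- as.integer(id)
  if (!id %in% 1:4) stop("model id must be 1, 2, 3 or 4")
  robust <- NULL
  if (id == 4L) {
    if (is.null(report)) stop("model 4 requires a robustness_report")
    robust <- robust_features(report)
    if (length(robust) == 0L)
      stop("model 4 requires at least one robust feature")
  }
  structure(list(id = id, robust = robust), class = "feature_set_model")
}

select_model_columns <- function(table, fs) {
  cols <- switch(fs$id,
                 feature_columns(table, "firstorder"),
                 feature_columns(table, "texture"),
                 feature_columns(table, "all"),
                 intersect(fs$robust, feature_columns(table, "all")))
  if (length(cols) == 0L) stop("feature-set model selects no columns")
  cols
}

#' Cross-validated evaluation of the five classifier families
#'
#' Stratified k-fold cross-validation of the low/high grade task.  Feature
#' standardization (column-wise mean/sd) is fit on the training rows of
#' each fold only and applied to the held-out rows — test rows never
#' influence the fold's parameters.  Per fold and family, balanced accuracy
#' (probability threshold 0.5) and ROC-AUC are recorded, giving `k * 5`
#' scores per metric; bootstrap percentile intervals summarize their pooled
#' mean.  Deterministic given `seed`.
#'
#' @param table Feature table from [extract_feature_table()] with a
#'   `grade` column in `{"low", "high"}`.
#' @param fs A [feature_set_model()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed (fold assignment, classifier RNG, bootstrap).
#' @param n_boot Bootstrap iterations for the CIs (default 1000).
#' @return An object of class `classification_result`: score matrices
#'   `bac` and `auc` (folds x families), means, `ci95` intervals, the fold
#'   assignment and condition metadata.
#' @export
cross_validate_models <- function(table, fs, k = 5L, seed = 1L,
                                  n_boot = 1000L) {
  cols <- select_model_columns(table, fs)
  y <- factor(table$grade, levels = c("low", "high"))
  if (any(is.na(y))) stop("'grade' must be 'low' or 'high'")
  if (any(table(y) < k)) stop("need at least k cases per class")
  x_all <- as.matrix(table[, cols, drop = FALSE])
  fold <- stratified_folds(y, k = k, seed = seed)
  fams <- classifier_families()
  bac <- matrix(NA_real_, k, length(fams), dimnames = list(NULL, fams))
  auc <- bac
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L)
      stop("stratification failure: a class is missing from fold ", f)
    mu <- colMeans(x_all[tr, , drop = FALSE])
    sdv <- apply(x_all[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv <= 0] <- 1
    xs_tr <- sweep(sweep(x_all[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    xs_te <- sweep(sweep(x_all[te, , drop = FALSE], 2, mu), 2, sdv, "/")
    for (m in seq_along(fams)) {
      pred <- fit_classifier(fams[m], xs_tr, y[tr],
                             seed = spawn_seed(seed, f, 10L + m))
      p <- pred(xs_te)
      cls <- factor(ifelse(p >= 0.5, "high", "low"), levels = c("low", "high"))
      conf <- table(truth = y[te], pred = cls)
      bac[f, m] <- balanced_accuracy(conf)
      auc[f, m] <- roc_auc(p, y[te] == "high")
    }
  }
  scores_bac <- as.numeric(bac); scores_auc <- as.numeric(auc)
  structure(list(bac = bac, auc = auc,
                 mean_bac = mean(scores_bac), mean_auc = mean(scores_auc),
                 ci95_bac = bootstrap_ci(scores_bac, n_boot = n_boot,
                                         seed = spawn_seed(seed, 999L, 1L)),
                 ci95_auc = bootstrap_ci(scores_auc, n_boot = n_boot,
                                         seed = spawn_seed(seed, 999L, 2L)),
                 fold = fold, model_id = fs$id, n_features = length(cols),
                 metadata = list(normalization = table$normalization[1],
                                 mode = table$mode[1], bins = table$bins[1]),
                 classifier_config = classifier_defaults()),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(paste0("<classification_result> model %d: BAC %.3f ",
                     "(95%% CI %.3f-%.3f), AUC %.3f (95%% CI %.3f-%.3f)\n"),
              x$model_id, x$mean_bac, x$ci95_bac[1], x$ci95_bac[2],
              x$mean_auc, x$ci95_auc[1], x$ci95_auc[2]))
  invisible(x)
}
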