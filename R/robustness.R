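#' Paired-acquisition robustness statistics
#'
#' Tools for the test-retest analysis: intensity histograms and their
#' Jensen-Shannon divergence, the two-way random-effects absolute-agreement
#' single-measurement intra-class correlation ICC(2,1), Lin's concordance
#' correlation coefficient, and the dual-threshold robust-feature rule
#' (a feature is robust iff both ICC and CCC exceed the threshold).
#'
#' @name robustness_doc
NULL

#' Probability histogram of in-mask intensities
#'
#' @param img A `volume_image`.
#' @param mask `binary_mask` on the same grid.
#' @param edges Increasing bin edges; values outside are clipped into the
#'   end bins.
#' @return An `intensity_histogram`: `list(edges =, probabilities =)`.
#' @export
histogram_of <- function(img, mask, edges) {
  vals <- mask_values(img, mask)
  if (length(vals) == 0L) stop("empty mask")
  edges <- as.numeric(edges)
  if (length(edges) < 2L || any(diff(edges) <= 0))
    stop("'edges' must be strictly increasing with at least 2 values")
  nb <- length(edges) - 1L
  bin <- findInterval(vals, edges, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), nb) # clip to end bins
  structure(list(edges = edges,
                 probabilities = tabulate(bin, nbins = nb) / length(vals)),
            class = "intensity_histogram")
}

#' Shared histogram support for a pair of acquisitions
#'
#' Equal-width bins spanning the union of the two in-mask intensity ranges.
#'
#' @param imgA,imgB `volume_image`s.
#' @param maskA,maskB Matching masks (`maskB` defaults to `maskA`).
#' @param n_bins Number of bins (default 256).
#' @return Numeric vector of `n_bins + 1` edges.
#' @export
shared_histogram_edges <- function(imgA, imgB, maskA, maskB = maskA,
                                   n_bins = 256L) {
  rA <- range(mask_values(imgA, maskA))
  rB <- range(mask_values(imgB, maskB))
  lo <- min(rA[1], rB[1]); hi <- max(rA[2], rB[2])
  if (hi <= lo) hi <- lo + 1e-6
  seq(lo, hi, length.out = n_bins + 1L)
}

#' Jensen-Shannon divergence between two histograms
#'
#' `JSD = KL(p||m)/2 + KL(q||m)/2` with `m = (p+q)/2`, base-2 logarithm, so
#' the value lies in `[0, 1]`; `0 log 0 := 0`.
#'
#' @param p,q `intensity_histogram`s on identical edges (or bare
#'   probability vectors of equal length).
#' @return The divergence in `[0, 1]`.
#' @export
jensen_shannon_divergence <- function(p, q) {
  if (inherits(p, "intensity_histogram") || inherits(q, "intensity_histogram")) {
    if (!inherits(p, "intensity_histogram") ||
        !inherits(q, "intensity_histogram") ||
        !isTRUE(all.equal(p$edges, q$edges)))
      stop("histograms must share identical bin edges")
    p <- p$probabilities; q <- q$probabilities
  }
  if (length(p) != length(q)) stop("probability vectors differ in length")
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * (log2(a) - log2(b)), 0))
  kl(p, m) / 2 + kl(q, m) / 2
}

#' Intra-class correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC from
#' the standard ANOVA mean squares: with `n` subjects and `k` raters,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param pairs Numeric matrix or data.frame, subjects x raters (>= 3
#'   subjects).
#' @return The ICC; exactly 1 when the table has zero total variance
#'   (perfect, degenerate agreement).
#' @export
icc <- function(pairs) {
  x <- as.matrix(pairs)
  n <- nrow(x); k <- ncol(x)
  if (n < 3L) stop("ICC needs at least 3 subjects")
  if (k < 2L) stop("ICC needs at least 2 raters")
  grand <- mean(x)
  sst <- sum((x - grand)^2)
  if (sst <= 0) return(1)
  ssr <- k * sum((rowMeans(x) - grand)^2)
  ssc <- n * sum((colMeans(x) - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 s_xy / (s_x^2 + s_y^2 + (mu_x - mu_y)^2)` with population
#' (divide by n) moments.
#'
#' @param pairs Numeric matrix or data.frame with two columns (>= 2 rows).
#' @return The CCC; exactly 1 when both columns are constant and equal.
#' @export
ccc <- function(pairs) {
  x <- as.matrix(pairs)
  if (nrow(x) < 2L || ncol(x) != 2L)
    stop("CCC needs an n x 2 table with n >= 2")
  a <- x[, 1]; b <- x[, 2]
  mua <- mean(a); mub <- mean(b)
  sa2 <- mean((a - mua)^2); sb2 <- mean((b - mub)^2)
  sab <- mean((a - mua) * (b - mub))
  den <- sa2 + sb2 + (mua - mub)^2
  if (den <= 0) return(1)
  2 * sab / den
}

#' Per-feature robustness across two paired feature tables
#'
#' Computes ICC(2,1) and CCC for every feature column across the two
#' acquisitions (rows paired by `case_id`) and flags a feature robust iff
#' both statistics are strictly greater than `threshold`.
#'
#' @param tableA,tableB Feature tables from [extract_feature_table()] with
#'   identical case ids and feature columns.
#' @param threshold Dual threshold (default 0.8, strict inequality).
#' @return An object of class `robustness_report`: `data.frame` `features`
#'   (feature, class, icc, ccc, robust), `summary` counts per class, and
#'   the threshold.
#' @export
robustness_report <- function(tableA, tableB, threshold = 0.8) {
  fc <- feature_columns(tableA)
  if (!identical(fc, feature_columns(tableB)))
    stop("the two tables have different feature columns")
  if (anyDuplicated(tableA$case_id) || anyDuplicated(tableB$case_id))
    stop("duplicated case ids")
  if (!setequal(tableA$case_id, tableB$case_id))
    stop("case ids of the two tables do not pair up")
  B <- tableB[match(tableA$case_id, tableB$case_id), , drop = FALSE]
  stats_df <- do.call(rbind, lapply(fc, function(f) {
    m <- cbind(tableA[[f]], B[[f]])
    data.frame(feature = f, class = feature_class_of(f),
               icc = icc(m), ccc = ccc(m), stringsAsFactors = FALSE)
  }))
  stats_df$robust <- stats_df$icc > threshold & stats_df$ccc > threshold
  summary <- do.call(rbind, lapply(split(stats_df, stats_df$class), function(d)
    data.frame(class = d$class[1], n_robust = sum(d$robust),
               n_total = nrow(d), stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  structure(list(features = stats_df, summary = summary,
                 threshold = threshold),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("<robustness_report> threshold", x$threshold, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Names of the robust features in a report
#' @param report A `robustness_report`.
#' @return Character vector (possibly empty).
#' @export
robust_features <- function(report) {
  report$features$feature[report$features$robust]
}
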