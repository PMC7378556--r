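#' Extract a feature table from a cohort of cases
#'
#' Runs one experimental condition end-to-end: normalizes each case's image
#' (learning the Nyul standard histogram from the cohort itself unless one
#' is supplied), discretizes the tumour ROI, and extracts the requested
#' features.  For FBS the cohort mean ROI range of this condition is
#' computed first and reused for every case, so the nominal bin count is
#' comparable across conditions.
#'
#' @param cases List of `phantom_case`s (or any objects with `image`,
#'   `brain`, `tumour`, `case_id`, `grade`, `scanner_id` fields).
#' @param norm_method `"none"`, `"zscore"`, `"whitestripe"` or `"nyul"`.
#' @param mode `"FBN"` or `"FBS"`.
#' @param bins Nominal bin count.
#' @param standard Optional `standard_histogram` for `"nyul"`.
#' @param mean_range Optional precomputed cohort mean ROI range (FBS).
#' @param which `"all"` (default), `"firstorder"` or `"texture"`: which
#'   feature families to compute.
#' @return A `data.frame` with one row per case: metadata columns
#'   (`case_id`, `grade`, `scanner_id`, `normalization`, `mode`, `bins`)
#'   followed by the feature columns (91 for `"all"`).
#' @export
extract_feature_table <- function(cases, norm_method = "none",
                                  mode = c("FBN", "FBS"), bins = 32L,
                                  standard = NULL, mean_range = NULL,
                                  which = c("all", "firstorder", "texture")) {
  mode <- match.arg(mode)
  which <- match.arg(which)
  if (length(cases) == 0L) stop("empty cohort")
  if (norm_method == "nyul" && is.null(standard))
    standard <- learn_standard_histogram(lapply(cases, `[[`, "image"),
                                         lapply(cases, `[[`, "brain"))
  roi_vals <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    res <- tryCatch(normalize_image(cs$image, cs$brain, norm_method,
                                    standard = standard),
                    error = function(e)
                      stop("normalization failed for case '", cs$case_id,
                           "': ", conditionMessage(e), call. = FALSE))
    mask_values(res$image, cs$tumour)
  })
  if (mode == "FBS" && is.null(mean_range))
    mean_range <- mean_roi_range(roi_vals)
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    vals <- roi_vals[[i]]
    feats <- tryCatch({
      disc <- discretize_roi(vals, mode = mode, bins = bins,
                             mean_range = mean_range)
      vv <- prod(cs$image$spacing)
      fo <- if (which != "texture")
        first_order_features(vals, voxel_volume = vv, disc = disc)
      tx <- if (which != "firstorder")
        texture_features(texture_matrices(disc, cs$tumour))
      c(fo, tx)
    }, error = function(e)
      stop("feature extraction failed for case '", cs$case_id, "': ",
           conditionMessage(e), call. = FALSE))
    cbind(data.frame(case_id = cs$case_id, grade = cs$grade,
                     scanner_id = cs$scanner_id,
                     normalization = norm_method, mode = mode,
                     bins = as.integer(bins),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(feats), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mean_range") <- mean_range
  out
}

#' Names of the feature columns of a feature table
#' @param table A feature table from [extract_feature_table()].
#' @param class `"all"`, `"firstorder"` or `"texture"`.
#' @return Character vector of column names.
#' @export
feature_columns <- function(table, class = c("all", "firstorder", "texture")) {
  class <- match.arg(class)
  nm <- names(table)
  pref <- switch(class,
                 all = "^(firstorder|glcm|glrlm|glszm|ngtdm|gldm)\\.",
                 firstorder = "^firstorder\\.",
                 texture = "^(glcm|glrlm|glszm|ngtdm|gldm)\\.")
  nm[grepl(pref, nm)]
}

feature_class_of <- function(names) {
  cls <- sub("\\..*$", "", names)
  ifelse(cls == "firstorder", "firstorder", "texture")
}
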