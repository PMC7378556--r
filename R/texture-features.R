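#' Textural (second-order) features
#'
#' 73 features over the five texture matrix families: 22 GLCM, 16 GLRLM,
#' 16 GLSZM, 5 NGTDM, 14 GLDM.  Direction-dependent families (GLCM, GLRLM)
#' are computed per direction and averaged over the 13 unique 3D
#' directions.  Degenerate inputs fall back to documented constants so the
#' feature vector is always finite: correlation-type features of a
#' zero-variance matrix return their limiting value, entropies of a
#' one-cell matrix return 0, and NGTDM Coarseness with a zero denominator
#' returns the sentinel `1e6`.
#'
#' @name texture_features_doc
NULL

xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

glcm_features_one <- function(P, ng) {
  nz <- which(P > 0, arr.ind = TRUE)
  p <- P[nz]
  i <- nz[, 1]; j <- nz[, 2]
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(seq_len(ng) * px); mu_y <- sum(seq_len(ng) * py)
  var_x <- sum((seq_len(ng) - mu_x)^2 * px)
  var_y <- sum((seq_len(ng) - mu_y)^2 * py)
  # sum and difference marginals
  ks <- i + j; kd <- abs(i - j)
  psum <- rowsum(p, ks); ps <- as.numeric(psum); ksv <- as.numeric(rownames(psum))
  pdif <- rowsum(p, kd); pd <- as.numeric(pdif); kdv <- as.numeric(rownames(pdif))
  da <- sum(kdv * pd)
  hxy <- -sum(xlog2(p))
  hxy1 <- -sum(p * ifelse(px[i] * py[j] > 0, log2(px[i] * py[j]), 0))
  pxy_out <- outer(px, py)
  hxy2 <- -sum(xlog2(pxy_out))
  hx <- -sum(xlog2(px)); hy <- -sum(xlog2(py))
  corr <- if (var_x > 0 && var_y > 0)
    (sum(i * j * p) - mu_x * mu_y) / sqrt(var_x * var_y) else 1
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  offd <- kd > 0
  c(Autocorrelation = sum(i * j * p),
    JointAverage = mu_x,
    ClusterProminence = sum((i + j - mu_x - mu_y)^4 * p),
    ClusterShade = sum((i + j - mu_x - mu_y)^3 * p),
    ClusterTendency = sum((i + j - mu_x - mu_y)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(xlog2(pd)),
    DifferenceVariance = sum((kdv - da)^2 * pd),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j) / ng)^2)),
    Id = sum(p / (1 + kd)),
    Idn = sum(p / (1 + kd / ng)),
    InverseVariance = if (any(offd)) sum(p[offd] / (i[offd] - j[offd])^2) else 0,
    MaximumProbability = max(p),
    SumEntropy = -sum(xlog2(ps)),
    SumSquares = var_x)
}

#' GLCM features averaged over directions
#' @param g Output of [glcm_matrix()].
#' @return Named numeric vector of 22 features (prefix `glcm.`).
#' @export
glcm_features <- function(g) {
  per_dir <- vapply(g$P, glcm_features_one, numeric(22), ng = g$n_levels)
  out <- rowMeans(per_dir)
  names(out) <- paste0("glcm.", names(out))
  out
}

rl_features_one <- function(R, kind = c("run", "zone")) {
  kind <- match.arg(kind)
  nz <- which(R > 0, arr.ind = TRUE)
  cnt <- R[nz]
  i <- nz[, 1]; j <- nz[, 2]
  nr <- sum(cnt)
  np <- sum(cnt * j) # voxels covered
  p <- cnt / nr
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  gl_marg <- rowsum(cnt, i)[, 1]
  sz_marg <- rowsum(cnt, j)[, 1]
  nm <- if (kind == "run")
    c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage",
      "GrayLevelVariance", "RunVariance", "RunEntropy",
      "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
      "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
      "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  else
    c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "ZonePercentage",
      "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
      "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
      "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
      "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  vals <- c(sum(cnt / j^2) / nr,
            sum(cnt * j^2) / nr,
            sum(gl_marg^2) / nr,
            sum(gl_marg^2) / nr^2,
            sum(sz_marg^2) / nr,
            sum(sz_marg^2) / nr^2,
            nr / np,
            sum((i - mu_i)^2 * p),
            sum((j - mu_j)^2 * p),
            -sum(xlog2(p)),
            sum(cnt / i^2) / nr,
            sum(cnt * i^2) / nr,
            sum(cnt / (i^2 * j^2)) / nr,
            sum(cnt * i^2 / j^2) / nr,
            sum(cnt * j^2 / i^2) / nr,
            sum(cnt * i^2 * j^2) / nr)
  names(vals) <- nm
  vals
}

#' GLRLM features averaged over directions
#' @param g Output of [glrlm_matrix()].
#' @return Named numeric vector of 16 features (prefix `glrlm.`).
#' @export
glrlm_features <- function(g) {
  per_dir <- vapply(g$R, rl_features_one, numeric(16), kind = "run")
  out <- rowMeans(per_dir)
  names(out) <- paste0("glrlm.", names(out))
  out
}

#' GLSZM features
#' @param g Output of [glszm_matrix()].
#' @return Named numeric vector of 16 features (prefix `glszm.`).
#' @export
glszm_features <- function(g) {
  out <- rl_features_one(g$S, kind = "zone")
  names(out) <- paste0("glszm.", names(out))
  out
}

#' NGTDM features
#' @param g Output of [ngtdm_matrix()].
#' @return Named numeric vector of 5 features (prefix `ngtdm.`).
#' @export
ngtdm_features <- function(g) {
  lev <- which(g$p > 0)
  p <- g$p[lev]; s <- g$s[lev]
  nvp <- g$n_valid
  ngp <- length(lev)
  coarse_den <- sum(p * s)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (ngp > 1) {
    sum(outer(p, p) * outer(lev, lev, `-`)^2) / (ngp * (ngp - 1)) *
      sum(s) / nvp
  } else 0
  bus_den <- sum(abs(outer(lev * p, lev * p, `-`)))
  busyness <- if (bus_den > 0) sum(p * s) / bus_den else 0
  # complexity and strength over pairs of present levels
  complexity <- 0; strength_num <- 0
  if (ngp > 1) {
    pi_ <- outer(p, rep(1, ngp)); pj_ <- outer(rep(1, ngp), p)
    si_ <- outer(s, rep(1, ngp)); sj_ <- outer(rep(1, ngp), s)
    dij <- abs(outer(lev, lev, `-`))
    complexity <- sum(dij * (pi_ * si_ + pj_ * sj_) / (pi_ + pj_)) / nvp
    strength_num <- sum((pi_ + pj_) * outer(lev, lev, `-`)^2)
  }
  strength <- if (sum(s) > 0) strength_num / sum(s) else 0
  c(ngtdm.Coarseness = coarseness,
    ngtdm.Contrast = contrast,
    ngtdm.Busyness = busyness,
    ngtdm.Complexity = complexity,
    ngtdm.Strength = strength)
}

#' GLDM features
#' @param g Output of [gldm_matrix()].
#' @return Named numeric vector of 14 features (prefix `gldm.`).
#' @export
gldm_features <- function(g) {
  D <- g$D
  nz <- which(D > 0, arr.ind = TRUE)
  cnt <- D[nz]
  i <- nz[, 1]; j <- nz[, 2]
  nzv <- sum(cnt)
  p <- cnt / nzv
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  gl_marg <- rowsum(cnt, i)[, 1]
  dp_marg <- rowsum(cnt, j)[, 1]
  c(gldm.SmallDependenceEmphasis = sum(cnt / j^2) / nzv,
    gldm.LargeDependenceEmphasis = sum(cnt * j^2) / nzv,
    gldm.GrayLevelNonUniformity = sum(gl_marg^2) / nzv,
    gldm.DependenceNonUniformity = sum(dp_marg^2) / nzv,
    gldm.DependenceNonUniformityNormalized = sum(dp_marg^2) / nzv^2,
    gldm.GrayLevelVariance = sum((i - mu_i)^2 * p),
    gldm.DependenceVariance = sum((j - mu_j)^2 * p),
    gldm.DependenceEntropy = -sum(xlog2(p)),
    gldm.LowGrayLevelEmphasis = sum(cnt / i^2) / nzv,
    gldm.HighGrayLevelEmphasis = sum(cnt * i^2) / nzv,
    gldm.SmallDependenceLowGrayLevelEmphasis = sum(cnt / (i^2 * j^2)) / nzv,
    gldm.SmallDependenceHighGrayLevelEmphasis = sum(cnt * i^2 / j^2) / nzv,
    gldm.LargeDependenceLowGrayLevelEmphasis = sum(cnt * j^2 / i^2) / nzv,
    gldm.LargeDependenceHighGrayLevelEmphasis = sum(cnt * i^2 * j^2) / nzv)
}

#' The 73 textural features of a discretized ROI
#'
#' @param mats A `texture_matrices` object (or a `discretized_roi`, in
#'   which case `mask` must be given and the matrices are built first).
#' @param mask ROI `binary_mask` when `mats` is a `discretized_roi`.
#' @return Named numeric vector of 73 finite values.
#' @export
texture_features <- function(mats, mask = NULL) {
  if (inherits(mats, "discretized_roi")) {
    if (is.null(mask)) stop("a mask is required with a discretized_roi")
    mats <- texture_matrices(mats, mask)
  }
  out <- c(glcm_features(mats$glcm),
           glrlm_features(mats$glrlm),
           glszm_features(mats$glszm),
           ngtdm_features(mats$ngtdm),
           gldm_features(mats$gldm))
  if (length(out) != 73L || any(!is.finite(out)))
    stop("internal error: texture feature vector is not 73 finite values")
  out
}
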