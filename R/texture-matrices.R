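#' Texture matrices from a discretized ROI
#'
#' Builders for the five 3D texture matrix families at Chebyshev distance 1:
#' grey-level co-occurrence (GLCM, symmetric, per direction), grey-level run
#' length (GLRLM, per direction), grey-level size zone (GLSZM, 26-connected
#' zones), neighbourhood grey tone difference (NGTDM) and grey-level
#' dependence (GLDM).  Direction-dependent matrices use the 13 unique 3D
#' directions; neighbourhoods are the 26 surrounding voxels; everything is
#' restricted to in-mask voxels.
#'
#' @name texture_matrices_doc
NULL

# the 13 unique 3D directions at Chebyshev distance 1
offsets13 <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

# out[v] = a[v + d], NA where v + d leaves the grid
shift3 <- function(a, d) {
  n <- dim(a)
  out <- array(NA_integer_, dim = n)
  lo <- pmax(1L, 1L - d); hi <- pmin(n, n - d)
  if (any(lo > hi)) return(out)
  dst <- lapply(1:3, function(k) seq.int(lo[k], hi[k]))
  src <- lapply(1:3, function(k) dst[[k]] + d[k])
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Place discretized levels on their 3D grid
#'
#' @param disc A `discretized_roi` whose `levels` follow the column-major
#'   order of the mask's foreground voxels.
#' @param mask The ROI `binary_mask`.
#' @param crop Crop to the mask bounding box (default TRUE).
#' @return 3D integer array of levels, `NA` outside the mask.
#' @export
level_grid <- function(disc, mask, crop = TRUE) {
  if (sum(mask$voxels) != length(disc$levels))
    stop("mask voxel count does not match the discretized ROI")
  arr <- array(NA_integer_, dim = dim(mask$voxels))
  arr[mask$voxels == 1L] <- disc$levels
  if (crop) {
    ind <- which(mask$voxels == 1L, arr.ind = TRUE)
    bb <- apply(ind, 2, range)
    arr <- arr[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2], bb[1, 3]:bb[2, 3],
               drop = FALSE]
  }
  arr
}

as_level_grid <- function(levels, mask = NULL) {
  if (inherits(levels, "discretized_roi")) {
    if (is.null(mask)) stop("a mask is required with a discretized_roi")
    level_grid(levels, mask)
  } else {
    arr <- as.array(levels)
    if (length(dim(arr)) != 3L) stop("'levels' must be 3D")
    arr
  }
}

#' Grey-level co-occurrence matrices (GLCM)
#'
#' Symmetric co-occurrence counts for each of the 13 unique 3D directions at
#' the given Chebyshev distance; pairs are restricted to in-mask voxels.
#'
#' @param levels A `discretized_roi` or a 3D integer array with `NA`
#'   outside the ROI.
#' @param mask ROI `binary_mask` (required with a `discretized_roi`).
#' @param distance Chebyshev distance (default 1).
#' @param n_levels Number of grey levels; defaults to the maximum observed.
#' @return List with `P` (per-direction probability matrices), `counts`
#'   (symmetric count matrices) and `n_levels`.  Directions with no valid
#'   pair are dropped; an error is raised if none remains.
#' @export
glcm_matrix <- function(levels, mask = NULL, distance = 1L, n_levels = NULL) {
  lv <- as_level_grid(levels, mask)
  if (all(is.na(lv))) stop("empty mask; GLCM undefined")
  ng <- if (is.null(n_levels)) max(lv, na.rm = TRUE) else as.integer(n_levels)
  offs <- offsets13() * as.integer(distance)
  counts <- list(); P <- list()
  for (k in seq_len(nrow(offs))) {
    nb <- shift3(lv, offs[k, ])
    ok <- !is.na(lv) & !is.na(nb)
    if (!any(ok)) next
    a <- lv[ok]; b <- nb[ok]
    tab <- tabulate(a + (b - 1L) * ng, nbins = ng * ng) +
      tabulate(b + (a - 1L) * ng, nbins = ng * ng)
    m <- matrix(tab, ng, ng)
    counts[[length(counts) + 1L]] <- m
    P[[length(P) + 1L]] <- m / sum(m)
  }
  if (length(counts) == 0L)
    stop("no valid voxel pair in any direction; GLCM undefined")
  list(P = P, counts = counts, n_levels = ng)
}

#' Grey-level run length matrices (GLRLM)
#'
#' Run-length counts along the 13 unique 3D directions; runs are truncated
#' at the mask boundary (and at out-of-mask holes).
#'
#' @inheritParams glcm_matrix
#' @return List with `R` (per-direction count matrices, levels x run
#'   length) and `n_levels`.
#' @export
glrlm_matrix <- function(levels, mask = NULL, n_levels = NULL) {
  lv <- as_level_grid(levels, mask)
  if (all(is.na(lv))) stop("empty mask; GLRLM undefined")
  ng <- if (is.null(n_levels)) max(lv, na.rm = TRUE) else as.integer(n_levels)
  d <- dim(lv)
  idx <- which(!is.na(lv))
  ai <- arrayInd(idx, d)
  val <- lv[idx]
  maxlen <- max(d)
  offs <- offsets13()
  out <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    dk <- offs[k, ]
    # position along the line: first nonzero component advances by 1 a step
    s <- if (dk[1] != 0) ai[, 1] * dk[1]
         else if (dk[2] != 0) ai[, 2] * dk[2]
         else ai[, 3] * dk[3]
    l1 <- ai[, 1] - s * dk[1]
    l2 <- ai[, 2] - s * dk[2]
    l3 <- ai[, 3] - s * dk[3]
    key <- (l1 + 3L * maxlen) + (8L * maxlen) * (l2 + 3L * maxlen) +
      (64L * maxlen * maxlen) * (l3 + 3L * maxlen)
    ord <- order(key, s)
    kk <- key[ord]; ss <- s[ord]; vv <- val[ord]
    n <- length(ord)
    newrun <- c(TRUE, kk[-1] != kk[-n] | ss[-1] != ss[-n] + 1L |
                  vv[-1] != vv[-n])
    starts <- which(newrun)
    lens <- diff(c(starts, n + 1L))
    rl <- pmin(lens, maxlen)
    rlev <- vv[starts]
    tab <- tabulate(rlev + (rl - 1L) * ng, nbins = ng * maxlen)
    m <- matrix(tab, ng, maxlen)
    nz <- max(1L, max(which(colSums(m) > 0)))
    out[[k]] <- m[, seq_len(nz), drop = FALSE]
  }
  list(R = out, n_levels = ng)
}

#' Grey-level size zone matrix (GLSZM)
#'
#' Zones are 26-connected components of equal level within the mask;
#' counts are indexed by (level, zone size).
#'
#' @inheritParams glcm_matrix
#' @return List with `S` (levels x size count matrix) and `n_levels`.
#' @export
glszm_matrix <- function(levels, mask = NULL, n_levels = NULL) {
  lv <- as_level_grid(levels, mask)
  idx <- which(!is.na(lv))
  if (length(idx) == 0L) stop("empty mask; GLSZM undefined")
  ng <- if (is.null(n_levels)) max(lv, na.rm = TRUE) else as.integer(n_levels)
  vid <- array(NA_integer_, dim = dim(lv))
  vid[idx] <- seq_along(idx)
  edges <- NULL
  offs <- offsets13()
  for (k in seq_len(nrow(offs))) {
    nb <- shift3(lv, offs[k, ])
    nbid <- shift3(vid, offs[k, ])
    ok <- !is.na(lv) & !is.na(nb) & lv == nb
    if (any(ok))
      edges <- rbind(edges, cbind(vid[ok], nbid[ok]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  sizes <- comp$csize
  # level of each component = level of any member voxel
  lev_by_comp <- integer(comp$no)
  lev_by_comp[comp$membership] <- lv[idx]
  maxsz <- max(sizes)
  tab <- tabulate(lev_by_comp + (sizes - 1L) * ng, nbins = ng * maxsz)
  list(S = matrix(tab, ng, maxsz), n_levels = ng)
}

#' Neighbourhood grey tone difference matrix (NGTDM)
#'
#' For each valid centre voxel (an in-mask voxel with at least one in-mask
#' 26-neighbour), the absolute difference between its level and the mean
#' level of its in-mask neighbours is accumulated per grey level.
#'
#' @inheritParams glcm_matrix
#' @return List with vectors `n`, `p`, `s` indexed by level `1..n_levels`,
#'   plus `n_valid` (count of valid centre voxels) and `n_levels`.
#' @export
ngtdm_matrix <- function(levels, mask = NULL, n_levels = NULL) {
  lv <- as_level_grid(levels, mask)
  if (all(is.na(lv))) stop("empty mask; NGTDM undefined")
  ng <- if (is.null(n_levels)) max(lv, na.rm = TRUE) else as.integer(n_levels)
  na0 <- lv; na0[is.na(na0)] <- 0L
  msk <- !is.na(lv)
  S <- array(0, dim = dim(lv)); C <- array(0L, dim = dim(lv))
  offs <- offsets13()
  for (k in seq_len(nrow(offs))) {
    for (sgn in c(1L, -1L)) {
      nb <- shift3(na0, sgn * offs[k, ])
      nbm <- shift3(msk * 1L, sgn * offs[k, ])
      nb[is.na(nb)] <- 0L
      nbm[is.na(nbm)] <- 0L
      S <- S + nb * nbm
      C <- C + nbm
    }
  }
  valid <- msk & C > 0L
  abar <- S[valid] / C[valid]
  li <- lv[valid]
  n_i <- tabulate(li, nbins = ng)
  s_i <- numeric(ng)
  acc <- rowsum(abs(li - abar), group = li)
  s_i[as.integer(rownames(acc))] <- acc[, 1]
  nv <- sum(n_i)
  list(n = n_i, p = if (nv > 0) n_i / nv else n_i, s = s_i,
       n_valid = nv, n_levels = ng)
}

#' Grey-level dependence matrix (GLDM)
#'
#' The dependence of a centre voxel is the number of its in-mask
#' 26-neighbours whose level differs from the centre's by at most `alpha`.
#' Counts are indexed by (level, dependence + 1): column `j` holds
#' dependence `j - 1`, so the matrix index stays positive in the feature
#' formulas.
#'
#' @inheritParams glcm_matrix
#' @param alpha Dependence tolerance on the level difference (default 0).
#' @return List with `D` (levels x dependence-size count matrix) and
#'   `n_levels`.
#' @export
gldm_matrix <- function(levels, mask = NULL, alpha = 0L, n_levels = NULL) {
  lv <- as_level_grid(levels, mask)
  if (all(is.na(lv))) stop("empty mask; GLDM undefined")
  ng <- if (is.null(n_levels)) max(lv, na.rm = TRUE) else as.integer(n_levels)
  dep <- array(0L, dim = dim(lv))
  offs <- offsets13()
  for (k in seq_len(nrow(offs))) {
    for (sgn in c(1L, -1L)) {
      nb <- shift3(lv, sgn * offs[k, ])
      ok <- !is.na(lv) & !is.na(nb) & abs(lv - nb) <= alpha
      dep <- dep + ok
    }
  }
  inm <- !is.na(lv)
  li <- lv[inm]
  di <- dep[inm] + 1L # column j holds dependence j - 1
  maxd <- max(di)
  tab <- tabulate(li + (di - 1L) * ng, nbins = ng * maxd)
  list(D = matrix(tab, ng, maxd), n_levels = ng)
}

#' All five texture matrices of a discretized ROI
#'
#' @param disc A `discretized_roi`.
#' @param mask The ROI `binary_mask`.
#' @param gldm_alpha GLDM dependence tolerance (default 0).
#' @return An object of class `texture_matrices` bundling the GLCM, GLRLM,
#'   GLSZM, NGTDM and GLDM outputs.
#' @export
texture_matrices <- function(disc, mask, gldm_alpha = 0L) {
  lv <- level_grid(disc, mask)
  structure(list(glcm = glcm_matrix(lv),
                 glrlm = glrlm_matrix(lv),
                 glszm = glszm_matrix(lv),
                 ngtdm = ngtdm_matrix(lv),
                 gldm = gldm_matrix(lv, alpha = gldm_alpha),
                 n_levels = max(lv, na.rm = TRUE)),
            class = "texture_matrices")
}
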