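# Independent brute-force oracles for the texture-matrix builders and the
# agreement statistics.  Everything here is deliberately written as plain
# nested loops / model fits, kept separate from the vectorized package code.

all_offsets13 <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                       c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
                       c(0, 1, 1), c(0, 1, -1),
                       c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

inb <- function(v, d) all(v >= 1L) && all(v <= d)

# symmetric co-occurrence counts, one matrix per direction
bf_glcm <- function(lv, ng) {
  d <- dim(lv)
  out <- list()
  for (k in seq_len(nrow(all_offsets13))) {
    off <- all_offsets13[k, ]
    m <- matrix(0L, ng, ng)
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      a <- lv[x, y, z]
      if (is.na(a)) next
      nbp <- c(x, y, z) + off
      if (!inb(nbp, d)) next
      b <- lv[nbp[1], nbp[2], nbp[3]]
      if (is.na(b)) next
      m[a, b] <- m[a, b] + 1L
      m[b, a] <- m[b, a] + 1L
    }
    if (sum(m) > 0) out[[length(out) + 1L]] <- m
  }
  out
}

# run-length counts per direction (maximal equal-level runs, truncated at
# the mask boundary)
bf_glrlm <- function(lv, ng) {
  d <- dim(lv)
  out <- list()
  for (k in seq_len(nrow(all_offsets13))) {
    off <- all_offsets13[k, ]
    runs <- list()
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      v <- c(x, y, z)
      a <- lv[x, y, z]
      if (is.na(a)) next
      prev <- v - off
      if (inb(prev, d) && !is.na(lv[prev[1], prev[2], prev[3]]) &&
          lv[prev[1], prev[2], prev[3]] == a) next # not a run start
      len <- 1L
      nxt <- v + off
      while (inb(nxt, d) && !is.na(lv[nxt[1], nxt[2], nxt[3]]) &&
             lv[nxt[1], nxt[2], nxt[3]] == a) {
        len <- len + 1L
        nxt <- nxt + off
      }
      runs[[length(runs) + 1L]] <- c(a, len)
    }
    maxlen <- max(vapply(runs, `[`, 1L, 2L))
    m <- matrix(0L, ng, maxlen)
    for (r in runs) m[r[1], r[2]] <- m[r[1], r[2]] + 1L
    out[[k]] <- m
  }
  out
}

# 26-connected zones by breadth-first flood fill
bf_glszm <- function(lv, ng) {
  d <- dim(lv)
  offs <- rbind(all_offsets13, -all_offsets13)
  seen <- array(FALSE, dim = d)
  zones <- list()
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (seen[x, y, z] || is.na(lv[x, y, z])) next
    a <- lv[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0L
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (k in seq_len(nrow(offs))) {
        nbp <- v + offs[k, ]
        if (!inb(nbp, d)) next
        if (seen[nbp[1], nbp[2], nbp[3]]) next
        b <- lv[nbp[1], nbp[2], nbp[3]]
        if (is.na(b) || b != a) next
        seen[nbp[1], nbp[2], nbp[3]] <- TRUE
        queue[[length(queue) + 1L]] <- nbp
      }
    }
    zones[[length(zones) + 1L]] <- c(a, size)
  }
  maxsz <- max(vapply(zones, `[`, 1L, 2L))
  m <- matrix(0L, ng, maxsz)
  for (zn in zones) m[zn[1], zn[2]] <- m[zn[1], zn[2]] + 1L
  m
}

# per-voxel neighbourhood grey tone differences
bf_ngtdm <- function(lv, ng) {
  d <- dim(lv)
  offs <- rbind(all_offsets13, -all_offsets13)
  n_i <- integer(ng); s_i <- numeric(ng)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- lv[x, y, z]
    if (is.na(a)) next
    nbv <- c()
    for (k in seq_len(nrow(offs))) {
      nbp <- c(x, y, z) + offs[k, ]
      if (!inb(nbp, d)) next
      b <- lv[nbp[1], nbp[2], nbp[3]]
      if (!is.na(b)) nbv <- c(nbv, b)
    }
    if (length(nbv) == 0L) next # no in-mask neighbour: excluded
    n_i[a] <- n_i[a] + 1L
    s_i[a] <- s_i[a] + abs(a - mean(nbv))
  }
  list(n = n_i, s = s_i, n_valid = sum(n_i))
}

# per-voxel dependence counts
bf_gldm <- function(lv, ng, alpha = 0L) {
  d <- dim(lv)
  offs <- rbind(all_offsets13, -all_offsets13)
  recs <- list()
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- lv[x, y, z]
    if (is.na(a)) next
    dep <- 0L
    for (k in seq_len(nrow(offs))) {
      nbp <- c(x, y, z) + offs[k, ]
      if (!inb(nbp, d)) next
      b <- lv[nbp[1], nbp[2], nbp[3]]
      if (!is.na(b) && abs(a - b) <= alpha) dep <- dep + 1L
    }
    recs[[length(recs) + 1L]] <- c(a, dep + 1L)
  }
  maxd <- max(vapply(recs, `[`, 1L, 2L))
  m <- matrix(0L, ng, maxd)
  for (r in recs) m[r[1], r[2]] <- m[r[1], r[2]] + 1L
  m
}

# random small level grids with a random mask
random_fixture <- function(seed, max_dim = 6L, ng = 4L) {
  set.seed(seed)
  d <- sample(2:max_dim, 3, replace = TRUE)
  lv <- array(sample.int(ng, prod(d), replace = TRUE), dim = d)
  lv[array(runif(prod(d)) < 0.3, dim = d)] <- NA_integer_
  if (all(is.na(lv))) lv[1, 1, 1] <- 1L
  lv
}

# ICC(2,1) via an independently fitted two-way ANOVA (aov mean squares)
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(value = as.numeric(m),
                  subject = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(value ~ subject + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Lin's concordance via the correlation form r * (2 sx sy / (...))
ccc_oracle <- function(m) {
  a <- m[, 1]; b <- m[, 2]
  n <- length(a)
  r <- stats::cor(a, b)
  sx <- stats::sd(a) * sqrt((n - 1) / n)
  sy <- stats::sd(b) * sqrt((n - 1) / n)
  r * 2 * sx * sy / (sx^2 + sy^2 + (mean(a) - mean(b))^2)
}
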