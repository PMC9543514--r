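# Independent reference implementations used as oracles. These deliberately
# use different algorithms / control flow from the package code they check.

# Rate-weighted COM by an explicit loop.
oracle_com <- function(map, bins) {
  sw <- 0; sx <- 0; sy <- 0
  for (k in seq_len(nrow(bins))) {
    w <- map$rate_smooth[bins[k, 1], bins[k, 2]]
    sw <- sw + w
    sx <- sx + w * map$x_centers[bins[k, 1]]
    sy <- sy + w * map$y_centers[bins[k, 2]]
  }
  c(sx / sw, sy / sw)
}

# Direct-summation Skaggs information over valid bins.
oracle_skaggs <- function(occupancy, rate) {
  v <- which(is.finite(rate) & occupancy > 0)
  p <- occupancy[v] / sum(occupancy[v])
  lam <- rate[v]
  lbar <- sum(p * lam)
  tot <- 0
  for (k in seq_along(v)) {
    if (lam[k] > 0) tot <- tot + p[k] * (lam[k] / lbar) * log2(lam[k] / lbar)
  }
  tot
}

# Two-pass Pearson correlation between raw rates and an explicitly looped
# 8-neighbour mean.
oracle_coherence <- function(rate, valid) {
  nx <- nrow(rate); ny <- ncol(rate)
  a <- c(); b <- c()
  for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
    if (!valid[ix, iy]) next
    vals <- c()
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      jx <- ix + dx; jy <- iy + dy
      if (jx < 1 || jx > nx || jy < 1 || jy > ny) next
      if (valid[jx, jy]) vals <- c(vals, rate[jx, jy])
    }
    if (!length(vals)) next
    a <- c(a, rate[ix, iy]); b <- c(b, mean(vals))
  }
  ma <- mean(a); mb <- mean(b)
  sum((a - ma) * (b - mb)) / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# Exhaustive O(n^2) burst reference: find maximal short-ISI runs by testing
# every (i, j) span, then merge by fixed-point iteration.
oracle_bursts <- function(times_s, max_intra = 6, min_ibi = 50) {
  t <- times_s * 1000
  n <- length(t)
  runs <- list()
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq_len(n)[-seq_len(i)]) {
      isis <- t[(i + 1):j] - t[i:(j - 1)]
      if (all(isis <= max_intra)) {
        left_max <- i == 1 || (t[i] - t[i - 1]) > max_intra
        right_max <- j == n || (t[j + 1] - t[j]) > max_intra
        if (left_max && right_max) runs[[length(runs) + 1]] <- c(i, j)
      }
    }
  }
  if (!length(runs)) {
    return(list(n_bursts = 0L, sizes = integer(0), durations = numeric(0)))
  }
  runs <- do.call(rbind, runs)
  runs <- runs[order(runs[, 1]), , drop = FALSE]
  repeat {
    merged <- FALSE
    k <- 1
    while (k < nrow(runs)) {
      if ((t[runs[k + 1, 1]] - t[runs[k, 2]]) < min_ibi) {
        runs[k, 2] <- runs[k + 1, 2]
        runs <- runs[-(k + 1), , drop = FALSE]
        merged <- TRUE
      } else k <- k + 1
    }
    if (!merged) break
  }
  list(n_bursts = nrow(runs),
       sizes = runs[, 2] - runs[, 1] + 1L,
       durations = t[runs[, 2]] - t[runs[, 1]])
}

# Textbook paired t statistic and two-sided p.
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  list(statistic = tstat, p = 2 * pt(-abs(tstat), df = n - 1))
}

# Exact two-sided Wilcoxon signed-rank p by enumerating all sign
# assignments (no zeros/ties assumed; n <= 12).
oracle_wilcoxon_exact <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p_ge <- mean(vs >= v_obs)
  p_le <- mean(vs <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

# Connected components by repeated neighbour expansion of bin sets
# (set-based, not flood fill).
oracle_components <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  remaining <- which(mask)
  comps <- list()
  neighbours <- function(cells) {
    ix <- (cells - 1L) %% nx + 1L
    iy <- (cells - 1L) %/% nx + 1L
    cand <- c((iy - 1L) * nx + ix - 1L, (iy - 1L) * nx + ix + 1L,
              (iy - 2L) * nx + ix, iy * nx + ix)
    ok <- c(ix > 1L, ix < nx, iy > 1L, iy < ny)
    unique(cand[ok])
  }
  while (length(remaining)) {
    comp <- remaining[1]
    repeat {
      grow <- intersect(neighbours(comp), remaining)
      grow <- setdiff(grow, comp)
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
    comps[[length(comps) + 1]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  comps
}

# Random valid rate map for property tests.
random_rate_map <- function(seed, nx = 10, ny = 10, bin_size = 2.5) {
  set.seed(seed)
  occ <- matrix(rexp(nx * ny, 1 / 2), nx, ny)
  rate <- matrix(rexp(nx * ny, 1), nx, ny)
  rate[sample(nx * ny, 5)] <- 0
  rate_map_from_matrices(occ, rate, bin_size = bin_size)
}
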