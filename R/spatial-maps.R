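#' Build an occupancy / firing rate map from a trajectory and spike train
#'
#' The arena is divided into square bins (origin at the south-west corner,
#' half-open intervals, bin centres at `(i + 0.5) * bin_size`). Occupancy is
#' the summed dwell time of position samples per bin; each spike is assigned
#' to the bin of the temporally nearest position sample. Bins occupied for
#' less than `min_occupancy` seconds are masked invalid and excluded from all
#' downstream statistics. The smoothed map is a mask-aware occupancy-weighted
#' boxcar: spike counts and occupancy are smoothed separately over a
#' `smooth_bins` x `smooth_bins` window of valid bins and then divided,
#' which keeps sparsely visited bins from dominating the smoothed map at the
#' low firing rates typical of claustral units.
#'
#' @param traj Trajectory tibble with columns `t`, `x`, `y`.
#' @param spikes Numeric vector of spike times, s. Spikes outside the session
#'   are clipped (with a warning) before binning.
#' @param bin_size Bin side, cm.
#' @param min_occupancy Minimum dwell time for a bin to be valid, s.
#' @param smooth Logical: apply the boxcar (default) or copy the raw map.
#' @param smooth_bins Odd boxcar side length in bins (default 5).
#' @param arena Optional [arena_spec()]; defaults to the trajectory's arena
#'   attribute, else its bounding box.
#' @return A `rate_map` object: list of matrices `occupancy`, `spike_count`,
#'   `rate_raw`, `rate_smooth` (all `nx` x `ny`, x along rows) and
#'   `valid_mask`, plus `bin_size` and bin-centre coordinate vectors.
#' @examples
#' traj <- simulate_trajectory(60, seed = 1)
#' spk <- simulate_place_cell(traj, c(40, 40), seed = 2)
#' rm <- compute_rate_map(traj, spk)
#' skaggs_information(rm)
#' @export
compute_rate_map <- function(traj, spikes, bin_size = 2.5,
                             min_occupancy = 0.1, smooth = TRUE,
                             smooth_bins = 5, arena = NULL) {
  if (is.null(traj) || nrow(traj) < 2L) abort("Trajectory must have >= 2 samples.")
  check_positive(bin_size, "bin_size")
  if (smooth_bins < 1 || smooth_bins %% 2 != 1) {
    abort("`smooth_bins` must be a positive odd integer.")
  }
  arena <- trajectory_arena(traj, arena)
  nx <- max(1L, ceiling(arena$width / bin_size - 1e-9))
  ny <- max(1L, ceiling(arena$height / bin_size - 1e-9))
  bin_of <- function(p, nbin) pmin(pmax(floor(p / bin_size) + 1L, 1L), nbin)
  ix <- bin_of(traj$x, nx)
  iy <- bin_of(traj$y, ny)
  flat <- (iy - 1L) * nx + ix
  # Dwell time of sample k: half-interval to each neighbouring sample.
  dts <- diff(traj$t)
  dwell <- c(dts / 2, 0) + c(0, dts / 2)
  occupancy <- matrix(0, nx, ny)
  occ_flat <- tapply(dwell, factor(flat, levels = seq_len(nx * ny)), sum)
  occupancy[] <- ifelse(is.na(occ_flat), 0, occ_flat)

  spikes <- as.numeric(spikes)
  n_out <- sum(spikes < min(traj$t) | spikes > max(traj$t))
  if (n_out > 0) {
    warn(sprintf("%d spike(s) outside the session were clipped.", n_out))
    spikes <- spikes[spikes >= min(traj$t) & spikes <= max(traj$t)]
  }
  spike_count <- matrix(0, nx, ny)
  if (length(spikes)) {
    sidx <- nearest_index(traj$t, spikes)
    sflat <- flat[sidx]
    cnt <- tabulate(sflat, nbins = nx * ny)
    spike_count[] <- cnt
  }
  valid <- occupancy >= min_occupancy
  rate_raw <- matrix(NA_real_, nx, ny)
  rate_raw[valid] <- spike_count[valid] / occupancy[valid]
  rate_smooth <- if (smooth) {
    boxcar_smooth(spike_count, occupancy, valid,
                  radius = (smooth_bins - 1L) %/% 2L)
  } else {
    rate_raw
  }
  structure(list(occupancy = occupancy, spike_count = spike_count,
                 rate_raw = rate_raw, rate_smooth = rate_smooth,
                 valid_mask = valid, bin_size = bin_size,
                 x_centers = (seq_len(nx) - 0.5) * bin_size,
                 y_centers = (seq_len(ny) - 0.5) * bin_size,
                 arena = arena),
            class = "rate_map")
}

#' Construct a rate map directly from matrices
#'
#' Mostly useful for tests and worked examples: wraps pre-computed grids in
#' the `rate_map` structure used by [skaggs_information()],
#' [spatial_coherence()] and [detect_place_field()].
#'
#' @param occupancy Occupancy matrix, s per bin (`nx` x `ny`).
#' @param rate Firing rate matrix, Hz per bin.
#' @param rate_smooth Optional smoothed rate; defaults to `rate`.
#' @param bin_size Bin side, cm.
#' @param valid_mask Logical matrix; defaults to finite-rate bins with
#'   positive occupancy.
#' @return A `rate_map` object.
#' @export
rate_map_from_matrices <- function(occupancy, rate, rate_smooth = rate,
                                   bin_size = 2.5, valid_mask = NULL) {
  stopifnot(all(dim(occupancy) == dim(rate)))
  valid <- valid_mask %||% (is.finite(rate) & occupancy > 0)
  rate[!valid] <- NA_real_
  rate_smooth[!valid] <- NA_real_
  nx <- nrow(rate); ny <- ncol(rate)
  structure(list(occupancy = occupancy,
                 spike_count = rate * occupancy,
                 rate_raw = rate, rate_smooth = rate_smooth,
                 valid_mask = valid, bin_size = bin_size,
                 x_centers = (seq_len(nx) - 0.5) * bin_size,
                 y_centers = (seq_len(ny) - 0.5) * bin_size,
                 arena = arena_spec(nx * bin_size, ny * bin_size)),
            class = "rate_map")
}

# Mask-aware neighbourhood sum over a (2r+1) x (2r+1) boxcar; also returns
# the per-bin count of valid contributing neighbours. `include_center`
# FALSE drops the centre bin (used by spatial coherence).
neighbor_sums <- function(m, valid, radius = 1L, include_center = TRUE) {
  nx <- nrow(m); ny <- ncol(m)
  v <- m
  v[!valid] <- 0
  ind <- matrix(as.numeric(valid), nx, ny)
  acc <- matrix(0, nx, ny)
  cnt <- matrix(0, nx, ny)
  for (dx in -radius:radius) {
    for (dy in -radius:radius) {
      if (!include_center && dx == 0L && dy == 0L) next
      xs <- seq_len(nx) + dx
      ys <- seq_len(ny) + dy
      okx <- xs >= 1 & xs <= nx
      oky <- ys >= 1 & ys <= ny
      acc[okx, oky] <- acc[okx, oky] + v[xs[okx], ys[oky]]
      cnt[okx, oky] <- cnt[okx, oky] + ind[xs[okx], ys[oky]]
    }
  }
  list(sum = acc, n = cnt)
}

neighbor_mean <- function(m, valid, radius = 1L, include_center = TRUE) {
  ns <- neighbor_sums(m, valid, radius, include_center)
  out <- matrix(NA_real_, nrow(m), ncol(m))
  has <- ns$n > 0
  out[has] <- ns$sum[has] / ns$n[has]
  out
}

# Occupancy-weighted boxcar smoothing: spike counts and occupancy are
# smoothed separately and then divided, so sparsely visited bins cannot
# inject huge rate estimates into the smoothed map.
boxcar_smooth <- function(spike_count, occupancy, valid, radius = 2L) {
  cnt <- neighbor_sums(spike_count, valid, radius)$sum
  occ <- neighbor_sums(occupancy, valid, radius)$sum
  sm <- matrix(NA_real_, nrow(occupancy), ncol(occupancy))
  ok <- valid & occ > 0
  sm[ok] <- cnt[ok] / occ[ok]
  sm
}

#' Detect the principal place field of a rate map
#'
#' Thresholds the smoothed map at `peak_fraction` of its global peak and
#' returns the largest 4-connected component of supra-threshold valid bins,
#' provided it has at least `min_bins` bins. Ties on component size are
#' broken by higher mean rate, then by lowest linear bin index.
#'
#' @param map A `rate_map`.
#' @param peak_fraction Threshold as a fraction of the global peak rate.
#' @param min_bins Minimum component size in bins.
#' @return A `place_field` (list with `member_bins` matrix of `(ix, iy)`,
#'   `peak_rate`, `com`) or `NULL` when no component qualifies.
#' @export
detect_place_field <- function(map, peak_fraction = 0.2, min_bins = 9) {
  stopifnot(inherits(map, "rate_map"))
  if (!any(map$valid_mask)) abort("Rate map has no valid bins.")
  r <- map$rate_smooth
  peak <- max(r[map$valid_mask], na.rm = TRUE)
  supra <- map$valid_mask & !is.na(r) & r >= peak_fraction * peak
  if (!any(supra)) return(NULL)
  comp <- connected_components(supra)
  sizes <- tabulate(comp[comp > 0])
  best <- 0L; best_key <- NULL
  for (cid in seq_along(sizes)) {
    members <- which(comp == cid)
    key <- c(sizes[cid], mean(r[members]), -min(members))
    if (is.null(best_key) ||
        key[1] > best_key[1] ||
        (key[1] == best_key[1] && key[2] > best_key[2]) ||
        (key[1] == best_key[1] && key[2] == best_key[2] && key[3] > best_key[3])) {
      best <- cid; best_key <- key
    }
  }
  members <- which(comp == best)
  if (length(members) < min_bins) return(NULL)
  nx <- nrow(r)
  bins <- cbind(ix = (members - 1L) %% nx + 1L,
                iy = (members - 1L) %/% nx + 1L)
  field <- structure(list(member_bins = bins,
                          peak_rate = max(r[members]),
                          com = NULL),
                     class = "place_field")
  field$com <- field_com(map, field)
  field
}

# 4-connected component labelling of a logical matrix via flood fill.
connected_components <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  comp <- matrix(0L, nx, ny)
  cur <- 0L
  for (start in which(mask)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      i <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ix <- (i - 1L) %% nx + 1L
      iy <- (i - 1L) %/% nx + 1L
      for (nb in list(c(ix - 1L, iy), c(ix + 1L, iy),
                      c(ix, iy - 1L), c(ix, iy + 1L))) {
        if (nb[1] < 1L || nb[1] > nx || nb[2] < 1L || nb[2] > ny) next
        j <- (nb[2] - 1L) * nx + nb[1]
        if (mask[j] && comp[j] == 0L) {
          comp[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

#' Centre of mass of a place field
#'
#' Rate-weighted mean of the member-bin centre coordinates, using the
#' smoothed rate restricted to the field's bins.
#'
#' @param map A `rate_map`.
#' @param field A `place_field` from [detect_place_field()].
#' @return `c(x, y)` in cm.
#' @export
field_com <- function(map, field) {
  bins <- field$member_bins
  if (is.null(bins) || nrow(bins) == 0L) abort("Place field is empty.")
  w <- map$rate_smooth[cbind(bins[, 1], bins[, 2])]
  if (all(w == 0)) abort("All member-bin rates are zero; COM undefined.")
  cx <- map$x_centers[bins[, 1]]
  cy <- map$y_centers[bins[, 2]]
  c(x = sum(w * cx) / sum(w), y = sum(w * cy) / sum(w))
}

#' Skaggs spatial information (bits per spike)
#'
#' \eqn{I = \sum_i p_i (\lambda_i/\bar\lambda) \log_2(\lambda_i/\bar\lambda)}
#' over valid bins, where \eqn{p_i} is the occupancy probability and
#' \eqn{\bar\lambda = \sum_i p_i \lambda_i}. Zero-rate bins contribute 0.
#' Computed on the smoothed map by default (the plug-in estimator on the raw
#' map is strongly upward-biased at low spike counts).
#'
#' @param map A `rate_map`.
#' @param use Which rate grid to use, `"smooth"` (default) or `"raw"`.
#' @return Information in bits per spike (>= 0 up to floating error).
#' @export
skaggs_information <- function(map, use = c("smooth", "raw")) {
  use <- match.arg(use)
  r <- if (use == "smooth") map$rate_smooth else map$rate_raw
  v <- map$valid_mask & is.finite(r)
  occ <- map$occupancy[v]
  lam <- r[v]
  if (!length(occ) || sum(occ) <= 0) abort("No occupied valid bins.")
  p <- occ / sum(occ)
  lbar <- sum(p * lam)
  if (lbar <= 0) abort("Mean rate is zero; spatial information undefined.")
  ratio <- lam / lbar
  terms <- ifelse(lam > 0, p * ratio * log2(ratio), 0)
  max(sum(terms), 0)
}

#' Spatial coherence of a rate map
#'
#' Pearson correlation, over valid bins, between the raw rate and the mean of
#' each bin's valid 3x3 neighbours (centre excluded). High coherence means
#' locally regular firing; it is one of the place-cell inclusion criteria.
#'
#' @param map A `rate_map`.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
spatial_coherence <- function(map) {
  nb <- neighbor_mean(map$rate_raw, map$valid_mask, include_center = FALSE)
  v <- map$valid_mask & is.finite(map$rate_raw) & is.finite(nb)
  if (sum(v) < 3L) abort("Need >= 3 valid bins with neighbours for coherence.")
  a <- map$rate_raw[v]; b <- nb[v]
  if (sd(a) == 0 || sd(b) == 0) {
    abort("Rate variance is zero; spatial coherence undefined.")
  }
  cor(a, b)
}

#' Mean running speed of a trajectory
#'
#' Mean over steps of displacement divided by the time step.
#'
#' @param traj Trajectory tibble with columns `t`, `x`, `y`.
#' @return Speed in cm/s.
#' @export
mean_speed <- function(traj) {
  if (nrow(traj) < 2L) abort("Need >= 2 position samples.")
  dt <- diff(traj$t)
  if (any(dt <= 0)) abort("Timestamps must be strictly increasing.")
  step <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  mean(step / dt)
}

#' @export
tidy.rate_map <- function(x, ...) {
  grid <- tidyr::expand_grid(iy = seq_along(x$y_centers),
                             ix = seq_along(x$x_centers))
  idx <- cbind(grid$ix, grid$iy)
  out <- list(x = x$x_centers[grid$ix], y = x$y_centers[grid$iy],
              occupancy = x$occupancy[idx],
              spikes = x$spike_count[idx],
              rate_raw = x$rate_raw[idx],
              rate_smooth = x$rate_smooth[idx],
              valid = x$valid_mask[idx])
  as_tibble(out)
}

#' @export
glance.rate_map <- function(x, ...) {
  v <- x$valid_mask
  occ <- x$occupancy[v]
  p <- occ / sum(occ)
  tibble(n_bins = length(v), n_valid = sum(v),
         total_occupancy = sum(x$occupancy),
         total_spikes = sum(x$spike_count),
         mean_rate = sum(p * x$rate_raw[v]),
         peak_rate = max(x$rate_smooth[v], na.rm = TRUE))
}

#' @export
autoplot.rate_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$rate_smooth)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90",
                                  name = "rate (Hz)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map> %d x %d bins of %.2f cm, %d valid, peak %.2f Hz\n",
              nrow(x$rate_raw), ncol(x$rate_raw), x$bin_size,
              sum(x$valid_mask),
              suppressWarnings(max(x$rate_smooth, na.rm = TRUE))))
  invisible(x)
}
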