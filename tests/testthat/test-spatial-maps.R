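make_traj <- function(t, x, y, arena = arena_spec()) {
  out <- tibble::tibble(t = t, x = x, y = y)
  attr(out, "arena") <- arena
  out
}

test_that("a stationary dwell gives one valid bin at the spike rate", {
  traj <- make_traj(seq(0, 10, by = 0.1), rep(10, 101), rep(10, 101))
  rm <- compute_rate_map(traj, spikes = seq(0.5, 9.5, length.out = 10))
  expect_equal(sum(rm$valid_mask), 1L)
  expect_equal(rm$rate_raw[rm$valid_mask], 1, tolerance = 1e-9)
  expect_true(all(is.na(rm$rate_raw[!rm$valid_mask])))
})

test_that("rate maps conserve spikes and occupancy", {
  traj <- simulate_trajectory(300, 10, 50, seed = 4)
  spk <- simulate_place_cell(traj, c(20, 60), seed = 5)
  rm <- compute_rate_map(traj, spk)
  expect_equal(sum(rm$spike_count), length(spk))
  expect_lt(abs(sum(rm$occupancy) - 300) / 300, 0.01)
  # empty spike train: a valid all-zero map, not an error
  rm0 <- compute_rate_map(traj, numeric(0))
  expect_equal(sum(rm0$spike_count), 0)
  expect_true(any(rm0$valid_mask))
  expect_error(compute_rate_map(traj[0, ], spk), "2 samples")
})

test_that("the smoothed map peaks near the true field centre", {
  errs <- vapply(1:20, function(s) {
    traj <- simulate_trajectory(600, 10, 50, seed = s)
    spk <- simulate_place_cell(traj, c(30, 50), seed = s + 500)
    rm <- compute_rate_map(traj, spk)
    peak <- which(rm$rate_smooth == max(rm$rate_smooth, na.rm = TRUE),
                  arr.ind = TRUE)[1, ]
    sqrt((rm$x_centers[peak[1]] - 30)^2 + (rm$y_centers[peak[2]] - 50)^2)
  }, numeric(1))
  expect_lt(median(errs), 2 * 2.5)
})

test_that("place-field detection matches brute-force component enumeration", {
  # single Gaussian bump: one field containing the peak bin
  xs <- (1:20 - 0.5) * 2.5
  bump <- outer(xs, xs, function(x, y) 5 * exp(-((x - 25)^2 + (y - 25)^2) / 50))
  rm <- rate_map_from_matrices(matrix(1, 20, 20), bump)
  f <- detect_place_field(rm)
  peak <- which(bump == max(bump), arr.ind = TRUE)
  expect_true(any(f$member_bins[, 1] == peak[1] & f$member_bins[, 2] == peak[2]))

  # uniform map at peak rate: the whole valid area is one field
  runi <- rate_map_from_matrices(matrix(1, 6, 6), matrix(2, 6, 6))
  expect_equal(nrow(detect_place_field(runi)$member_bins), 36)

  # two unequal bumps: larger-area component wins; verify against the
  # set-based component oracle
  r <- matrix(0.01, 15, 15)
  r[2:5, 2:5] <- 3      # 16 bins
  r[9:14, 9:14] <- 2.5  # 36 bins
  rm2 <- rate_map_from_matrices(matrix(1, 15, 15), r)
  f2 <- detect_place_field(rm2, peak_fraction = 0.5, min_bins = 4)
  supra <- r >= 0.5 * max(r)
  comps <- oracle_components(supra)
  biggest <- comps[[which.max(lengths(comps))]]
  got <- sort((f2$member_bins[, 2] - 1) * 15 + f2$member_bins[, 1])
  expect_equal(got, biggest)

  # equal-area tie broken by higher mean rate
  r3 <- matrix(0.01, 12, 12)
  r3[2:4, 2:4] <- 2
  r3[8:10, 8:10] <- 3
  rm3 <- rate_map_from_matrices(matrix(1, 12, 12), r3)
  f3 <- detect_place_field(rm3, peak_fraction = 0.5, min_bins = 4)
  expect_true(all(f3$member_bins[, 1] >= 8))

  # min_bins filters small components
  expect_null(detect_place_field(rm3, peak_fraction = 0.5, min_bins = 10))
})

test_that("field COM equals the explicit weighted-loop oracle", {
  for (s in 1:10) {
    rm <- random_rate_map(s)
    all_bins <- which(rm$valid_mask, arr.ind = TRUE)
    f <- structure(list(member_bins = all_bins), class = "place_field")
    expect_equal(unname(field_com(rm, f)), oracle_com(rm, all_bins),
                 tolerance = 1e-12)
  }
  # single-bin field sits at the bin centre
  rm1 <- rate_map_from_matrices(matrix(1, 32, 32), matrix(1, 32, 32))
  f1 <- structure(list(member_bins = cbind(16L, 16L)), class = "place_field")
  expect_equal(unname(field_com(rm1, f1)), c(38.75, 38.75))
  # symmetric bump: COM within half a bin of the true centre
  xs <- (1:32 - 0.5) * 2.5
  bump <- outer(xs, xs, function(x, y) exp(-((x - 20)^2 + (y - 60)^2) / 100))
  rmb <- rate_map_from_matrices(matrix(1, 32, 32), bump)
  fb <- detect_place_field(rmb, peak_fraction = 0.1, min_bins = 4)
  expect_lt(max(abs(fb$com - c(20, 60))), 1.25)
})

test_that("Skaggs information: closed forms, oracle equality, scale invariance", {
  # uniform map carries no spatial information
  runi <- rate_map_from_matrices(matrix(2, 8, 8), matrix(3, 8, 8))
  expect_equal(skaggs_information(runi), 0)

  # two equal-occupancy bins with rates (2, 0) Hz -> exactly 1 bit/spike
  r2 <- rate_map_from_matrices(matrix(1, 2, 1), matrix(c(2, 0), 2, 1))
  expect_equal(skaggs_information(r2), 1)

  for (s in 1:10) {
    rm <- random_rate_map(s)
    expect_equal(skaggs_information(rm),
                 oracle_skaggs(rm$occupancy, rm$rate_smooth),
                 tolerance = 1e-12)
    # invariant under uniform rate rescaling
    rm_scaled <- rate_map_from_matrices(rm$occupancy, 7.3 * rm$rate_raw,
                                        7.3 * rm$rate_smooth)
    expect_equal(skaggs_information(rm_scaled), skaggs_information(rm),
                 tolerance = 1e-10)
  }
  zero <- rate_map_from_matrices(matrix(1, 3, 3), matrix(0, 3, 3))
  expect_error(skaggs_information(zero), "undefined")
})

test_that("spatial coherence: ramp, stripes, and Pearson oracle", {
  ramp <- outer(1:12, 1:12, function(i, j) i + 0.5 * j)
  rmap <- rate_map_from_matrices(matrix(1, 12, 12), ramp)
  expect_gt(spatial_coherence(rmap), 0.99)

  stripes <- 2 + outer(1:12, 1:12, function(i, j) (-1)^i)
  rst <- rate_map_from_matrices(matrix(1, 12, 12), stripes)
  expect_lt(spatial_coherence(rst), -0.9)

  for (s in 1:10) {
    rm <- random_rate_map(s)
    expect_equal(spatial_coherence(rm),
                 oracle_coherence(rm$rate_raw, rm$valid_mask),
                 tolerance = 1e-12)
  }
  flat <- rate_map_from_matrices(matrix(1, 5, 5), matrix(2, 5, 5))
  expect_error(spatial_coherence(flat), "undefined")
})

test_that("mean speed: constant velocity, stationary, simulated target", {
  line <- make_traj(seq(0, 8, by = 0.1), seq(0, 80, length.out = 81),
                    rep(1, 81))
  expect_equal(mean_speed(line), 10, tolerance = 1e-9)
  still <- make_traj(0:10, rep(5, 11), rep(5, 11))
  expect_equal(mean_speed(still), 0)
  dup <- make_traj(c(0, 1, 1, 2), rep(5, 4), rep(5, 4))
  expect_error(mean_speed(dup), "increasing")
  expect_equal(mean_speed(simulate_trajectory(600, 10, 50, seed = 9)), 10,
               tolerance = 0.15)
})

test_that("simulated place cells clear the place-cell thresholds; constant cells do not", {
  stats <- t(vapply(1:20, function(s) {
    traj <- simulate_trajectory(600, 10, 50, seed = s + 40)
    spk <- simulate_place_cell(traj, c(50, 30), seed = s + 900)
    rm <- compute_rate_map(traj, spk)
    c(skaggs = skaggs_information(rm), coh = spatial_coherence(rm))
  }, numeric(2)))
  expect_gte(mean(stats[, "skaggs"] >= 0.5 & stats[, "coh"] >= 0.25), 0.9)

  traj <- simulate_trajectory(600, 10, 50, seed = 77)
  const <- simulate_place_cell(traj, c(40, 40),
                               place_cell_spec(peak_rate = 0.35,
                                               baseline_rate = 0.35),
                               seed = 78)
  expect_lt(skaggs_information(compute_rate_map(traj, const)), 0.5)
})

test_that("rate-map tidiers expose the grids faithfully", {
  traj <- simulate_trajectory(60, 10, 50, seed = 2)
  rm <- compute_rate_map(traj, simulate_place_cell(traj, c(40, 40), seed = 3))
  td <- tidy(rm)
  expect_equal(nrow(td), 32 * 32)
  expect_equal(sum(td$occupancy), sum(rm$occupancy))
  g <- glance(rm)
  expect_equal(g$total_spikes, sum(rm$spike_count))
  p <- autoplot(rm)
  expect_s3_class(p, "ggplot")
})
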