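test_that("trajectory stays in the arena with the right sampling and seed determinism", {
  traj <- simulate_trajectory(600, mean_speed = 10, sample_rate = 50, seed = 1)
  expect_equal(nrow(traj), 30000)
  expect_true(all(traj$x > 0 & traj$x < 80))
  expect_true(all(traj$y > 0 & traj$y < 80))
  expect_equal(diff(traj$t), rep(0.02, 29999), tolerance = 1e-12)

  again <- simulate_trajectory(600, mean_speed = 10, sample_rate = 50, seed = 1)
  expect_identical(traj, again)
  other <- simulate_trajectory(600, mean_speed = 10, sample_rate = 50, seed = 2)
  expect_false(identical(traj$x, other$x))

  expect_error(simulate_trajectory(-1, 10, 50, seed = 1), "positive")
  expect_error(simulate_trajectory(600, 0, 50, seed = 1), "positive")
})

test_that("trajectory mean speed matches the target within 15%", {
  speeds <- vapply(1:5, function(s) {
    mean_speed(simulate_trajectory(600, mean_speed = 10, seed = s))
  }, numeric(1))
  expect_true(all(abs(speeds - 10) / 10 < 0.15))
})

test_that("place-cell generator matches an independent quadrature of its intensity", {
  traj <- simulate_trajectory(600, 10, 50, seed = 11)
  spec <- place_cell_spec()
  com <- c(30, 50)
  # independent oracle: numerical quadrature of lambda along the path
  d2 <- (traj$x - com[1])^2 + (traj$y - com[2])^2
  lam <- spec$baseline_rate + (spec$peak_rate - spec$baseline_rate) *
    exp(-d2 / (2 * spec$field_sigma^2))
  expected <- sum(lam) * 0.02
  counts <- vapply(1:50, function(s) {
    length(simulate_place_cell(traj, com, spec, seed = s))
  }, numeric(1))
  sem <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 2 * sem)
  # spike count within 4 sd of the Poisson expectation for every seed
  expect_true(all(abs(counts - expected) < 4 * sqrt(expected)))
})

test_that("zero-rate and out-of-arena place-cell calls behave per contract", {
  traj <- simulate_trajectory(30, 10, 50, seed = 1)
  spec0 <- place_cell_spec(peak_rate = 1, baseline_rate = 0)
  expect_length(simulate_place_cell(traj, c(40, 40), spec0, rate_scale = 0,
                                    seed = 1), 0)
  expect_error(simulate_place_cell(traj, c(90, 40), seed = 1), "arena")
})

test_that("a constant-rate cell has exponential ISIs (KS at alpha 0.01, >= 18/20 seeds)", {
  traj <- simulate_trajectory(600, 10, 50, seed = 3)
  spec <- place_cell_spec(peak_rate = 2, baseline_rate = 2)
  pass <- vapply(1:20, function(s) {
    spk <- simulate_place_cell(traj, c(40, 40), spec, seed = s)
    isi <- diff(spk)
    suppressWarnings(stats::ks.test(isi, "pexp", 1 / mean(isi))$p.value) > 0.01
  }, logical(1))
  expect_gte(sum(pass), 18)
})

test_that("bursting-cell trains have the configured rate and burst structure", {
  spec <- burst_cell_spec(mean_rate = 3, spikes_per_burst = 4)
  spk <- simulate_bursting_cell(600, spec, seed = 1)
  expect_lt(abs(length(spk) / 600 - 3) / 3, 0.25)
  expect_identical(spk, simulate_bursting_cell(600, spec, seed = 1))

  # round-trip: detect_bursts recovers the configured spikes/burst mean
  spb <- vapply(1:20, function(s) {
    detect_bursts(simulate_bursting_cell(600, spec, seed = s))$spikes_per_burst
  }, numeric(1))
  expect_lt(abs(mean(spb) - 4) / 4, 0.15)

  tiny <- simulate_bursting_cell(0.001, spec, seed = 2)
  expect_lte(length(tiny), 1)
  expect_equal(detect_bursts(tiny)$n_bursts, 0L)

  long <- simulate_bursting_cell(10 / 3 + 5, spec, seed = 3)
  expect_gte(detect_bursts(long)$n_bursts, 1L)
})

test_that("LFP synthesis hits its relative band-power targets", {
  # dark-condition profile
  spec <- lfp_spec(bands = default_bands(c(0.280, 0.314, 0.099)),
                   total_power = 4972)
  rel <- relative_band_powers(welch_psd(simulate_lfp(300, spec, seed = 1)))
  expect_true(all(abs(rel$relative - c(0.280, 0.314, 0.099)) < 0.05))

  # single-band signal concentrates nearly all power in theta
  th <- lfp_spec(bands = tibble::tibble(band = "theta", low = 5, high = 11,
                                        rel_power = 1), noise_floor = 0)
  rel_th <- relative_band_powers(welch_psd(simulate_lfp(60, th, seed = 2)))
  expect_gte(rel_th$relative[rel_th$band == "theta"], 0.95)

  # white noise only: relative powers track bandwidth fractions of 1.5-90 Hz
  wn <- lfp_spec(bands = default_bands()[0, ], noise_floor = 50)
  rel_wn <- relative_band_powers(welch_psd(simulate_lfp(300, wn, seed = 3)))
  expect_equal(rel_wn$relative, c(2.5, 6, 60) / 88.5, tolerance = 0.05)

  expect_error(lfp_spec(fs = 100, bands = default_bands(c(0.3, 0.3, 0.1))),
               "Nyquist")
})

test_that("the generated experiment encodes the configured remapping geometry", {
  out <- withr::local_tempdir()
  man <- generate_ldl_experiment(out, seed = 5, angle = 50, shift = 12.75,
                                 n_place_cells = 3, n_burst_cells = 1,
                                 duration = 20)
  expect_true(file.exists(file.path(out, "manifest.json")))
  for (lab in c("L1", "D", "L2")) {
    expect_true(file.exists(file.path(out, lab, "position.csv")))
    expect_true(file.exists(file.path(out, lab, "meta.json")))
  }
  for (u in man$units) {
    if (u$type != "place") next
    l1 <- c(u$com$L1$x, u$com$L1$y)
    d <- c(u$com$D$x, u$com$D$y)
    l2 <- c(u$com$L2$x, u$com$L2$y)
    expect_equal(com_distance(l1, d), 12.75, tolerance = 1e-9)
    expect_equal(com_distance(d, l2), 12.75, tolerance = 1e-9)
    expect_equal(l1dl2_angle(l1, d, l2), 50, tolerance = 1e-9)
  }

  # collinear configuration: D exactly between the two light fields
  out2 <- withr::local_tempdir()
  man2 <- generate_ldl_experiment(out2, seed = 6, angle = 180, shift = 10,
                                  n_place_cells = 2, n_burst_cells = 0,
                                  duration = 20)
  u <- man2$units[[1]]
  expect_equal(l1dl2_angle(c(u$com$L1$x, u$com$L1$y),
                           c(u$com$D$x, u$com$D$y),
                           c(u$com$L2$x, u$com$L2$y)), 180, tolerance = 1e-9)

  # zero angle returns the field to its light position (L2 == L1)
  out3 <- withr::local_tempdir()
  man3 <- generate_ldl_experiment(out3, seed = 7, angle = 0, shift = 10,
                                  n_place_cells = 2, n_burst_cells = 0,
                                  duration = 20)
  u3 <- man3$units[[1]]
  expect_equal(c(u3$com$L2$x, u3$com$L2$y), c(u3$com$L1$x, u3$com$L1$y),
               tolerance = 1e-9)
})
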