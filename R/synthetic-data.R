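#' Specification constructors for the synthetic L1/D/L2 experiment
#'
#' These lightweight spec objects parameterise the synthetic-data generator.
#' Defaults describe a foraging rat in an 80 x 80 cm square arena recorded
#' over three 10-minute sessions (light / dark / light), with place-cell
#' firing chosen so that session mean rates sit near 0.35 Hz in light and
#' 0.23 Hz in darkness, and bursting units firing near 3 Hz.
#'
#' @param width,height Arena extent in cm.
#' @return A named list with class `arena_spec`.
#' @examples
#' arena_spec()
#' @export
arena_spec <- function(width = 80, height = 80) {
  check_positive(width, "width")
  check_positive(height, "height")
  structure(list(width = width, height = height), class = "arena_spec")
}

as_arena <- function(arena) {
  if (inherits(arena, "arena_spec")) return(arena)
  if (is.numeric(arena) && length(arena) == 2L) {
    return(arena_spec(arena[[1]], arena[[2]]))
  }
  abort("`arena` must be an arena_spec or a numeric (width, height) pair.")
}

#' @rdname arena_spec
#' @param peak_rate Peak in-field firing rate, Hz.
#' @param field_sigma Isotropic Gaussian field width, cm. The field size is an
#'   assumption of the generator (10 cm gives fields occupying a few percent
#'   of the arena), not an empirically reported value.
#' @param baseline_rate Out-of-field firing rate, Hz.
#' @export
place_cell_spec <- function(peak_rate = 3, field_sigma = 10,
                            baseline_rate = 0.05) {
  if (!is.numeric(baseline_rate) || baseline_rate < 0) {
    abort("`baseline_rate` must be >= 0.")
  }
  if (peak_rate < baseline_rate) {
    abort("`peak_rate` must be >= `baseline_rate`.")
  }
  check_positive(field_sigma, "field_sigma")
  structure(list(peak_rate = peak_rate, field_sigma = field_sigma,
                 baseline_rate = baseline_rate), class = "place_cell_spec")
}

#' @rdname arena_spec
#' @param mean_rate Target overall firing rate of the bursting unit, Hz.
#' @param intra_burst_isi Typical within-burst inter-spike interval, ms;
#'   must stay below the 6 ms burst-detection bound.
#' @param spikes_per_burst Mean number of spikes per burst (>= 2).
#' @param inter_burst_interval Minimum gap between burst events, ms (>= 50).
#' @export
burst_cell_spec <- function(mean_rate = 3, intra_burst_isi = 3,
                            spikes_per_burst = 4,
                            inter_burst_interval = 150) {
  check_positive(mean_rate, "mean_rate")
  if (intra_burst_isi <= 0 || intra_burst_isi >= 6) {
    abort("`intra_burst_isi` must lie in (0, 6) ms.")
  }
  if (spikes_per_burst < 2) abort("`spikes_per_burst` must be >= 2.")
  if (inter_burst_interval < 50) {
    abort("`inter_burst_interval` must be >= 50 ms.")
  }
  structure(list(mean_rate = mean_rate, intra_burst_isi = intra_burst_isi,
                 spikes_per_burst = spikes_per_burst,
                 inter_burst_interval = inter_burst_interval),
            class = "burst_cell_spec")
}

#' @rdname arena_spec
#' @param fs LFP sampling rate, Hz.
#' @param bands Data frame with columns `band`, `low`, `high`, `rel_power`:
#'   target relative power of each band with respect to total power over
#'   `total_range`. Relative powers must be >= 0 and sum to <= 1.
#' @param noise_floor Broadband white-noise floor, uV rms over the full
#'   bandwidth. Kept small by default; it adds realism without perturbing
#'   the band targets (its in-band contribution is subtracted from each
#'   target).
#' @param total_power Target absolute power over `total_range`, uV^2.
#' @param total_range Frequency range defining "total" power, Hz. When the
#'   band targets sum to less than 1, the residual power is assigned to the
#'   spectral gaps between bands, split in proportion to the integral of 1/f
#'   over each gap (LFP spectra fall roughly as 1/f).
#' @export
lfp_spec <- function(fs = 250,
                     bands = default_bands(c(0.312, 0.274, 0.099)),
                     noise_floor = 3, total_power = 5000,
                     total_range = c(1.5, 90)) {
  check_positive(fs, "fs")
  check_positive(total_power, "total_power")
  bands <- as_tibble(bands)
  stopifnot(all(c("band", "low", "high", "rel_power") %in% names(bands)))
  if (nrow(bands) && any(bands$high > fs / 2)) {
    abort("Band edge above Nyquist frequency.")
  }
  if (nrow(bands) && (any(bands$rel_power < 0) || sum(bands$rel_power) > 1 + 1e-9)) {
    abort("Relative band powers must be >= 0 and sum to <= 1.")
  }
  if (noise_floor < 0) abort("`noise_floor` must be >= 0.")
  structure(list(fs = fs, bands = bands, noise_floor = noise_floor,
                 total_power = total_power, total_range = total_range),
            class = "lfp_spec")
}

#' Canonical delta/theta/gamma band table
#'
#' Delta 1.5-4 Hz, theta 5-11 Hz, gamma 30-90 Hz. Note the deliberate gaps
#' (4-5 and 11-30 Hz): relative powers over these bands do not sum to 1.
#'
#' @param rel_power Optional target relative powers (delta, theta, gamma) for
#'   use in [lfp_spec()]; defaults to zeros.
#' @return A tibble with columns `band`, `low`, `high`, `rel_power`.
#' @export
default_bands <- function(rel_power = c(0, 0, 0)) {
  tibble(band = c("delta", "theta", "gamma"),
         low = c(1.5, 5, 30), high = c(4, 11, 90),
         rel_power = rel_power)
}

#' Simulate a foraging trajectory in a rectangular arena
#'
#' Velocity follows a two-dimensional Ornstein-Uhlenbeck process (smooth,
#' mean-zero, with a ~1 s correlation time) whose stationary speed
#' distribution is Rayleigh with the requested mean; the integrated path is
#' folded back into the arena, which is equivalent to specular reflection at
#' the walls and preserves speed.
#'
#' @param duration Session length, s.
#' @param mean_speed Target mean running speed, cm/s.
#' @param sample_rate Position sampling rate, Hz.
#' @param arena An [arena_spec()] or `c(width, height)` in cm.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param tau Velocity correlation time, s.
#' @return A tibble with columns `t`, `x`, `y` (s, cm, cm) and an `arena`
#'   attribute.
#' @examples
#' traj <- simulate_trajectory(60, mean_speed = 10, seed = 1)
#' mean_speed(traj)
#' @export
simulate_trajectory <- function(duration, mean_speed = 10, sample_rate = 50,
                                arena = arena_spec(), seed = 1, tau = 1) {
  check_positive(duration, "duration")
  check_positive(mean_speed, "mean_speed")
  check_positive(sample_rate, "sample_rate")
  check_positive(tau, "tau")
  arena <- as_arena(arena)
  n <- max(2L, as.integer(round(duration * sample_rate)))
  dt <- 1 / sample_rate
  a <- exp(-dt / tau)
  sigma_v <- mean_speed * sqrt(2 / pi)   # per-component sd => Rayleigh mean
  with_seed(seed, {
    innov_sd <- sigma_v * sqrt(1 - a^2)
    vx <- stats::filter(rnorm(n, 0, innov_sd), a, method = "recursive",
                        init = rnorm(1, 0, sigma_v))
    vy <- stats::filter(rnorm(n, 0, innov_sd), a, method = "recursive",
                        init = rnorm(1, 0, sigma_v))
    x0 <- runif(1, 0.25, 0.75) * arena$width
    y0 <- runif(1, 0.25, 0.75) * arena$height
    x <- x0 + cumsum(as.numeric(vx)) * dt
    y <- y0 + cumsum(as.numeric(vy)) * dt
  })
  x <- fold_reflect(x, arena$width)
  y <- fold_reflect(y, arena$height)
  out <- tibble(t = (seq_len(n) - 1L) * dt, x = x, y = y)
  attr(out, "arena") <- arena
  out
}

# Fold an unbounded coordinate into (0, w) by the triangle wave, i.e. elastic
# reflection at 0 and w; nudged off the walls so positions are strictly inside.
fold_reflect <- function(p, w) {
  eps <- 1e-9 * w
  p <- abs(p) %% (2 * w)
  p <- w - abs(p - w)
  pmin(pmax(p, eps), w - eps)
}

trajectory_arena <- function(traj, arena = NULL) {
  arena <- arena %||% attr(traj, "arena")
  if (is.null(arena)) {
    arena <- arena_spec(max(traj$x) * 1.0000001, max(traj$y) * 1.0000001)
  }
  as_arena(arena)
}

#' Simulate a place cell as an inhomogeneous Poisson process
#'
#' The firing intensity is a baseline plus an isotropic Gaussian bump centred
#' on `field_com`, scaled by `rate_scale`:
#' \eqn{\lambda(x,y) = s\,[b + (p-b)\exp(-d^2/2\sigma^2)]}.
#' Spikes are drawn by thinning a homogeneous Poisson process at the peak
#' intensity, evaluating \eqn{\lambda} at the animal's position at each
#' candidate spike time.
#'
#' @param traj Trajectory tibble from [simulate_trajectory()].
#' @param field_com Field centre `c(x, y)` in cm; must lie inside the arena.
#' @param spec A [place_cell_spec()].
#' @param rate_scale Multiplier on the intensity (>= 0); e.g. 0.65 emulates
#'   the firing-rate drop observed in darkness.
#' @param seed Integer seed.
#' @param arena Optional arena override; defaults to the trajectory's.
#' @return Sorted numeric vector of spike times, s.
#' @examples
#' traj <- simulate_trajectory(60, seed = 1)
#' spk <- simulate_place_cell(traj, c(40, 40), seed = 2)
#' @export
simulate_place_cell <- function(traj, field_com, spec = place_cell_spec(),
                                rate_scale = 1, seed = 1, arena = NULL) {
  stopifnot(is.numeric(field_com), length(field_com) == 2L)
  if (rate_scale < 0) abort("`rate_scale` must be >= 0.")
  arena <- trajectory_arena(traj, arena)
  if (field_com[1] <= 0 || field_com[1] >= arena$width ||
      field_com[2] <= 0 || field_com[2] >= arena$height) {
    abort("`field_com` must lie strictly inside the arena.")
  }
  duration <- max(traj$t) - min(traj$t)
  lambda_max <- rate_scale * spec$peak_rate
  if (lambda_max <= 0) return(numeric(0))
  with_seed(seed, {
    n_cand <- rpois(1, lambda_max * duration)
    if (n_cand == 0) return(numeric(0))
    cand <- sort(runif(n_cand, min(traj$t), max(traj$t)))
    idx <- nearest_index(traj$t, cand)
    d2 <- (traj$x[idx] - field_com[1])^2 + (traj$y[idx] - field_com[2])^2
    lam <- rate_scale * (spec$baseline_rate +
      (spec$peak_rate - spec$baseline_rate) *
        exp(-d2 / (2 * spec$field_sigma^2)))
    keep <- runif(n_cand) < lam / lambda_max
    cand[keep]
  })
}

#' Simulate a bursting (non-spatial) unit
#'
#' Burst events form a renewal process whose inter-event intervals are the
#' minimum inter-burst interval plus an exponential tail, with the event rate
#' chosen so the overall firing rate matches `mean_rate`. Each event carries
#' `2 + Poisson(spikes_per_burst - 2)` spikes with within-burst intervals
#' jittered around `intra_burst_isi`.
#'
#' @param duration Session length, s.
#' @param spec A [burst_cell_spec()].
#' @param seed Integer seed.
#' @return Sorted numeric vector of spike times, s.
#' @export
simulate_bursting_cell <- function(duration, spec = burst_cell_spec(),
                                   seed = 1) {
  check_positive(duration, "duration")
  mean_interval <- spec$spikes_per_burst / spec$mean_rate            # s
  min_gap <- spec$inter_burst_interval / 1000                        # s
  tail_mean <- max(mean_interval - min_gap, 0.02)
  with_seed(seed, {
    # Oversample event intervals, then truncate to the session.
    n_ev <- max(10L, ceiling(2 * duration / mean_interval) + 10L)
    starts <- cumsum(min_gap + rexp(n_ev, 1 / tail_mean))
    starts <- starts[starts < duration]
    if (!length(starts)) return(numeric(0))
    spikes <- lapply(starts, function(t0) {
      k <- 2L + rpois(1, max(spec$spikes_per_burst - 2, 0))
      isis <- runif(k - 1L, 0.5, 1) * spec$intra_burst_isi / 1000
      t0 + c(0, cumsum(isis))
    })
    out <- sort(unlist(spikes))
    out[out < duration]
  })
}

#' Simulate an LFP trace with target band composition
#'
#' Spectrally shaped Gaussian noise: a white Gaussian series is transformed to
#' the frequency domain and its coefficients scaled so the expected one-sided
#' spectral density is flat within each target band (at the height giving the
#' requested relative power) plus a broadband white-noise floor. Using shaped
#' noise rather than sinusoids gives Welch estimates realistic variance.
#'
#' @param duration Trace length, s (>= 10 s recommended for spectral targets).
#' @param spec An [lfp_spec()].
#' @param seed Integer seed.
#' @return A tibble with columns `t` (s) and `uv` (microvolts) plus an `fs`
#'   attribute.
#' @export
simulate_lfp <- function(duration, spec = lfp_spec(), seed = 1) {
  check_positive(duration, "duration")
  fs <- spec$fs
  nyq <- fs / 2
  n <- as.integer(round(duration * fs))
  bands <- spec$bands
  rel_sum <- if (nrow(bands)) sum(bands$rel_power) else 0
  total <- spec$total_power
  v_n <- spec$noise_floor^2
  # Piecewise-flat target segments: each named band carries its target
  # power; the residual (1 - sum of targets) is split over the spectral
  # gaps within total_range in proportion to the integral of 1/f over each
  # gap (a 1/f-like background), so the synthesised spectrum has realistic
  # shape without leaking into the named bands.
  segs <- NULL
  if (nrow(bands)) {
    ord <- order(bands$low)
    segs <- tibble(low = bands$low[ord], high = bands$high[ord],
                   power = bands$rel_power[ord] * total)
    if (rel_sum < 1 - 1e-9) {
      edges <- c(spec$total_range[1], as.vector(rbind(segs$low, segs$high)),
                 spec$total_range[2])
      gaps <- matrix(edges, ncol = 2, byrow = TRUE)  # pre/inter/post gaps
      gaps <- gaps[gaps[, 2] - gaps[, 1] > 1e-9, , drop = FALSE]
      if (nrow(gaps)) {
        wts <- log(gaps[, 2] / gaps[, 1])
        segs <- dplyr::bind_rows(segs,
                                 tibble(low = gaps[, 1], high = gaps[, 2],
                                        power = (1 - rel_sum) * total *
                                          wts / sum(wts)))
      }
    }
  }
  freqs <- (0:(n - 1)) * fs / n
  freqs <- pmin(freqs, fs - freqs)                 # two-sided |f|
  dens2 <- rep(v_n / fs, n)                        # two-sided noise density
  if (!is.null(segs)) {
    for (i in seq_len(nrow(segs))) {
      s_b <- segs$power[i] - v_n * (segs$high[i] - segs$low[i]) / nyq
      if (s_b < -1e-9) {
        abort("Band target infeasible: noise floor alone exceeds band power.")
      }
      sel <- freqs > segs$low[i] & freqs <= segs$high[i]
      dens2[sel] <- dens2[sel] +
        max(s_b, 0) / (2 * (segs$high[i] - segs$low[i]))
    }
  }
  dens2[1] <- 0                                    # no DC component
  gain <- sqrt(fs * dens2)
  x <- with_seed(seed, {
    z <- rnorm(n)
    Re(fft(fft(z) * gain, inverse = TRUE)) / n
  })
  out <- tibble(t = (seq_len(n) - 1L) / fs, uv = x)
  attr(out, "fs") <- fs
  out
}

#' Generate a complete synthetic light/dark/light experiment on disk
#'
#' Writes three session directories (`L1`, `D`, `L2`) in the package's session
#' format (see [load_session()]) plus a `manifest.json` recording every
#' ground-truth parameter. Each simulated place cell keeps its field fixed in
#' both light sessions; in darkness the field centre is displaced by `shift`
#' cm, placed so that the angle at the dark centre between the vectors to the
#' two light centres equals `angle` (the light centre is rotated about the
#' dark centre; `angle = 0` returns the field to its light position, i.e. no
#' effective triangle). Dark firing is scaled down and the dark LFP uses a
#' higher-theta / lower-delta band profile.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed controlling every random element.
#' @param angle True L1DL2 angle at the dark field centre, degrees.
#' @param shift True L1 to D centre-of-mass displacement, cm.
#' @param n_place_cells,n_burst_cells Cohort sizes.
#' @param duration Session length, s (default three 10-min sessions).
#' @param arena An [arena_spec()].
#' @param sample_rate Position sampling rate, Hz.
#' @param mean_speed Mean running speed, cm/s.
#' @param place_spec,burst_spec Cell specs.
#' @param rate_scales Named multipliers on place-cell intensity per session.
#' @param lfp_light,lfp_dark [lfp_spec()]s used for light / dark sessions.
#' @param margin Minimum distance of any true field centre from the walls, cm.
#' @return Invisibly, the manifest as a list (also written as JSON).
#' @export
generate_ldl_experiment <- function(out_dir, seed = 1, angle = 50,
                                    shift = 12.75,
                                    n_place_cells = 20, n_burst_cells = 2,
                                    duration = 600, arena = arena_spec(),
                                    sample_rate = 50, mean_speed = 10,
                                    place_spec = place_cell_spec(),
                                    burst_spec = burst_cell_spec(),
                                    rate_scales = c(L1 = 1, D = 0.65,
                                                    L2 = 1.1),
                                    lfp_light = lfp_spec(
                                      bands = default_bands(c(0.312, 0.274, 0.099)),
                                      total_power = 5235),
                                    lfp_dark = lfp_spec(
                                      bands = default_bands(c(0.280, 0.314, 0.099)),
                                      total_power = 4972),
                                    margin = 16) {
  arena <- as_arena(arena)
  if (angle < 0 || angle > 180) abort("`angle` must be in [0, 180] degrees.")
  if (shift < 0) abort("`shift` must be >= 0.")
  sessions <- c("L1", "D", "L2")
  stopifnot(all(sessions %in% names(rate_scales)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sub_seed <- function(k) as.integer((as.numeric(seed) * 1000 + k) %% 2147483647)
  coms <- with_seed(sub_seed(1L), {
    lapply(seq_len(n_place_cells), function(i) {
      draw_com_triplet(arena, angle, shift, margin)
    })
  })
  wf_amps <- with_seed(sub_seed(2L), {
    135 * exp(rnorm(n_place_cells + n_burst_cells, 0, 0.25))
  })
  wf_widths <- with_seed(sub_seed(3L), {
    250 * exp(rnorm(n_place_cells + n_burst_cells, 0, 0.1))
  })

  unit_ids <- sprintf("u%02d", seq_len(n_place_cells + n_burst_cells))
  cell_type <- c(rep("place", n_place_cells), rep("bursting", n_burst_cells))

  for (si in seq_along(sessions)) {
    lab <- sessions[si]
    sdir <- file.path(out_dir, lab)
    dir.create(file.path(sdir, "spikes"), showWarnings = FALSE,
               recursive = TRUE)
    dir.create(file.path(sdir, "waveforms"), showWarnings = FALSE)
    dir.create(file.path(sdir, "lfp"), showWarnings = FALSE)
    traj <- simulate_trajectory(duration, mean_speed, sample_rate, arena,
                                seed = sub_seed(10L + si))
    readr::write_csv(traj, file.path(sdir, "position.csv"))
    scale <- rate_scales[[lab]]
    for (ui in seq_along(unit_ids)) {
      if (cell_type[ui] == "place") {
        com <- coms[[ui]][[lab]]
        spk <- simulate_place_cell(traj, com, place_spec, rate_scale = scale,
                                   seed = sub_seed(100L + si * 100L + ui))
      } else {
        spk <- simulate_bursting_cell(duration, burst_spec,
                                      seed = sub_seed(100L + si * 100L + ui))
        spk <- spk[spk <= max(traj$t)]   # keep within the tracked session
      }
      readr::write_csv(tibble(t = spk),
                       file.path(sdir, "spikes",
                                 paste0("unit_", unit_ids[ui], ".csv")))
      wf <- waveform_template(wf_amps[ui], wf_widths[ui], fs = 48000)
      readr::write_csv(tibble(uv = wf),
                       file.path(sdir, "waveforms",
                                 paste0("unit_", unit_ids[ui], ".csv")))
    }
    lspec <- if (lab == "D") lfp_dark else lfp_light
    lfp <- simulate_lfp(duration, lspec, seed = sub_seed(500L + si))
    readr::write_csv(lfp, file.path(sdir, "lfp", "ch1.csv"))
    meta <- list(label = lab, duration_s = duration,
                 arena = list(width = arena$width, height = arena$height),
                 position_fs = sample_rate, lfp_fs = lspec$fs,
                 waveform_fs = 48000, n_units = length(unit_ids))
    jsonlite::write_json(meta, file.path(sdir, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    seed = seed, angle_deg = angle, shift_cm = shift,
    duration_s = duration, mean_speed = mean_speed,
    arena = list(width = arena$width, height = arena$height),
    rate_scales = as.list(rate_scales),
    place_spec = unclass(place_spec), burst_spec = unclass(burst_spec),
    lfp_targets = list(
      light = list(bands = lfp_light$bands, total_power = lfp_light$total_power),
      dark = list(bands = lfp_dark$bands, total_power = lfp_dark$total_power)),
    units = purrr::map(seq_along(unit_ids), function(ui) {
      u <- list(unit_id = unit_ids[ui], type = cell_type[ui],
                waveform_amplitude_uv = wf_amps[ui],
                waveform_width_us = wf_widths[ui])
      if (cell_type[ui] == "place") {
        u$com <- lapply(coms[[ui]], function(p) list(x = p[1], y = p[2]))
      }
      u
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Draw a ground-truth (L1, D, L2) field-centre triplet
#'
#' L1 is uniform in the margin box, D is displaced from L1 by `shift` cm in
#' a random feasible direction, and L2 is L1 rotated about D by `angle`
#' degrees, so the true L1DL2 angle equals `angle` and both light-session
#' legs |D-L1| and |D-L2| equal `shift` (with `angle = 0`, L2 coincides with
#' L1: perfectly stable light fields). Uses the current RNG state; seed the
#' session (e.g. [with_seed][set.seed]) for reproducibility.
#'
#' @param arena An [arena_spec()].
#' @param angle True L1DL2 angle, degrees.
#' @param shift True |L1-D| displacement, cm.
#' @param margin Minimum distance of each centre from the walls, cm.
#' @return Named list of `L1`, `D`, `L2` coordinates `c(x, y)`.
#' @export
draw_com_triplet <- function(arena, angle, shift, margin = 16) {
  w <- arena$width; h <- arena$height
  if (2 * margin >= w || 2 * margin >= h) {
    abort("`margin` too large for the arena.")
  }
  inside <- function(p) {
    p[1] >= margin && p[1] <= w - margin && p[2] >= margin && p[2] <= h - margin
  }
  theta <- angle * pi / 180
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  for (try in 1:400) {
    l1 <- c(runif(1, margin, w - margin), runif(1, margin, h - margin))
    phi <- runif(1, 0, 2 * pi)
    d <- l1 + shift * c(cos(phi), sin(phi))
    l2 <- d + as.numeric(rot %*% (l1 - d))
    if (inside(d) && inside(l2)) {
      return(list(L1 = l1, D = d, L2 = l2))
    }
  }
  abort("Could not place a field triplet inside the arena; reduce `shift` or `margin`.")
}

#' Biphasic extracellular spike template
#'
#' A dominant negative trough followed by a smaller positive
#' after-potential, built from two Gaussian lobes. `amplitude` is the
#' trough-to-peak excursion (uV) and `width` the approximate 25%-of-amplitude
#' width (us) of the trough. Used by [generate_ldl_experiment()] to give
#' every synthetic unit a mean waveform.
#'
#' @param amplitude Peak-to-peak amplitude, uV.
#' @param width Target 25%-level width, us.
#' @param fs Sampling rate, Hz.
#' @param n Number of samples.
#' @return Numeric vector of `n` waveform samples, uV.
#' @export
waveform_template <- function(amplitude = 135, width = 250, fs = 48000,
                              n = 64) {
  t_us <- (seq_len(n) - 1) / fs * 1e6
  t_neg <- 350; t_pos <- 700
  sigma_neg <- width / (2 * sqrt(2 * log(3)))   # 25%-of-p2p crossings on trough
  sigma_pos <- 1.6 * sigma_neg
  a_neg <- 0.75 * amplitude; a_pos <- 0.25 * amplitude
  -a_neg * exp(-(t_us - t_neg)^2 / (2 * sigma_neg^2)) +
    a_pos * exp(-(t_us - t_pos)^2 / (2 * sigma_pos^2))
}
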