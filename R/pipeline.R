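#' Analysis configuration
#'
#' Collects every tunable threshold and default of the L1/D/L2 pipeline in
#' one place. Values are the package defaults: 2.5 cm bins, 0.1 s minimum
#' occupancy, occupancy-weighted 5x5 boxcar smoothing, field threshold at 20% of peak with at
#' least 9 bins, place-cell inclusion at Skaggs >= 0.5 bits/spike,
#' coherence >= 0.25 and rate >= 0.25 Hz, burst detection at ISI <= 6 ms and
#' IBI >= 50 ms, Welch with 2 s Hamming windows and 50% overlap, canonical
#' delta/theta/gamma bands, and a Shapiro normality gate at alpha = 0.05
#' choosing between the paired t and Wilcoxon signed-rank tests.
#'
#' @param ... Named overrides of any default.
#' @return A named list with class `ldl_config`.
#' @export
ldl_config <- function(...) {
  cfg <- list(
    bin_size = 2.5, min_occupancy = 0.1, smooth = TRUE, smooth_bins = 5,
    peak_fraction = 0.2, min_bins = 9,
    skaggs_min = 0.5, coherence_min = 0.25, rate_min = 0.25,
    burst_propensity_min = 0.1, burst_rate_min = 1,
    max_intra_isi = 6, min_ibi = 50,
    welch_window_s = 2, welch_overlap = 0.5,
    bands = default_bands(), total_range = c(1.5, 90),
    test = "auto", normality_alpha = 0.05,
    clip_spikes = TRUE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    abort(paste0("Unknown config option(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "ldl_config")
}

#' Load a session directory
#'
#' Reads the on-disk session layout written by [generate_ldl_experiment()]:
#' `meta.json`, `position.csv` (`t,x,y`), `spikes/unit_<id>.csv` (`t`),
#' optional `waveforms/unit_<id>.csv` (`uv`) and `lfp/ch<k>.csv` (`t,uv`).
#' All type invariants are validated on load; spike times beyond the session
#' end are clipped with a warning (or rejected with `clip = FALSE`).
#'
#' @param dir Session directory.
#' @param clip Clip out-of-session spikes (warning) instead of erroring.
#' @return A `session_bundle`: list with `label`, `meta`, `trajectory`,
#'   `units` (tibble with `unit_id`, `spikes`, `waveform` list-columns) and
#'   `lfp` (tibble with `channel`, `trace` list-columns).
#' @export
load_session <- function(dir, clip = TRUE) {
  if (!dir.exists(dir)) abort(sprintf("Session directory '%s' not found.", dir))
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) abort(sprintf("Missing meta.json in '%s'.", dir))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pos_path <- file.path(dir, "position.csv")
  if (!file.exists(pos_path)) abort(sprintf("Missing position.csv in '%s'.", dir))
  traj <- readr::read_csv(pos_path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("t", "x", "y") %in% names(traj)) || nrow(traj) < 2L) {
    abort(sprintf("Ill-formed position.csv in '%s' (need columns t,x,y).", dir))
  }
  if (any(!is.finite(traj$t)) || is.unsorted(traj$t, strictly = TRUE)) {
    abort(sprintf("position.csv in '%s': t must be strictly increasing.", dir))
  }
  arena <- arena_spec(meta$arena$width, meta$arena$height)
  if (any(traj$x < 0 | traj$x > arena$width |
          traj$y < 0 | traj$y > arena$height)) {
    abort(sprintf("position.csv in '%s': positions outside the arena.", dir))
  }
  attr(traj, "arena") <- arena

  spike_files <- sort(list.files(file.path(dir, "spikes"),
                                 pattern = "^unit_.*\\.csv$", full.names = TRUE))
  t0 <- min(traj$t); t1 <- max(traj$t)
  units <- purrr::map_dfr(spike_files, function(f) {
    id <- sub("^unit_(.*)\\.csv$", "\\1", basename(f))
    spk <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
    times <- if (nrow(spk)) as.numeric(spk$t) else numeric(0)
    if (is.unsorted(times)) {
      abort(sprintf("Spike file '%s': times must be non-decreasing.", f))
    }
    out <- sum(times < t0 | times > t1)
    if (out > 0) {
      if (!clip) abort(sprintf("Spike file '%s': %d spike(s) outside session.",
                               f, out))
      warn(sprintf("Spike file '%s': clipped %d out-of-session spike(s).",
                   f, out))
      times <- times[times >= t0 & times <= t1]
    }
    wf_path <- file.path(dir, "waveforms", basename(f))
    wf <- if (file.exists(wf_path)) {
      as.numeric(readr::read_csv(wf_path, show_col_types = FALSE,
                                 progress = FALSE)$uv)
    }
    tibble(unit_id = id, spikes = list(times), waveform = list(wf))
  })
  if (!nrow(units)) {
    units <- tibble(unit_id = character(), spikes = list(), waveform = list())
  }

  lfp_files <- sort(list.files(file.path(dir, "lfp"),
                               pattern = "^ch.*\\.csv$", full.names = TRUE))
  lfp <- purrr::map_dfr(lfp_files, function(f) {
    tr <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
    if (!all(c("t", "uv") %in% names(tr))) {
      abort(sprintf("LFP file '%s': need columns t,uv.", f))
    }
    attr(tr, "fs") <- meta$lfp_fs %||% (1 / stats::median(diff(tr$t)))
    tibble(channel = sub("\\.csv$", "", basename(f)), trace = list(tr))
  })
  if (!nrow(lfp)) lfp <- tibble(channel = character(), trace = list())

  structure(list(label = meta$label %||% basename(dir), meta = meta,
                 trajectory = traj, units = units, lfp = lfp),
            class = "session_bundle")
}

analyze_session <- function(bundle, cfg) {
  traj <- bundle$trajectory
  duration <- max(traj$t) - min(traj$t)
  wf_fs <- bundle$meta$waveform_fs %||% 48000
  per_unit <- purrr::pmap(bundle$units, function(unit_id, spikes, waveform) {
    rm <- compute_rate_map(traj, spikes, bin_size = cfg$bin_size,
                           min_occupancy = cfg$min_occupancy,
                           smooth = cfg$smooth, smooth_bins = cfg$smooth_bins)
    field <- detect_place_field(rm, cfg$peak_fraction, cfg$min_bins)
    tm <- train_metrics(spikes, duration)
    burst <- detect_bursts(spikes, cfg$max_intra_isi, cfg$min_ibi)
    skag <- tryCatch(skaggs_information(rm), error = function(e) NA_real_)
    coh <- tryCatch(spatial_coherence(rm), error = function(e) NA_real_)
    wfm <- if (!is.null(waveform)) {
      tryCatch(waveform_metrics(waveform, wf_fs),
               error = function(e) tibble(amplitude_uv = NA_real_,
                                          width_us = NA_real_))
    } else {
      tibble(amplitude_uv = NA_real_, width_us = NA_real_)
    }
    cls <- classify_unit(skag, coh, tm$mean_rate_hz, burst,
                         has_field = !is.null(field),
                         skaggs_min = cfg$skaggs_min,
                         coherence_min = cfg$coherence_min,
                         rate_min = cfg$rate_min,
                         burst_propensity_min = cfg$burst_propensity_min,
                         burst_rate_min = cfg$burst_rate_min)
    list(
      metrics = tibble(
        unit_id = unit_id, n_spikes = tm$n_spikes,
        rate_hz = tm$mean_rate_hz, isi_ms = tm$mean_isi_ms,
        amplitude_uv = wfm$amplitude_uv, width_us = wfm$width_us,
        skaggs = skag, coherence = coh,
        n_bursts = burst$n_bursts, burst_propensity = burst$propensity,
        has_field = !is.null(field),
        com_x = if (!is.null(field)) field$com[["x"]] else NA_real_,
        com_y = if (!is.null(field)) field$com[["y"]] else NA_real_,
        label = cls$label),
      rate_map = rm, field = field)
  })
  metrics <- purrr::map_dfr(per_unit, "metrics")
  band <- purrr::pmap_dfr(bundle$lfp, function(channel, trace) {
    psd <- welch_psd(trace, window_s = cfg$welch_window_s,
                     overlap_frac = cfg$welch_overlap)
    rel <- relative_band_powers(psd, cfg$bands, cfg$total_range)
    dplyr::mutate(rel, channel = channel,
                  total = total_power(psd, cfg$total_range), .before = 1)
  })
  list(label = bundle$label, speed = mean_speed(traj), metrics = metrics,
       band_powers = band,
       rate_maps = purrr::set_names(purrr::map(per_unit, "rate_map"),
                                    metrics$unit_id))
}

#' Paired comparison between two conditions
#'
#' Two-tailed paired test on matched samples. With `test = "auto"` a
#' Shapiro-Wilk check on the pair differences (at `alpha`) chooses between
#' the paired t test and the Wilcoxon signed-rank test. Degenerate inputs
#' are flagged rather than silently tested: all-zero differences give a t
#' statistic of 0 with p = 1, constant nonzero differences have no valid t
#' statistic, and the Wilcoxon errors when every difference is zero.
#'
#' @param x,y Paired numeric vectors (same length; pairs with a missing
#'   value are dropped).
#' @param test `"auto"`, `"t_paired"` or `"wilcoxon"`.
#' @param name Optional comparison label carried into the output.
#' @param alpha Normality-gate level for `"auto"`.
#' @return One-row tibble: `name`, `n`, `test`, `statistic`, `p_value`,
#'   `mean_diff`, `degenerate`.
#' @export
paired_comparison <- function(x, y, test = c("auto", "t_paired", "wilcoxon"),
                              name = NA_character_, alpha = 0.05) {
  test <- match.arg(test)
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  d <- x - y
  n <- length(d)
  if (n < 2L) abort("Need >= 2 complete pairs.")
  if (test == "auto") {
    test <- if (sd(d) == 0 || n < 3L) {
      "t_paired"
    } else if (shapiro.test(d)$p.value >= alpha) "t_paired" else "wilcoxon"
  }
  if (test == "t_paired") {
    if (sd(d) == 0) {
      if (all(d == 0)) {
        return(tibble(name = name, n = n, test = "t_paired", statistic = 0,
                      p_value = 1, mean_diff = 0, degenerate = TRUE))
      }
      return(tibble(name = name, n = n, test = "t_paired",
                    statistic = NA_real_, p_value = NA_real_,
                    mean_diff = mean(d), degenerate = TRUE))
    }
    ht <- t.test(x, y, paired = TRUE)
    tibble(name = name, n = n, test = "t_paired",
           statistic = unname(ht$statistic), p_value = ht$p.value,
           mean_diff = mean(d), degenerate = FALSE)
  } else {
    if (all(d == 0)) {
      abort("All differences are zero; the signed-rank test is degenerate.")
    }
    ht <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
    tibble(name = name, n = n, test = "wilcoxon",
           statistic = unname(ht$statistic), p_value = ht$p.value,
           mean_diff = mean(d), degenerate = FALSE)
  }
}

#' Run the full light/dark/light analysis
#'
#' For each session and unit: rate map, place field and centre of mass,
#' Skaggs information, spatial coherence, waveform, firing and burst
#' metrics, and place/bursting classification. Across sessions: the L1DL2
#' remapping summary over units with a field in all three sessions, LFP
#' band powers per channel, and paired comparisons (L1 vs D, D vs L2, L1 vs
#' L2) of rate, information, coherence, amplitude, width and relative band
#' powers. Deterministic given the inputs and configuration. No
#' multiple-comparison correction is applied to the paired tests; p-values
#' are reported unadjusted.
#'
#' @param l1,d,l2 Session directories or `session_bundle`s.
#' @param config An [ldl_config()].
#' @return An `ldl_report` object; see [tidy.ldl_report()], [write_report()].
#' @export
run_ldl_analysis <- function(l1, d, l2, config = ldl_config()) {
  cfg <- config
  bundles <- list(L1 = l1, D = d, L2 = l2)
  bundles <- purrr::map(bundles, function(b) {
    if (inherits(b, "session_bundle")) b else load_session(b, clip = cfg$clip_spikes)
  })
  sessions <- purrr::imap(bundles, function(b, lab) {
    res <- analyze_session(b, cfg)
    res$label <- lab
    res
  })
  metrics <- purrr::map_dfr(sessions, function(s) {
    dplyr::mutate(s$metrics, session = s$label, .before = 1)
  })

  # Remapping cohort: units classified as place cells in at least one
  # session, with a detected field in every session they appear in.
  place_ids <- unique(metrics$unit_id[metrics$label == "place"])
  coms <- dplyr::filter(metrics, .data$has_field,
                        .data$unit_id %in% place_ids)
  coms <- dplyr::select(coms, "unit_id", "session",
                        x = "com_x", y = "com_y")
  all_units <- unique(metrics$unit_id)
  remap <- if (nrow(coms) && length(unique(coms$session)) == 3L) {
    full <- tidyr::expand_grid(unit_id = all_units,
                               session = c("L1", "D", "L2"))
    remap_summary(dplyr::left_join(full, coms,
                                   by = c("unit_id", "session")))
  } else {
    warn("No unit has a place field in all three sessions; remapping empty.")
    remap_summary(tibble(unit_id = all_units[1] %||% "none",
                         session = c("L1", "D", "L2"),
                         x = NA_real_, y = NA_real_))
  }

  band <- purrr::map_dfr(sessions, function(s) {
    if (nrow(s$band_powers)) {
      dplyr::mutate(s$band_powers, session = s$label, .before = 1)
    } else {
      s$band_powers
    }
  })

  paired <- paired_tests_table(metrics, band, cfg)
  speeds <- tibble(session = names(sessions),
                   mean_speed_cms = purrr::map_dbl(sessions, "speed"))

  structure(list(config = cfg, metrics = metrics, remapping = remap,
                 band_powers = band, paired_tests = paired, speeds = speeds,
                 rate_maps = purrr::map(sessions, "rate_maps")),
            class = "ldl_report")
}

# All L1/D, D/L2, L1/L2 contrasts for unit metrics (paired over units
# present in both sessions) and relative band powers (paired over channels).
paired_tests_table <- function(metrics, band, cfg) {
  contrasts <- list(c("L1", "D"), c("D", "L2"), c("L1", "L2"))
  vars <- c("rate_hz", "skaggs", "coherence", "amplitude_uv", "width_us")
  rows <- list()
  for (ct in contrasts) {
    for (v in vars) {
      a <- dplyr::filter(metrics, .data$session == ct[1])
      b <- dplyr::filter(metrics, .data$session == ct[2])
      m <- dplyr::inner_join(a[c("unit_id", v)], b[c("unit_id", v)],
                             by = "unit_id", suffix = c("_a", "_b"))
      xa <- m[[paste0(v, "_a")]]; xb <- m[[paste0(v, "_b")]]
      ok <- is.finite(xa) & is.finite(xb)
      if (sum(ok) >= 2L && sd(xa[ok] - xb[ok]) >= 0) {
        row <- tryCatch(
          paired_comparison(xa[ok], xb[ok], test = cfg$test,
                            name = sprintf("%s_%s_vs_%s", v, ct[1], ct[2]),
                            alpha = cfg$normality_alpha),
          error = function(e) NULL)
        if (!is.null(row)) rows[[length(rows) + 1L]] <- row
      }
    }
    if (nrow(band)) {
      for (bn in unique(band$band)) {
        a <- dplyr::filter(band, .data$session == ct[1], .data$band == bn)
        b <- dplyr::filter(band, .data$session == ct[2], .data$band == bn)
        m <- dplyr::inner_join(a[c("channel", "relative")],
                               b[c("channel", "relative")],
                               by = "channel", suffix = c("_a", "_b"))
        if (nrow(m) >= 2L) {
          row <- tryCatch(
            paired_comparison(m$relative_a, m$relative_b, test = cfg$test,
                              name = sprintf("rel_%s_%s_vs_%s", bn, ct[1], ct[2]),
                              alpha = cfg$normality_alpha),
            error = function(e) NULL)
          if (!is.null(row)) rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble(name = character(), n = integer(), test = character(),
           statistic = numeric(), p_value = numeric(),
           mean_diff = numeric(), degenerate = logical())
}

#' Tidy / summarise an L1DL2 report
#'
#' `tidy()` returns one of the report tables; `glance()` a one-row cohort
#' summary.
#'
#' @param x An `ldl_report`.
#' @param type One of `"metrics"`, `"remapping"`, `"band_powers"`,
#'   `"paired_tests"`, `"speeds"`.
#' @param ... Unused.
#' @export
tidy.ldl_report <- function(x, type = c("metrics", "remapping", "band_powers",
                                        "paired_tests", "speeds"), ...) {
  type <- match.arg(type)
  switch(type,
         metrics = x$metrics,
         remapping = tidy(x$remapping),
         band_powers = x$band_powers,
         paired_tests = x$paired_tests,
         speeds = x$speeds)
}

#' @export
glance.ldl_report <- function(x, ...) {
  lab <- dplyr::filter(x$metrics, .data$session == "L1")
  g <- glance(x$remapping)
  tibble(n_units = length(unique(x$metrics$unit_id)),
         n_place = sum(lab$label == "place"),
         n_bursting = sum(lab$label == "bursting"),
         angle_mean_deg = g$angle_mean_deg,
         angle_sem_deg = g$angle_sem_deg,
         d_l1d_mean_cm = g$d_l1d_mean_cm,
         mean_rate_l1 = mean(lab$rate_hz))
}

#' @export
print.ldl_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0("<ldl_report> %d units (%d place, %d bursting); ",
                     "angle %.1f deg, dL1D %.1f cm\n"),
              g$n_units, g$n_place, g$n_bursting,
              g$angle_mean_deg, g$d_l1d_mean_cm))
  invisible(x)
}

#' @export
autoplot.ldl_report <- function(object, ...) {
  autoplot(object$remapping, ...)
}

#' Write an analysis report to disk
#'
#' Emits `unit_metrics.csv`, `remapping_units.csv`, `band_powers.csv`,
#' `paired_tests.csv` and `summary.json` into `out_dir`. Output is
#' deterministic: re-running on the same inputs reproduces byte-identical
#' files.
#'
#' @param report An `ldl_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(unit_metrics = "unit_metrics.csv",
             remapping = "remapping_units.csv",
             band_powers = "band_powers.csv",
             paired_tests = "paired_tests.csv")
  readr::write_csv(report$metrics, file.path(out_dir, files["unit_metrics"]))
  readr::write_csv(tidy(report$remapping),
                   file.path(out_dir, files["remapping"]))
  bp <- report$band_powers
  if (!nrow(bp)) {
    bp <- tibble(session = character(), channel = character(),
                 band = character(), absolute = numeric(),
                 relative = numeric())
  }
  readr::write_csv(bp, file.path(out_dir, files["band_powers"]))
  readr::write_csv(report$paired_tests,
                   file.path(out_dir, files["paired_tests"]))
  summary <- list(glance = glance(report),
                  remapping = glance(report$remapping),
                  speeds = report$speeds,
                  config = report$config[c("bin_size", "min_occupancy",
                                           "peak_fraction", "min_bins",
                                           "skaggs_min", "coherence_min",
                                           "rate_min", "welch_window_s",
                                           "welch_overlap")])
  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = 10,
                       na = "null")
  invisible(c(file.path(out_dir, files), json_path))
}
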