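#' Waveform amplitude and width
#'
#' Amplitude (uV) is the difference between the first positive peak and the
#' first negative peak of the mean waveform (a peak being the earliest local
#' extremum of that sign; a missing sign contributes the 0 baseline). Width
#' (us) is measured at 25% of the amplitude: the interval between the two
#' crossings of the 25%-of-amplitude level that bracket the principal
#' (larger-magnitude) peak, linearly interpolated between samples.
#'
#' @param waveform Numeric vector of mean-waveform samples, uV (>= 8).
#' @param fs Waveform sampling rate, Hz.
#' @return A tibble with columns `amplitude_uv` and `width_us`.
#' @examples
#' wf <- waveform_template(amplitude = 135, width = 250)
#' waveform_metrics(wf, fs = 48000)
#' @export
waveform_metrics <- function(waveform, fs) {
  w <- as.numeric(waveform)
  if (length(w) < 8L) abort("Need >= 8 waveform samples.")
  check_positive(fs, "fs")
  n <- length(w)
  d <- diff(w)
  is_max <- c(FALSE, d[-length(d)] > 0 & d[-1] <= 0, FALSE)
  is_min <- c(FALSE, d[-length(d)] < 0 & d[-1] >= 0, FALSE)
  pos_peaks <- which(is_max & w > 0)
  neg_peaks <- which(is_min & w < 0)
  if (!length(pos_peaks) && !length(neg_peaks)) {
    abort("Waveform has no local extrema; metrics undefined.")
  }
  v_pos <- if (length(pos_peaks)) w[pos_peaks[1]] else 0
  v_neg <- if (length(neg_peaks)) w[neg_peaks[1]] else 0
  amplitude <- v_pos - v_neg
  if (amplitude <= 0) abort("Non-positive amplitude; metrics undefined.")

  # Principal peak: larger-magnitude extremum (first one on ties).
  cand <- c(if (length(pos_peaks)) pos_peaks[1], if (length(neg_peaks)) neg_peaks[1])
  principal <- cand[which.max(abs(w[cand]))]
  level <- sign(w[principal]) * 0.25 * amplitude
  # Work on the side of the principal peak: flip so the peak is positive.
  s <- sign(w[principal])
  ws <- s * w
  lv <- s * level
  above <- ws >= lv
  if (!above[principal]) abort("Principal peak below the 25% level.")
  left <- principal
  while (left > 1L && above[left - 1L]) left <- left - 1L
  right <- principal
  while (right < n && above[right + 1L]) right <- right + 1L
  t_us <- (seq_len(n) - 1) / fs * 1e6
  t_left <- if (left == 1L) t_us[1] else {
    approx(ws[c(left - 1L, left)], t_us[c(left - 1L, left)], xout = lv)$y
  }
  t_right <- if (right == n) t_us[n] else {
    approx(ws[c(right, right + 1L)], t_us[c(right, right + 1L)], xout = lv)$y
  }
  tibble(amplitude_uv = amplitude, width_us = t_right - t_left)
}

#' Firing-rate and inter-spike-interval metrics of a spike train
#'
#' Mean firing rate is the spike count divided by the session duration; the
#' mean inter-spike interval (ms) is averaged over consecutive spike pairs
#' and is `NA` for trains with fewer than two spikes.
#'
#' @param spikes Numeric vector of spike times, s (sorted).
#' @param duration Session duration, s.
#' @return A tibble with `n_spikes`, `mean_rate_hz`, `mean_isi_ms`.
#' @export
train_metrics <- function(spikes, duration) {
  check_positive(duration, "duration")
  spikes <- as.numeric(spikes)
  n <- length(spikes)
  tibble(n_spikes = n,
         mean_rate_hz = n / duration,
         mean_isi_ms = if (n >= 2L) mean(diff(spikes)) * 1000 else NA_real_)
}

#' Detect bursts in a spike train
#'
#' A burst is a maximal run of two or more spikes whose consecutive
#' inter-spike intervals are all at most `max_intra_isi` ms. Two candidate
#' bursts separated by less than `min_ibi` ms (gap from the last spike of one
#' to the first spike of the next) are merged into a single burst event.
#'
#' @param spikes Numeric vector of spike times, s (sorted).
#' @param max_intra_isi Maximum within-burst ISI, ms.
#' @param min_ibi Minimum inter-burst interval, ms.
#' @return A `burst_summary`: tibble with `n_bursts`, `n_burst_spikes`,
#'   `spikes_per_burst` (mean), `propensity` (fraction of all spikes inside
#'   bursts) and a `burst_durations_ms` list-column.
#' @examples
#' detect_bursts(c(0, 3, 5, 100, 200) / 1000)
#' @export
detect_bursts <- function(spikes, max_intra_isi = 6, min_ibi = 50) {
  spikes <- as.numeric(spikes)
  if (is.unsorted(spikes)) abort("Spike times must be sorted.")
  n <- length(spikes)
  empty <- tibble(n_bursts = 0L, n_burst_spikes = 0L,
                  spikes_per_burst = NA_real_, propensity = 0,
                  burst_durations_ms = list(numeric(0)))
  class(empty) <- c("burst_summary", class(empty))
  if (n < 2L) return(empty)
  isi_ms <- diff(spikes) * 1000
  in_run <- isi_ms <= max_intra_isi
  # Runs of consecutive short ISIs -> candidate bursts (>= 2 spikes each).
  r <- rle(in_run)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- cbind(first = starts[r$values], last = ends[r$values] + 1L)
  if (!nrow(cand)) return(empty)
  # Merge candidates whose separating gap is < min_ibi.
  merged <- list()
  cur <- cand[1, ]
  if (nrow(cand) > 1) {
    for (k in 2:nrow(cand)) {
      gap_ms <- (spikes[cand[k, "first"]] - spikes[cur["last"]]) * 1000
      if (gap_ms < min_ibi) {
        cur["last"] <- cand[k, "last"]
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- cand[k, ]
      }
    }
  }
  merged[[length(merged) + 1L]] <- cur
  m <- do.call(rbind, merged)
  sizes <- m[, "last"] - m[, "first"] + 1L
  durations <- (spikes[m[, "last"]] - spikes[m[, "first"]]) * 1000
  out <- tibble(n_bursts = nrow(m),
                n_burst_spikes = as.integer(sum(sizes)),
                spikes_per_burst = mean(sizes),
                propensity = sum(sizes) / n,
                burst_durations_ms = list(as.numeric(durations)))
  class(out) <- c("burst_summary", class(out))
  out
}

#' Classify a unit as a place cell, bursting cell, or unclassified
#'
#' Place-cell criteria: spatial information >= `skaggs_min` (bits/spike),
#' spatial coherence >= `coherence_min`, mean firing rate >= `rate_min` Hz,
#' and a detected place field. Units failing those are labelled bursting
#' when their burst propensity and firing rate exceed the bursting-cell
#' bounds (operational defaults; both configurable); otherwise unclassified.
#'
#' @param skaggs Spatial information, bits/spike.
#' @param coherence Spatial coherence (Pearson r).
#' @param mean_rate Mean firing rate, Hz.
#' @param burst A `burst_summary` from [detect_bursts()] (or `NULL`).
#' @param has_field Logical: was a place field detected?
#' @param skaggs_min,coherence_min,rate_min Place-cell thresholds.
#' @param burst_propensity_min,burst_rate_min Bursting-cell thresholds.
#' @return A tibble with `label` and per-criterion logical columns.
#' @export
classify_unit <- function(skaggs, coherence, mean_rate, burst = NULL,
                          has_field = FALSE,
                          skaggs_min = 0.5, coherence_min = 0.25,
                          rate_min = 0.25,
                          burst_propensity_min = 0.1, burst_rate_min = 1) {
  ok <- function(x, thr) is.finite(x) && x >= thr
  crit <- tibble(
    skaggs_ok = ok(skaggs, skaggs_min),
    coherence_ok = ok(coherence, coherence_min),
    rate_ok = ok(mean_rate, rate_min),
    field_ok = isTRUE(has_field))
  propensity <- if (!is.null(burst) && nrow(burst)) burst$propensity[1] else 0
  is_place <- all(unlist(crit))
  is_burst <- !is_place && ok(propensity, burst_propensity_min) &&
    ok(mean_rate, burst_rate_min)
  dplyr::mutate(crit,
                propensity = propensity,
                label = if (is_place) "place"
                        else if (is_burst) "bursting"
                        else "unclassified",
                .before = 1)
}
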