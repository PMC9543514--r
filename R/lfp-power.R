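#' Welch power spectral density estimate
#'
#' Splits the trace into overlapping segments, removes a linear trend from
#' each, applies a Hamming window, and averages the one-sided modified
#' periodograms. Scaling is as a density (uV^2/Hz): the integral of the PSD
#' over frequency approximates the signal variance (Parseval).
#'
#' @param trace An LFP trace: either a tibble with columns `t` and `uv` (as
#'   produced by [simulate_lfp()] / [load_session()]) or a numeric vector of
#'   samples with `fs` supplied.
#' @param fs Sampling rate, Hz (taken from the trace attribute if present).
#' @param window_s Segment length, s.
#' @param overlap_frac Fractional overlap between segments, in `[0, 1)`.
#' @return A `psd` tibble with columns `freq` (Hz) and `power` (uV^2/Hz) and
#'   an `fs` attribute.
#' @examples
#' lfp <- simulate_lfp(30, lfp_spec(bands = default_bands(c(0, 1, 0)),
#'                                  noise_floor = 0), seed = 1)
#' psd <- welch_psd(lfp)
#' relative_band_powers(psd)
#' @export
welch_psd <- function(trace, fs = NULL, window_s = 2, overlap_frac = 0.5) {
  if (is.data.frame(trace)) {
    fs <- fs %||% attr(trace, "fs") %||% (1 / stats::median(diff(trace$t)))
    x <- trace$uv
  } else {
    x <- as.numeric(trace)
    if (is.null(fs)) abort("`fs` must be supplied for a bare sample vector.")
  }
  check_positive(fs, "fs")
  check_positive(window_s, "window_s")
  if (overlap_frac < 0 || overlap_frac >= 1) {
    abort("`overlap_frac` must be in [0, 1).")
  }
  nper <- as.integer(round(window_s * fs))
  if (nper > length(x)) abort("Window longer than the trace.")
  if (nper < 8L) abort("Window too short for a spectral estimate.")
  step <- max(1L, as.integer(round(nper * (1 - overlap_frac))))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nper - 1)) / (nper - 1))
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nper %/% 2L + 1L
  acc <- numeric(nfreq)
  idx0 <- seq_len(nper)
  tt <- idx0 - mean(idx0)
  stt <- sum(tt^2)
  for (s0 in starts) {
    seg <- x[s0 + idx0 - 1L]
    # linear detrend: subtract least-squares line
    beta <- sum(tt * seg) / stt
    seg <- seg - mean(seg) - beta * tt
    X <- fft(seg * w)
    p <- (Mod(X[seq_len(nfreq)])^2) * scale
    # one-sided: double everything except DC and (for even nper) Nyquist
    dbl <- rep(2, nfreq)
    dbl[1] <- 1
    if (nper %% 2L == 0L) dbl[nfreq] <- 1
    acc <- acc + p * dbl
  }
  out <- tibble(freq = (seq_len(nfreq) - 1L) * fs / nper,
                power = acc / length(starts))
  class(out) <- c("psd", class(out))
  attr(out, "fs") <- fs
  out
}

# Definite integral over [a, b] of the quadratic through (x1, y1) (centre)
# with neighbours at offsets -h0 and +h1 carrying y0, y2.
quad_piece <- function(x0, x1, x2, y0, y1, y2, a, b) {
  h0 <- x1 - x0
  h1 <- x2 - x1
  c2 <- ((y2 - y1) / h1 + (y0 - y1) / h0) / (h0 + h1)
  c1 <- ((y2 - y1) / h1 * h0 + (y1 - y0) / h0 * h1) / (h0 + h1)
  ta <- a - x1; tb <- b - x1
  y1 * (tb - ta) + c1 * (tb^2 - ta^2) / 2 + c2 * (tb^3 - ta^3) / 3
}

# Composite Simpson integration over [low, high] of a sampled function.
# Quadratic interpolants are fitted over consecutive point pairs anchored to
# the full grid (as in the classical composite rule) and integrated over
# their overlap with the band. Anchoring to the grid rather than to the band
# edges makes band integrals exactly additive under any split and weights
# every grid point consistently across different bands.
simpson_band <- function(x, y, low, high) {
  n <- length(x)
  total <- 0
  k <- 1L
  while (k + 2L <= n) {
    a <- max(low, x[k]); b <- min(high, x[k + 2L])
    if (b > a) {
      total <- total + quad_piece(x[k], x[k + 1L], x[k + 2L],
                                  y[k], y[k + 1L], y[k + 2L], a, b)
    }
    k <- k + 2L
  }
  if (k < n) {
    # trailing single interval: reuse the quadratic through the last three
    a <- max(low, x[n - 1L]); b <- min(high, x[n])
    if (b > a) {
      total <- total + quad_piece(x[n - 2L], x[n - 1L], x[n],
                                  y[n - 2L], y[n - 1L], y[n], a, b)
    }
  }
  as.numeric(total)
}

#' Absolute band power by Simpson integration of the periodogram
#'
#' Integrates the PSD over `[low, high]` with a composite Simpson rule
#' anchored to the frequency grid: each pair of grid intervals contributes
#' the integral of its quadratic interpolant over the part lying inside the
#' band, so band edges between grid points are handled exactly and
#' integrals are additive over sub-bands.
#'
#' @param psd A `psd` from [welch_psd()] (or any tibble with `freq`, `power`).
#' @param low,high Band edges, Hz; must lie within the frequency grid.
#' @return Absolute power, uV^2.
#' @export
band_power <- function(psd, low, high) {
  f <- psd$freq; p <- psd$power
  if (low >= high) abort("`low` must be < `high`.")
  if (length(f) < 3L) abort("Need >= 3 frequency grid points.")
  if (low < f[1] - 1e-9 || high > f[length(f)] + 1e-9) {
    abort("Band lies outside the frequency grid.")
  }
  simpson_band(f, p, low, high)
}

#' Total LFP power over the analysis range
#'
#' Integrates the periodogram between 1.5 and 90 Hz (by default), a range
#' chosen to exclude very low and very high frequency noise.
#'
#' @param psd A `psd`.
#' @param range Two-element frequency range, Hz.
#' @return Absolute power, uV^2.
#' @export
total_power <- function(psd, range = c(1.5, 90)) {
  band_power(psd, range[1], range[2])
}

#' Absolute and relative delta/theta/gamma band powers
#'
#' Relative power is the band's absolute power divided by the total power
#' over `total_range`. With the canonical bands (delta 1.5-4, theta 5-11,
#' gamma 30-90 Hz) the spectral gaps at 4-5 and 11-30 Hz are deliberately
#' not assigned to any band, so relative powers sum to less than 1.
#'
#' @param psd A `psd`.
#' @param bands Band table as in [default_bands()].
#' @param total_range Range defining total power, Hz.
#' @return A tibble with `band`, `low`, `high`, `absolute`, `relative`.
#' @export
relative_band_powers <- function(psd, bands = default_bands(),
                                 total_range = c(1.5, 90)) {
  tot <- total_power(psd, total_range)
  if (tot <= 0) abort("Total power is zero; relative power undefined.")
  bands <- as_tibble(bands)
  dplyr::mutate(bands[c("band", "low", "high")],
                absolute = purrr::map2_dbl(.data$low, .data$high,
                                           ~band_power(psd, .x, .y)),
                relative = .data$absolute / tot)
}

#' @export
autoplot.psd <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$freq, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = expression(PSD ~ (mu * V^2 / Hz)))
}
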