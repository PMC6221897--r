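fir_bandpass_coefs <- function(band, fs, n_signal) {
  nyq <- fs / 2
  if (band[1] <= 0 || band[2] <= band[1] || band[2] >= nyq) {
    stop("invalid band: need 0 < low < high < Nyquist (", nyq, " Hz)", call. = FALSE)
  }
  trans <- 0.25 * band[1]                     # transition width, Hz
  order <- ceiling(3.3 * fs / trans)          # Hamming window design rule
  order <- order + order %% 2                 # even order -> odd, symmetric taps
  cap <- n_signal - 1
  cap <- cap - cap %% 2
  if (order > cap) {
    warning("FIR order capped at signal length; transition band widened",
            call. = FALSE)
    order <- cap
  }
  signal::fir1(order, band / nyq, type = "pass")
}

# Zero-phase filtering of one signal with a symmetric FIR: forward and backward
# pass via FFT convolution (padded to a composite length), trimming the group
# delay after each pass. Equivalent to filtfilt for a symmetric FIR.
zero_phase_filter <- function(x, b, B = NULL, m = NULL) {
  n <- length(x)
  L <- length(b)
  half <- (L - 1) / 2
  if (is.null(m)) m <- stats::nextn(n + L - 1)
  if (is.null(B)) B <- fft(c(b, numeric(m - L)))
  conv1 <- function(v) {
    y <- Re(fft(fft(c(v, numeric(m - n))) * B, inverse = TRUE) / m)
    y[(half + 1):(half + n)]
  }
  rev(conv1(rev(conv1(x))))
}

#' Zero-phase band-pass filter an epoch set
#'
#' Applies a symmetric windowed-sinc (Hamming) FIR band-pass forward and
#' backward to every trial and channel, so the group delay is zero and phase is
#' undistorted. The filter order follows the Hamming design rule with a
#' transition width of 25% of the lower band edge, capped at the epoch length.
#'
#' @param epochs A `plv_epochs`.
#' @param band `c(low, high)` in Hz.
#' @return A `plv_epochs` with filtered data and the band recorded.
#' @export
bandpass <- function(epochs, band) {
  stopifnot(inherits(epochs, "plv_epochs"))
  b <- fir_bandpass_coefs(band, epochs$sampling_rate, dim(epochs$data)[3])
  out <- epochs
  d <- dim(epochs$data)
  m <- stats::nextn(d[3] + length(b) - 1)
  B <- fft(c(b, numeric(m - length(b))))
  for (r in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      out$data[r, ch, ] <- zero_phase_filter(epochs$data[r, ch, ], b, B = B, m = m)
    }
  }
  out$band <- band
  out
}

analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

trim_buffer_index <- function(epochs) {
  nb <- round(epochs$buffer_s * epochs$sampling_rate)
  n <- length(epochs$time_s)
  if (nb == 0) return(seq_len(n))
  (nb + 1):(n - nb)
}

#' Instantaneous phase via the Hilbert transform
#'
#' Computes the argument of the analytic signal of each (already band-limited)
#' trial x channel trace, then trims the filter buffer so that downstream bins
#' see no edge artifacts.
#'
#' @param filtered A band-passed `plv_epochs` (see [bandpass()]). Passing
#'   unfiltered broadband data triggers a warning (instantaneous phase is
#'   ill-defined for broadband signals) but is not an error.
#' @return An object of class `plv_phase`: list with `phase` (trial x channel x
#'   time array, radians in (-pi, pi]), `time_s`, `sampling_rate`,
#'   `channel_labels`, `rts_ms`, `trial_id`, `band`.
#' @export
analytic_phase <- function(filtered) {
  stopifnot(inherits(filtered, "plv_epochs"))
  if (is.null(filtered$band)) {
    warning("input epochs carry no band: instantaneous phase of broadband data is ill-defined",
            call. = FALSE)
  }
  keep <- trim_buffer_index(filtered)
  d <- dim(filtered$data)
  ph <- array(0, dim = c(d[1], d[2], length(keep)))
  for (r in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      a <- analytic_signal(filtered$data[r, ch, ])
      ph[r, ch, ] <- Arg(a[keep])
    }
  }
  structure(
    list(phase = ph, time_s = filtered$time_s[keep],
         sampling_rate = filtered$sampling_rate,
         channel_labels = filtered$channel_labels,
         rts_ms = filtered$rts_ms, trial_id = filtered$trial_id,
         band = filtered$band),
    class = "plv_phase"
  )
}

bin_sample_index <- function(time_s, bin_ms) {
  which(time_s >= bin_ms[1] / 1000 - 1e-9 & time_s < bin_ms[2] / 1000 - 1e-9)
}

check_bins <- function(bins_ms) {
  if (is.numeric(bins_ms) && is.null(dim(bins_ms))) bins_ms <- matrix(bins_ms, nrow = 1)
  bins_ms <- as.matrix(bins_ms)
  stopifnot(ncol(bins_ms) == 2, all(bins_ms[, 2] > bins_ms[, 1]))
  bins_ms
}

#' Band power per trial, time bin and channel
#'
#' Power is the time-average of the squared analytic-signal amplitude divided
#' by two, which equals the mean squared signal for a narrowband input (a unit
#' sinusoid has power 0.5). The filter buffer is trimmed before binning; bins
#' are half-open `[start, end)` in ms relative to cue.
#'
#' @param filtered A band-passed `plv_epochs`.
#' @param bins_ms Matrix (or single pair) of bin edges in ms.
#' @return A trial x bin x channel numeric array.
#' @export
band_power <- function(filtered, bins_ms) {
  stopifnot(inherits(filtered, "plv_epochs"))
  bins_ms <- check_bins(bins_ms)
  keep <- trim_buffer_index(filtered)
  time_s <- filtered$time_s[keep]
  idx <- lapply(seq_len(nrow(bins_ms)), function(b) bin_sample_index(time_s, bins_ms[b, ]))
  if (any(vapply(idx, length, 0L) == 0)) {
    stop("bin outside epoch time range", call. = FALSE)
  }
  d <- dim(filtered$data)
  out <- array(0, dim = c(d[1], nrow(bins_ms), d[2]))
  for (r in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      amp2 <- Mod(analytic_signal(filtered$data[r, ch, ])[keep])^2
      for (b in seq_len(nrow(bins_ms))) {
        out[r, b, ch] <- mean(amp2[idx[[b]]]) / 2
      }
    }
  }
  out
}

#' z-score a trial x bin x channel tensor across trials
#'
#' For each (bin, channel) cell the trial dimension is standardised with the
#' sample (n-1) standard deviation. Cells with zero variance across trials get
#' z = 0 with a warning.
#'
#' @param power trial x bin x channel array (>= 3 trials).
#' @return Array of the same shape in z-units.
#' @export
zscore_across_trials <- function(power) {
  d <- dim(power)
  stopifnot(length(d) == 3)
  if (d[1] < 3) stop("need at least 3 trials to z-score", call. = FALSE)
  out <- power
  zero_var <- 0L
  for (b in seq_len(d[2])) {
    for (ch in seq_len(d[3])) {
      v <- power[, b, ch]
      s <- stats::sd(v)
      if (s == 0) {
        out[, b, ch] <- 0
        zero_var <- zero_var + 1L
      } else {
        out[, b, ch] <- (v - mean(v)) / s
      }
    }
  }
  if (zero_var > 0) {
    warning(zero_var, " (bin, channel) cell(s) had zero variance across trials; z set to 0",
            call. = FALSE)
  }
  out
}

#' Spectral tilt: high-band minus low-band z-scored power
#'
#' @param hfa_z,low_z Same-shaped z-scored power tensors (see
#'   [zscore_across_trials()]).
#' @return Elementwise difference `hfa_z - low_z`.
#' @export
spectral_tilt <- function(hfa_z, low_z) {
  if (!identical(dim(hfa_z), dim(low_z))) {
    stop("shape mismatch between high- and low-band tensors", call. = FALSE)
  }
  hfa_z - low_z
}

#' Spectral baseline features (HFA and spectral tilt)
#'
#' Convenience wrapper: band-pass the epochs in the high-gamma and low bands,
#' compute binned analytic-amplitude power, z-score each band across trials per
#' (bin, channel), and form the tilt (high minus low).
#'
#' @param epochs Unfiltered `plv_epochs`.
#' @param bins_ms Bin edge matrix in ms.
#' @param gamma_band,low_band Bands in Hz.
#' @param log_power Take log of power before z-scoring (default `FALSE`).
#' @return List of class `plv_spectral` with trial x bin x channel arrays
#'   `hfa_z`, `low_z`, `tilt`, plus `bins_ms` and `channel_labels`.
#' @export
spectral_features <- function(epochs, bins_ms, gamma_band = c(70, 100),
                              low_band = c(3, 12), log_power = FALSE) {
  bins_ms <- check_bins(bins_ms)
  p_hi <- band_power(bandpass(epochs, gamma_band), bins_ms)
  p_lo <- band_power(bandpass(epochs, low_band), bins_ms)
  if (log_power) {
    p_hi <- log(p_hi)
    p_lo <- log(p_lo)
  }
  hfa_z <- zscore_across_trials(p_hi)
  low_z <- zscore_across_trials(p_lo)
  structure(
    list(hfa_z = hfa_z, low_z = low_z, tilt = spectral_tilt(hfa_z, low_z),
         bins_ms = bins_ms, channel_labels = epochs$channel_labels),
    class = "plv_spectral"
  )
}
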