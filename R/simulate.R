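#' Configuration for the synthetic sEEG session generator
#'
#' Defines the study conditions emulated by [simulate_session()]: a cued
#' delayed-reaction task recorded from many intracranial contacts, with
#' band-limited high-gamma oscillations whose inter-channel phase coupling is
#' controlled per trial by a coupling parameter `kappa` in \[0, 1\], a low-band
#' oscillation, 1/f background noise, and reaction times generated as a
#' decreasing linear function of the pre-cue coupling plus Gaussian noise.
#'
#' Coupling is injected only in the pre-cue window (-500..0 ms relative to
#' cue); the coupling in the delay period is drawn independently of the
#' reaction time, so only pre-cue features carry behavioural signal by
#' construction.
#'
#' @param n_channels Number of recording channels (network nodes).
#' @param n_trials Number of trials.
#' @param sampling_rate Sampling rate in Hz; must be at least 2.5 times the
#'   upper gamma band edge.
#' @param delay_options Instructed delay durations in ms, chosen per trial
#'   with equal probability. Must be a subset of `c(500, 1500)`.
#' @param gamma_band,low_band Frequency bands in Hz as `c(low, high)` pairs.
#' @param coupling_range Range of the per-trial coupling parameter `kappa`
#'   (uniformly sampled), a subinterval of \[0, 1\].
#' @param phase_jitter_map How the coupling `kappa` maps to the von Mises
#'   concentration of each channel's phase jitter around the trial-common
#'   oscillator. `"plv"` (default) inverts the squared mean resultant length so
#'   that the population pairwise PLV equals `kappa` — the coupling parameter
#'   then directly controls the quantity the pipeline estimates. `"linear"`
#'   uses concentration `kappa * kappa_max`.
#' @param kappa_max von Mises concentration at `kappa = 1` under the linear
#'   map.
#' @param jitter_hold_ms Duration over which each channel's phase jitter is
#'   held before an independent von Mises redraw. Phase slips in band-limited
#'   field potentials occur at the oscillation-cycle timescale, not per sample;
#'   holding the jitter for about two carrier cycles (default 25 ms) also
#'   keeps the injected concentration from being averaged away by the analysis
#'   band-pass filter, so the coupling parameter directly controls the PLV the
#'   pipeline estimates.
#' @param rt_intercept,rt_slope,rt_noise_sd Reaction-time model in ms:
#'   `RT = rt_intercept - rt_slope * kappa + N(0, rt_noise_sd)`.
#' @param rt_floor Lower truncation of generated reaction times, ms.
#' @param background_exponent Spectral exponent of the 1/f background
#'   (power spectral density proportional to `1/f^background_exponent`).
#' @param background_rms RMS amplitude of the background, in µV.
#' @param gamma_amp_meanlog,gamma_amp_sdlog Per-trial, per-channel gamma
#'   oscillation amplitude is lognormal with these parameters (µV scale);
#'   drawing amplitude independently of `kappa` dissociates power-based from
#'   phase-coupling-based features by construction.
#' @param low_amp Amplitude of the low-band oscillation, µV.
#' @param iti_s Inter-trial interval (keypress to next cue), seconds.
#' @param pad_s Recording padding before the first cue and after the last
#'   keypress, seconds.
#' @param seed Integer seed; with a fixed seed the generated session is
#'   bit-reproducible.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_channels = 4, n_trials = 8, sampling_rate = 500)
#' sess <- simulate_session(cfg)
#' sess$ground_truth
sim_config <- function(n_channels = 122,
                       n_trials = 120,
                       sampling_rate = 1000,
                       delay_options = c(500, 1500),
                       gamma_band = c(70, 100),
                       low_band = c(3, 12),
                       coupling_range = c(0, 1),
                       phase_jitter_map = c("plv", "linear"),
                       kappa_max = 20,
                       jitter_hold_ms = 25,
                       rt_intercept = 450,
                       rt_slope = 200,
                       rt_noise_sd = 100,
                       rt_floor = 100,
                       background_exponent = 1,
                       background_rms = 1,
                       gamma_amp_meanlog = log(2),
                       gamma_amp_sdlog = 0.4,
                       low_amp = 2,
                       iti_s = 1,
                       pad_s = 2,
                       seed = 1L) {
  if (n_channels < 1 || n_trials < 1) {
    stop("invalid config: n_channels and n_trials must be positive", call. = FALSE)
  }
  if (!all(delay_options %in% c(500, 1500)) || length(delay_options) < 1) {
    stop("invalid config: delay_options must be drawn from {500, 1500} ms", call. = FALSE)
  }
  if (sampling_rate < 2 * gamma_band[2] * 1.25) {
    stop("aliasing: sampling_rate must be at least 2.5x the upper gamma edge", call. = FALSE)
  }
  if (coupling_range[1] < 0 || coupling_range[2] > 1 || diff(coupling_range) < 0) {
    stop("invalid config: coupling_range must lie within [0, 1]", call. = FALSE)
  }
  if (rt_intercept - rt_slope * coupling_range[2] <= 0 && rt_floor <= 0) {
    stop("invalid config: RT model admits non-positive reaction times", call. = FALSE)
  }
  cfg <- list(
    n_channels = as.integer(n_channels), n_trials = as.integer(n_trials),
    sampling_rate = sampling_rate, delay_options = delay_options,
    gamma_band = gamma_band, low_band = low_band,
    coupling_range = coupling_range,
    phase_jitter_map = match.arg(phase_jitter_map), kappa_max = kappa_max,
    jitter_hold_ms = jitter_hold_ms,
    rt_intercept = rt_intercept, rt_slope = rt_slope,
    rt_noise_sd = rt_noise_sd, rt_floor = rt_floor,
    background_exponent = background_exponent, background_rms = background_rms,
    gamma_amp_meanlog = gamma_amp_meanlog, gamma_amp_sdlog = gamma_amp_sdlog,
    low_amp = low_amp, iti_s = iti_s, pad_s = pad_s, seed = seed
  )
  structure(cfg, class = "sim_config")
}

# Best-Fisher rejection sampler for the von Mises(0, kappa) distribution,
# vectorised in n. kappa near 0 degenerates to the uniform distribution.
rvonmises <- function(n, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- max(16L, ceiling((n - got) / 0.6))
    z <- cos(pi * runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- runif(m)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    f <- f[keep]
    if (length(f) > 0) {
      take <- min(length(f), n - got)
      f <- f[seq_len(take)]
      sgn <- ifelse(runif(take) < 0.5, -1, 1)
      out[got + seq_len(take)] <- sgn * acos(pmax(pmin(f, 1), -1))
      got <- got + take
    }
  }
  out
}

# Fisher's approximation to the inverse of A1(c) = I1(c)/I0(c), the von Mises
# mean resultant length as a function of concentration.
a1inv <- function(R) {
  ifelse(R < 0.53, 2 * R + R^3 + 5 * R^5 / 6,
         ifelse(R < 0.85, -0.4 + 1.39 * R + 0.43 / (1 - R),
                1 / (R^3 - 4 * R^2 + 3 * R)))
}

# kappa -> von Mises jitter concentration under the configured map. Under the
# "plv" map the population pairwise PLV, |E exp(i(d_i - d_j))| = A1(c)^2,
# equals kappa.
jitter_concentration <- function(kappa, map = "plv", kappa_max = 20) {
  if (map == "linear") return(kappa * kappa_max)
  R <- sqrt(pmin(pmax(kappa, 0), 1 - 1e-9))
  conc <- a1inv(R)
  conc[kappa <= 0] <- 0
  pmin(conc, 1e8)
}

# von Mises jitter held constant over blocks of hold_samples (cycle-scale
# phase slips); hold_samples = 1 gives iid per-sample jitter.
held_jitter <- function(n, kappa, hold_samples) {
  if (hold_samples <= 1) return(rvonmises(n, kappa))
  nb <- ceiling(n / hold_samples)
  rep(rvonmises(nb, kappa), each = hold_samples)[seq_len(n)]
}

# 1/f^alpha coloured noise of length n via FFT spectral shaping of white noise,
# normalised to unit RMS.
colored_noise <- function(n, exponent) {
  w <- rnorm(n)
  if (exponent == 0) return(w / stats::sd(w))
  m <- stats::nextn(n)       # composite FFT length, truncated back to n
  W <- fft(c(w, numeric(m - n)))
  k <- 0:(m - 1)
  f <- pmin(k, m - k)        # symmetric frequency index; DC handled below
  f[1] <- 1
  shape <- f^(-exponent / 2)
  shape[1] <- 0              # remove DC
  x <- Re(fft(W * shape, inverse = TRUE) / m)[seq_len(n)]
  x / stats::sd(x)
}

#' Simulate a synthetic sEEG session with controllable phase coupling
#'
#' Generates a continuous multichannel recording, an event table for a cued
#' delayed-reaction task, and the generating ground truth. Each channel is the
#' sum of 1/f background noise, a low-band oscillation, and a gamma-band
#' oscillation whose instantaneous phase equals a trial-common oscillator phase
#' plus per-sample von Mises jitter whose concentration increases with the
#' trial's coupling `kappa` (pre-cue window) or with an independently drawn
#' coupling (delay window). Reaction times decrease linearly in the pre-cue
#' `kappa`.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `recording` (a `plv_recording`), `events`
#'   (a tibble with columns `trial_id`, `cue_time_s`, `delay_ms`, `go_time_s`,
#'   `keypress_time_s`) and `ground_truth` (a tibble with `trial_id`, `kappa`,
#'   `rt_ms`, `delay_ms`).
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$sampling_rate
  nt <- config$n_trials
  nc <- config$n_channels

  delays <- if (length(config$delay_options) == 1) {
    rep(config$delay_options, nt)
  } else {
    sample(config$delay_options, nt, replace = TRUE)
  }
  kappa <- runif(nt, config$coupling_range[1], config$coupling_range[2])
  kappa_delay <- runif(nt, config$coupling_range[1], config$coupling_range[2])
  rt <- config$rt_intercept - config$rt_slope * kappa +
    rnorm(nt, 0, config$rt_noise_sd)
  rt <- pmax(rt, config$rt_floor)
  gamma_amp <- matrix(
    stats::rlnorm(nt * nc, config$gamma_amp_meanlog, config$gamma_amp_sdlog),
    nrow = nt, ncol = nc
  )

  # event timeline, cue times snapped to the sample grid
  cue <- numeric(nt)
  t_cursor <- config$pad_s
  for (i in seq_len(nt)) {
    cue[i] <- round(t_cursor * fs) / fs
    t_cursor <- cue[i] + delays[i] / 1000 + rt[i] / 1000 + config$iti_s
  }
  go <- cue + delays / 1000
  keypress <- go + rt / 1000
  dur <- keypress[nt] + config$pad_s
  n_samples <- ceiling(dur * fs)
  tvec <- (0:(n_samples - 1)) / fs

  # per-sample von Mises concentration: kappa-controlled pre-cue, independent
  # coupling during the delay, uncoupled elsewhere
  # the pre-cue coupling state onsets one margin before the analysis window so
  # that band-pass filter bleed from the uncoupled inter-trial period does not
  # contaminate the pre-cue bin
  margin <- 0.1
  conc <- numeric(n_samples)
  for (i in seq_len(nt)) {
    pre <- floor((cue[i] - 0.5 - margin) * fs) + 1
    cue_idx <- floor(cue[i] * fs) + 1
    del_end <- floor(go[i] * fs)
    conc[pre:(cue_idx - 1)] <-
      jitter_concentration(kappa[i], config$phase_jitter_map, config$kappa_max)
    conc[cue_idx:del_end] <-
      jitter_concentration(kappa_delay[i], config$phase_jitter_map, config$kappa_max)
  }
  seg <- rle(conc)
  seg_end <- cumsum(seg$lengths)
  seg_start <- seg_end - seg$lengths + 1

  # per-sample gamma amplitude per channel, per-trial lognormal in the coupled
  # window, baseline elsewhere
  amp_base <- exp(config$gamma_amp_meanlog)
  f_gamma <- mean(config$gamma_band)
  f_low <- mean(config$low_band)
  theta_common <- 2 * pi * f_gamma * tvec

  hold <- max(1L, round(config$jitter_hold_ms / 1000 * fs))
  data <- matrix(0, nrow = nc, ncol = n_samples)
  for (ch in seq_len(nc)) {
    jit <- numeric(n_samples)
    for (s in seq_along(seg$lengths)) {
      jit[seg_start[s]:seg_end[s]] <-
        held_jitter(seg$lengths[s], seg$values[s], hold)
    }
    amp <- rep(amp_base, n_samples)
    for (i in seq_len(nt)) {
      a <- floor((cue[i] - 0.5) * fs) + 1
      b <- floor(go[i] * fs)
      amp[a:b] <- gamma_amp[i, ch]
    }
    gamma_sig <- amp * cos(theta_common + jit)
    low_sig <- config$low_amp * cos(2 * pi * f_low * tvec + runif(1, 0, 2 * pi))
    bg <- config$background_rms * colored_noise(n_samples, config$background_exponent)
    data[ch, ] <- gamma_sig + low_sig + bg
  }

  labels <- sprintf("CH%03d", seq_len(nc))
  recording <- new_recording(data, fs, labels)
  events <- tibble::tibble(
    trial_id = seq_len(nt),
    cue_time_s = cue,
    delay_ms = delays,
    go_time_s = go,
    keypress_time_s = keypress
  )
  ground_truth <- tibble::tibble(
    trial_id = seq_len(nt),
    kappa = kappa,
    rt_ms = rt,
    delay_ms = delays
  )
  list(recording = recording, events = events, ground_truth = ground_truth)
}

#' Trial-common coupled phase traces
#'
#' Generates the phase model used by [simulate_session()] directly: for each
#' trial a common oscillator phase (constant angular frequency) plus iid
#' per-sample von Mises jitter on every channel with concentration
#' `kappa * kappa_max`. Useful for testing phase-locking estimators against a
#' known coupling level without the full signal model.
#'
#' @param n_trials,n_channels,n_samples Tensor dimensions.
#' @param kappa Coupling level in \[0, 1\] (scalar or per-trial vector).
#' @param phase_jitter_map,kappa_max Map from `kappa` to jitter concentration,
#'   as in [sim_config()].
#' @param freq_hz,sampling_rate Oscillator frequency and sampling rate.
#' @param hold_samples Samples per independent jitter draw; 1 (default) gives
#'   iid per-sample jitter.
#' @return A trial x channel x time array of phases wrapped to (-pi, pi].
#' @export
coupled_phases <- function(n_trials, n_channels, n_samples, kappa,
                           phase_jitter_map = "plv", kappa_max = 20,
                           freq_hz = 85, sampling_rate = 1000,
                           hold_samples = 1) {
  kappa <- rep_len(kappa, n_trials)
  conc <- jitter_concentration(kappa, phase_jitter_map, kappa_max)
  ph <- array(0, dim = c(n_trials, n_channels, n_samples))
  base <- 2 * pi * freq_hz * (0:(n_samples - 1)) / sampling_rate
  for (r in seq_len(n_trials)) {
    for (ch in seq_len(n_channels)) {
      ph[r, ch, ] <- wrap_phase(
        base + held_jitter(n_samples, conc[r], hold_samples))
    }
  }
  ph
}

wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi   # map -pi to pi so values lie in (-pi, pi]
  y
}

#' Write a session to disk (EDF signal + CSV tables)
#'
#' @param recording A `plv_recording`.
#' @param events Event tibble as produced by [simulate_session()].
#' @param path Output directory (created if missing).
#' @param ground_truth Optional ground-truth tibble; written alongside when given.
#' @return Invisibly, a named character vector of the written file paths.
#' @export
write_session <- function(recording, events, path, ground_truth = NULL) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", path, call. = FALSE)
  }
  edf_path <- file.path(path, "recording.edf")
  ev_path <- file.path(path, "events.csv")
  write_edf(recording, edf_path)
  readr::write_csv(events, ev_path)
  files <- c(edf = edf_path, events = ev_path)
  if (!is.null(ground_truth)) {
    gt_path <- file.path(path, "ground_truth.csv")
    readr::write_csv(ground_truth, gt_path)
    files <- c(files, ground_truth = gt_path)
  }
  invisible(files)
}
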