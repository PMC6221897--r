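# Wrap a raw trial x channel x time phase array as a plv_phase object.
phase_tensor <- function(ph, fs = 1000, t0_s = 0, band = c(70, 100)) {
  d <- dim(ph)
  structure(
    list(phase = ph, time_s = t0_s + (0:(d[3] - 1)) / fs, sampling_rate = fs,
         channel_labels = sprintf("CH%03d", seq_len(d[2])),
         rts_ms = rep(300, d[1]), trial_id = seq_len(d[1]), band = band),
    class = "plv_phase"
  )
}

# One bin covering a whole phase tensor, in ms.
full_bin <- function(ph_obj) {
  matrix(c(ph_obj$time_s[1], ph_obj$time_s[length(ph_obj$time_s)] +
             1 / ph_obj$sampling_rate) * 1000, nrow = 1)
}

# Naive double-loop PLV implementation: the independent oracle for
# single_trial_plv.
plv_naive <- function(ph) {
  d <- dim(ph)
  out <- array(0, dim = c(d[1], d[2], d[2]))
  for (r in seq_len(d[1])) {
    for (i in seq_len(d[2])) {
      for (j in seq_len(d[2])) {
        if (i == j) next
        s <- 0 + 0i
        for (t in seq_len(d[3])) {
          s <- s + exp(1i * (ph[r, i, t] - ph[r, j, t]))
        }
        out[r, i, j] <- Mod(s / d[3])
      }
    }
  }
  out
}

# Monte-Carlo oracle for the chance-level PLV of T iid uniform-phase unit
# vectors: returns the mean and sd of |mean of T unit phasors| over n_draws.
plv_chance_oracle <- function(T, n_draws = 1e4) {
  vals <- vapply(seq_len(n_draws), function(i) {
    Mod(mean(exp(1i * runif(T, -pi, pi))))
  }, 0)
  list(mean = mean(vals), sd = stats::sd(vals))
}

# Truncated power-series matrix exponential: oracle for communicability.
expm_series <- function(m, k_max = 30) {
  acc <- diag(nrow(m))
  term <- diag(nrow(m))
  for (k in seq_len(k_max)) {
    term <- term %*% m / k
    acc <- acc + term
  }
  acc
}

# Small epochs object holding given per-trial/channel signals.
signal_epochs <- function(data, fs = 1000, t0_s = -0.5, buffer_s = 0,
                          band = NULL) {
  d <- dim(data)
  structure(
    list(data = data, time_s = t0_s + (0:(d[3] - 1)) / fs, sampling_rate = fs,
         channel_labels = sprintf("CH%03d", seq_len(d[2])),
         rts_ms = rep(300, d[1]), trial_id = seq_len(d[1]), delay_ms = 1500,
         window_s = c(t0_s + buffer_s, t0_s + d[3] / fs - buffer_s),
         buffer_s = buffer_s, band = band),
    class = "plv_epochs"
  )
}

# Simulate a small session and run it through epoching, gamma phase and PLV.
mini_session_features <- function(cfg, bins_ms = default_bins(), qexp = FALSE) {
  s <- simulate_session(cfg)
  ep <- epoch_trials(s$recording, s$events)
  ph <- analytic_phase(bandpass(ep, cfg$gamma_band))
  fe <- network_features(single_trial_plv(ph, bins_ms), qexp = qexp)
  list(session = s, epochs = ep, features = fe)
}
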