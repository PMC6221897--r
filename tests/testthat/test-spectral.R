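sine_epochs <- function(freq, amp = 1, fs = 1000, n = 2000, n_ch = 1,
                        phase = 0, buffer_s = 0.25) {
  t <- (0:(n - 1)) / fs
  data <- array(0, dim = c(1, n_ch, n))
  for (ch in seq_len(n_ch)) data[1, ch, ] <- amp * cos(2 * pi * freq * t + phase)
  signal_epochs(data, fs = fs, t0_s = 0, buffer_s = buffer_s)
}

central <- function(x, frac = 0.6) {
  n <- length(x)
  drop <- floor(n * (1 - frac) / 2)
  x[(drop + 1):(n - drop)]
}

test_that("the band-pass keeps in-band sinusoids and rejects out-of-band ones", {
  ep <- sine_epochs(85)
  filt <- bandpass(ep, c(70, 100))
  amp_ratio <- max(abs(central(filt$data[1, 1, ]))) / 1
  expect_lt(abs(amp_ratio - 1), 0.05)

  ep10 <- sine_epochs(10)
  filt10 <- bandpass(ep10, c(70, 100))
  in_rms <- sqrt(mean(central(ep10$data[1, 1, ])^2))
  out_rms <- sqrt(mean(central(filt10$data[1, 1, ])^2))
  expect_lt(out_rms / in_rms, 0.01)

  zero <- sine_epochs(85, amp = 0)
  expect_equal(max(abs(bandpass(zero, c(70, 100))$data)), 0, tolerance = 1e-12)

  expect_error(bandpass(ep, c(400, 600)), "Nyquist")
})

test_that("instantaneous phase advances at the oscillation frequency", {
  ep <- sine_epochs(80, buffer_s = 0.25)
  ep$band <- c(70, 100)   # already narrowband by construction
  ph <- analytic_phase(ep)
  unwrapped <- plvnet:::wrap_phase(ph$phase[1, 1, ])
  d <- diff(unwrapped)
  d[d < -pi] <- d[d < -pi] + 2 * pi
  slope <- mean(d) * ep$sampling_rate / (2 * pi)
  expect_lt(abs(slope - 80) / 80, 0.001)
})

test_that("sin and cos at one frequency differ by a constant phase of pi/2", {
  fs <- 1000
  n <- 2000
  t <- (0:(n - 1)) / fs
  data <- array(0, dim = c(1, 2, n))
  data[1, 1, ] <- cos(2 * pi * 80 * t)
  data[1, 2, ] <- sin(2 * pi * 80 * t)
  ep <- signal_epochs(data, fs = fs, t0_s = 0, buffer_s = 0.25, band = c(70, 100))
  ph <- analytic_phase(ep)
  dphi <- plvnet:::wrap_phase(ph$phase[1, 1, ] - ph$phase[1, 2, ])
  expect_lt(max(abs(dphi - pi / 2)), 0.01)
})

test_that("amplitude modulation does not change the phase slope of the carrier", {
  fs <- 1000
  n <- 2000
  t <- (0:(n - 1)) / fs
  carrier <- array(cos(2 * pi * 80 * t), dim = c(1, 1, n))
  modulated <- array((1 + 0.5 * cos(2 * pi * 2 * t)) * cos(2 * pi * 80 * t),
                     dim = c(1, 1, n))
  ep_c <- signal_epochs(carrier, fs = fs, t0_s = 0, buffer_s = 0.25, band = c(70, 100))
  ep_m <- signal_epochs(modulated, fs = fs, t0_s = 0, buffer_s = 0.25, band = c(70, 100))
  ph_c <- analytic_phase(ep_c)$phase[1, 1, ]
  ph_m <- analytic_phase(ep_m)$phase[1, 1, ]
  dphi <- plvnet:::wrap_phase(ph_m - ph_c)
  expect_lt(max(abs(dphi)), 0.01)
})

test_that("unfiltered broadband input triggers a warning, not an error", {
  set.seed(3)
  ep <- signal_epochs(array(rnorm(1000), dim = c(1, 1, 1000)), buffer_s = 0)
  expect_warning(analytic_phase(ep), "broadband")
})

test_that("band power follows the closed form and the amplitude scaling law", {
  ep <- sine_epochs(85, buffer_s = 0.25)
  ep$band <- c(70, 100)
  bins <- matrix(c(250, 1500), 1)   # relative to t0 = 0, within the trimmed range
  ep$time_s <- ep$time_s - 0        # time axis starts at 0
  p <- band_power(ep, bins)
  expect_lt(abs(p[1, 1, 1] - 0.5) / 0.5, 0.02)

  zero <- sine_epochs(85, amp = 0)
  zero$band <- c(70, 100)
  expect_equal(band_power(zero, bins)[1, 1, 1], 0)

  double <- sine_epochs(85, amp = 2, buffer_s = 0.25)
  double$band <- c(70, 100)
  expect_equal(band_power(double, bins)[1, 1, 1] / p[1, 1, 1], 4,
               tolerance = 1e-9)

  expect_error(band_power(ep, matrix(c(5000, 6000), 1)), "outside")
})

test_that("z-scoring across trials uses the sample sd and is permutation equivariant", {
  p <- array(0, dim = c(3, 1, 1))
  p[, 1, 1] <- c(1, 2, 3)
  expect_equal(zscore_across_trials(p)[, 1, 1], c(-1, 0, 1))

  const <- array(7, dim = c(4, 2, 2))
  expect_warning(z <- zscore_across_trials(const), "zero variance")
  expect_true(all(z == 0))

  set.seed(13)
  p2 <- array(runif(5 * 2 * 3), dim = c(5, 2, 3))
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(zscore_across_trials(p2[perm, , , drop = FALSE]),
               zscore_across_trials(p2)[perm, , , drop = FALSE])

  expect_error(zscore_across_trials(p2[1:2, , , drop = FALSE]), "3 trials")
})

test_that("spectral tilt is the elementwise difference and is antisymmetric", {
  h <- array(1, dim = c(2, 2, 2))
  l <- array(-1, dim = c(2, 2, 2))
  expect_true(all(spectral_tilt(h, h) == 0))
  expect_true(all(spectral_tilt(h, l) == 2))
  expect_equal(spectral_tilt(h, l), -spectral_tilt(l, h))
  expect_error(spectral_tilt(h, array(0, dim = c(2, 2, 3))), "mismatch")
})

test_that("phase of a channel with itself gives PLV exactly 1", {
  set.seed(23)
  cfg <- sim_config(n_channels = 2, n_trials = 3, sampling_rate = 500,
                    delay_options = 1500, seed = 5)
  s <- simulate_session(cfg)
  ep <- epoch_trials(s$recording, s$events)
  ph <- analytic_phase(bandpass(ep, c(70, 100)))
  dup <- ph
  dup$phase <- array(ph$phase[, c(1, 1), , drop = FALSE],
                     dim = c(dim(ph$phase)[1], 2, dim(ph$phase)[3]))
  conn <- single_trial_plv(dup, default_bins())
  expect_equal(max(abs(conn$plv[, , 1, 2] - 1)), 0, tolerance = 1e-12)
})

test_that("filtering and phase extraction commute with trial reordering", {
  set.seed(33)
  data <- array(rnorm(4 * 2 * 600), dim = c(4, 2, 600))
  ep <- signal_epochs(data, fs = 1000, t0_s = -0.1, buffer_s = 0.1)
  perm <- c(3, 1, 4, 2)
  ep_perm <- ep
  ep_perm$data <- ep$data[perm, , , drop = FALSE]
  a <- analytic_phase(bandpass(ep, c(70, 100)))$phase
  b <- analytic_phase(bandpass(ep_perm, c(70, 100)))$phase
  expect_equal(b, a[perm, , , drop = FALSE], tolerance = 1e-12)
})
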