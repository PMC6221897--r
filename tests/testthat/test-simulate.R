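small_cfg <- function(...) {
  sim_config(n_channels = 3, n_trials = 10, sampling_rate = 500,
             delay_options = 1500, seed = 101, ...)
}

test_that("config validation rejects impossible study conditions", {
  expect_error(sim_config(n_trials = 0), "positive")
  expect_error(sim_config(n_channels = -2), "positive")
  expect_error(sim_config(sampling_rate = 200), "aliasing")
  expect_error(sim_config(delay_options = c(500, 700)), "500, 1500")
  expect_error(sim_config(coupling_range = c(-0.2, 1)), "coupling_range")
})

test_that("simulated sessions honour the ground-truth invariants", {
  s <- simulate_session(sim_config(n_channels = 3, n_trials = 40,
                                   sampling_rate = 500, seed = 7))
  gt <- s$ground_truth
  expect_equal(nrow(gt), 40)
  expect_true(all(gt$kappa >= 0 & gt$kappa <= 1))
  expect_true(all(gt$rt_ms > 0))
  expect_true(all(gt$delay_ms %in% c(500, 1500)))
  expect_equal(s$events$go_time_s, s$events$cue_time_s + s$events$delay_ms / 1000)
  expect_equal(s$events$keypress_time_s - s$events$go_time_s, gt$rt_ms / 1000)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  a <- simulate_session(small_cfg())
  b <- simulate_session(small_cfg())
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$events, b$events)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("channel spectra peak inside both configured bands", {
  cfg <- sim_config(n_channels = 1, n_trials = 12, sampling_rate = 500,
                    delay_options = 1500, coupling_range = c(0.7, 1), seed = 17)
  s <- simulate_session(cfg)
  sp <- stats::spec.pgram(stats::ts(s$recording$data[1, ], frequency = 500),
                          spans = 25, plot = FALSE, taper = 0)
  band_mean <- function(lo, hi) mean(sp$spec[sp$freq >= lo & sp$freq < hi])
  expect_gt(band_mean(70, 100) / band_mean(105, 135), 2)
  expect_gt(band_mean(3, 12) / band_mean(15, 24), 2)
})

test_that("full coupling yields near-perfect downstream pre-cue PLV", {
  # low-noise setting isolates the coupling mechanism (the claim is about the
  # phase model, not the 1/f noise floor)
  cfg <- sim_config(n_channels = 4, n_trials = 8, sampling_rate = 500,
                    delay_options = 1500, coupling_range = c(1, 1),
                    background_rms = 0.1, low_amp = 0.5, seed = 27)
  out <- mini_session_features(cfg)
  expect_true(all(out$features$nodal_strength[, 1, ] > 0.99))
})

test_that("with a flat RT model kappa does not predict reaction time", {
  n_sig <- 0L
  for (i in 1:20) {
    cfg <- sim_config(n_channels = 1, n_trials = 30, sampling_rate = 500,
                      delay_options = 1500, rt_slope = 0, seed = 1000 + i)
    gt <- simulate_session(cfg)$ground_truth
    p <- stats::cor.test(gt$kappa, gt$rt_ms)$p.value
    if (p < 0.05) n_sig <- n_sig + 1L
  }
  expect_gte(20 - n_sig, 18)   # non-significant in at least 90% of runs
})

test_that("written sessions round-trip exactly through the readers", {
  s <- simulate_session(small_cfg())
  dir <- withr::local_tempdir()
  files <- write_session(s$recording, s$events, dir, s$ground_truth)
  expect_true(all(file.exists(files)))

  rec <- read_edf(files["edf"])
  ev <- read_events(files["events"])
  expect_equal(rec$channel_labels, s$recording$channel_labels)
  ep <- epoch_trials(rec, ev)
  expect_equal(ep$rts_ms, s$ground_truth$rt_ms)   # RT recovered exactly

  # deterministic writer: a second write is byte-identical
  dir2 <- withr::local_tempdir()
  files2 <- write_session(s$recording, s$events, dir2, s$ground_truth)
  expect_identical(readLines(files[["events"]]), readLines(files2[["events"]]))
  expect_identical(readBin(files[["edf"]], "raw", file.size(files[["edf"]])),
                   readBin(files2[["edf"]], "raw", file.size(files2[["edf"]])))
})

test_that("epoched gamma phase tracks the generator's common oscillator at full coupling", {
  cfg <- sim_config(n_channels = 2, n_trials = 4, sampling_rate = 500,
                    delay_options = 1500, coupling_range = c(1, 1),
                    background_rms = 0.2, seed = 37)
  s <- simulate_session(cfg)
  ep <- epoch_trials(s$recording, s$events)
  ph <- analytic_phase(bandpass(ep, cfg$gamma_band))
  fs <- 500
  f_gamma <- mean(cfg$gamma_band)
  for (r in 1:4) {
    # predicted common phase at the epoch's absolute sample times
    cue <- s$events$cue_time_s[s$events$trial_id == ph$trial_id[r]]
    abs_t <- cue + ph$time_s
    predicted <- 2 * pi * f_gamma * abs_t
    resultant <- Mod(mean(exp(1i * (ph$phase[r, 1, ] - predicted))))
    expect_gt(resultant, 0.95)
  }
})
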