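#' Configuration for the end-to-end analysis pipeline
#'
#' Exactly one input source must be given: either a simulator configuration or
#' paths to an EDF recording plus a CSV event table.
#'
#' @param simulation A [sim_config()], or `NULL` when reading from files.
#' @param edf_path,events_path Input file paths, or `NULL` when simulating.
#' @param gamma_band,low_band Analysis bands in Hz.
#' @param window_s Epoch window relative to cue (s).
#' @param buffer_s Filter buffer on each side (s), trimmed after phase/power
#'   extraction.
#' @param bins_ms Analysis bin edges (ms), default the four contiguous 500-ms
#'   bins from pre-cue to late delay.
#' @param delay_filter_ms Analyse only trials with this instructed delay.
#' @param alpha Family-wise significance level for the bin-wise contrasts.
#' @param ranksum_sided Sidedness of the bin-wise strength rank-sum contrasts.
#' @param decoder List: `enabled`, `k` folds, `n_perm`, `null`
#'   (`"bernoulli"`/`"permute"`), `channel` (designated communicability
#'   channel index, or `NULL` to pick the maximum fast-slow |t| channel).
#' @param seed Integer seed controlling all randomness downstream of the input.
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulation = sim_config(),
                       edf_path = NULL, events_path = NULL,
                       gamma_band = c(70, 100), low_band = c(3, 12),
                       window_s = c(-0.5, 1.5), buffer_s = 0.5,
                       bins_ms = default_bins(), delay_filter_ms = 1500,
                       alpha = 0.05, ranksum_sided = "two",
                       decoder = list(enabled = TRUE, k = 10, n_perm = 1000,
                                      null = "bernoulli", channel = NULL),
                       seed = 1L) {
  from_files <- !is.null(edf_path) || !is.null(events_path)
  if (from_files && (is.null(edf_path) || is.null(events_path))) {
    stop("both edf_path and events_path are required to read from files", call. = FALSE)
  }
  if (from_files) simulation <- NULL
  if (is.null(simulation) && !from_files) {
    stop("exactly one of simulation or (edf_path, events_path) must be given", call. = FALSE)
  }
  bins_ms <- check_bins(bins_ms)
  o <- order(bins_ms[, 1])
  if (any(bins_ms[o, ][-1, 1] < bins_ms[o, ][-nrow(bins_ms), 2])) {
    stop("bins must be non-overlapping and ordered", call. = FALSE)
  }
  dec_defaults <- list(enabled = TRUE, k = 10, n_perm = 1000,
                       null = "bernoulli", channel = NULL)
  decoder <- utils::modifyList(dec_defaults, decoder)
  structure(
    list(simulation = simulation, edf_path = edf_path, events_path = events_path,
         gamma_band = gamma_band, low_band = low_band, window_s = window_s,
         buffer_s = buffer_s, bins_ms = bins_ms,
         delay_filter_ms = delay_filter_ms, alpha = alpha,
         ranksum_sided = ranksum_sided, decoder = decoder,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full network control-signal analysis
#'
#' Orchestrates input (simulation or files), epoching, high-gamma PLV network
#' construction, network and spectral features, the trial partition, the
#' statistical battery (bin-wise fast/slow strength contrasts with Bonferroni
#' threshold, pre-cue per-node contrasts for nodal strength, HFA and spectral
#' tilt, an early/late control contrast, strength-RT and communicability-RT
#' correlations) and the permutation-tested decoder.
#'
#' @param config A [run_config()].
#' @param session Optional pre-simulated session (as returned by
#'   [simulate_session()]); when supplied, the input stage is skipped so
#'   upstream results need not be recomputed.
#' @return Object of class `plv_run`: list with `config`, `partition`,
#'   `netfeat`, `spectral`, tables `binwise`, `nodal`, `correlations`,
#'   `qexp_by_channel`, `decoder`, `designated_channel`, `log`, and
#'   `ground_truth` when simulated.
#' @export
run_pipeline <- function(config, session = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  ground_truth <- NULL

  # stage: input
  if (!is.null(session) || !is.null(config$simulation)) {
    if (is.null(session)) session <- simulate_session(config$simulation)
    recording <- session$recording
    events <- session$events
    ground_truth <- session$ground_truth
    say("input: simulated session, %d channels, %d events",
        nrow(recording$data), nrow(events))
  } else {
    recording <- read_edf(config$edf_path)
    events <- read_events(config$events_path)
    say("input: %s, %d channels, %d events",
        config$edf_path, nrow(recording$data), nrow(events))
  }

  # stage: epoch
  epochs <- epoch_trials(recording, events, window_s = config$window_s,
                         delay_filter_ms = config$delay_filter_ms,
                         buffer_s = config$buffer_s)
  n_trials <- dim(epochs$data)[1]
  say("epoch: %d trials retained at delay %d ms", n_trials, config$delay_filter_ms)

  # stage: connectivity + network features
  phases <- analytic_phase(bandpass(epochs, config$gamma_band))
  conn <- single_trial_plv(phases, config$bins_ms)
  netfeat <- network_features(conn)
  say("features: PLV networks in %d bins; strength and communicability computed",
      nrow(config$bins_ms))

  # stage: spectral baselines
  spec <- spectral_features(epochs, config$bins_ms,
                            gamma_band = config$gamma_band,
                            low_band = config$low_band)

  # stage: statistics
  part <- partition_terciles(epochs$rts_ms)
  fast <- part$performance_class == "fast"
  slow <- part$performance_class == "slow"
  say("partition: %d fast, %d slow of %d trials", sum(fast), sum(slow), n_trials)

  rt_contrast <- rank_sum(epochs$rts_ms[fast], epochs$rts_ms[slow],
                          sided = "one", direction = "less")

  nb <- nrow(config$bins_ms)
  thr <- bonferroni(config$alpha, nb)
  binwise <- purrr::map_dfr(seq_len(nb), function(b) {
    rs <- rank_sum(netfeat$global_strength[fast, b],
                   netfeat$global_strength[slow, b],
                   sided = config$ranksum_sided, direction = "greater")
    tibble::tibble(bin = bin_names(config$bins_ms)[b],
                   z = rs$statistic, p_value = rs$p_value)
  })
  binwise$corrected_threshold <- thr
  binwise$significant <- binwise$p_value < thr

  labels <- as.character(part$performance_class)
  pre <- 1L
  nodal <- list(
    strength = nodal_contrast_t(netfeat$nodal_strength[, pre, ], labels),
    hfa = nodal_contrast_t(spec$hfa_z[, pre, ], labels),
    tilt = nodal_contrast_t(spec$tilt[, pre, ], labels),
    early_late = nodal_contrast_t(netfeat$nodal_strength[, pre, ],
                                  as.character(part$order_class),
                                  levels = c("late", "early")),
    qexp = nodal_contrast_t(netfeat$nodal_qexp[, pre, ], labels)
  )
  nodal_tbl <- purrr::map_dfr(names(nodal), function(nm) {
    d <- nodal[[nm]]
    d$metric <- nm
    d$channel_label <- epochs$channel_labels[d$channel]
    d
  })

  designated <- config$decoder$channel
  if (is.null(designated)) designated <- attr(nodal$qexp, "max_channel")
  say("designated communicability channel: %s (max |t| fast-slow contrast)",
      epochs$channel_labels[designated])

  corr_strength <- correlate_rt(netfeat$global_strength[, pre], epochs$rts_ms)
  corr_qexp <- correlate_rt(netfeat$nodal_qexp[, pre, designated], epochs$rts_ms)
  correlations <- tibble::tibble(
    feature = c("pre_cue_global_strength",
                paste0("pre_cue_qexp_", epochs$channel_labels[designated])),
    r = c(corr_strength$r, corr_qexp$r),
    df = c(corr_strength$df, corr_qexp$df),
    p_value = c(corr_strength$p_value, corr_qexp$p_value)
  )
  qexp_by_channel <- purrr::map_dfr(seq_along(epochs$channel_labels), function(ch) {
    cr <- correlate_rt(netfeat$nodal_qexp[, pre, ch], epochs$rts_ms)
    tibble::tibble(channel = ch, channel_label = epochs$channel_labels[ch],
                   r = cr$r, p_value = cr$p_value)
  })

  # stage: decoder
  dec <- NULL
  if (isTRUE(config$decoder$enabled)) {
    feats <- decoder_features(netfeat, part, designated, bin = pre)
    dec <- permutation_test(feats, k = config$decoder$k,
                            n_perm = config$decoder$n_perm,
                            null = config$decoder$null, seed = config$seed)
    say("decoder: AUC = %.3f, permutation p = %.4g", dec$auc, dec$p_value)
  } else {
    say("decoder: disabled")
  }

  structure(
    list(config = config, n_trials = n_trials,
         channel_labels = epochs$channel_labels,
         partition = part, rt_contrast = rt_contrast, binwise = binwise,
         nodal = nodal_tbl, correlations = correlations,
         qexp_by_channel = qexp_by_channel,
         designated_channel = designated, decoder = dec,
         netfeat = netfeat, spectral = spec,
         ground_truth = ground_truth, log = log),
    class = "plv_run"
  )
}

#' @export
print.plv_run <- function(x, ...) {
  cat("<plv_run>\n")
  cat(sprintf("  %d trials analysed, %d channels\n",
              x$n_trials, length(x$channel_labels)))
  cat(sprintf("  RT fast vs slow: z = %.2f, one-sided p = %.3g\n",
              x$rt_contrast$statistic, x$rt_contrast$p_value))
  cat(sprintf("  pre-cue strength fast vs slow: z = %.2f, p = %.3g (threshold %.4g)\n",
              x$binwise$z[1], x$binwise$p_value[1], x$binwise$corrected_threshold[1]))
  cat(sprintf("  pre-cue strength vs RT: r = %.2f, p = %.3g\n",
              x$correlations$r[1], x$correlations$p_value[1]))
  if (!is.null(x$decoder)) {
    cat(sprintf("  decoder: AUC = %.3f, permutation p = %.4g\n",
                x$decoder$auc, x$decoder$p_value))
  }
  invisible(x)
}
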