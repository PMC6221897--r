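config_echo <- function(config) {
  sim <- config$simulation
  list(
    seed = config$seed,
    gamma_band = config$gamma_band, low_band = config$low_band,
    window_s = config$window_s, buffer_s = config$buffer_s,
    bins_ms = apply(config$bins_ms, 1, function(r) unname(r), simplify = FALSE),
    delay_filter_ms = config$delay_filter_ms, alpha = config$alpha,
    ranksum_sided = config$ranksum_sided,
    decoder = config$decoder[c("enabled", "k", "n_perm", "null")],
    input = if (is.null(sim)) {
      list(edf = config$edf_path, events = config$events_path)
    } else {
      list(simulation = unclass(sim))
    },
    config_hash = rlang::hash(unclass(config))
  )
}

#' Write the report bundle of a pipeline run
#'
#' Emits the analysis tables as CSV, the decoder result and config echo as
#' JSON, the permutation null distribution as CSV, and a plain-text summary in
#' narrative order. Two runs differing only in output path produce identical
#' table contents.
#'
#' @param run A `plv_run` from [run_pipeline()].
#' @param path Output directory (created if missing).
#' @return Invisibly, the vector of written file paths.
#' @export
write_report <- function(run, path) {
  stopifnot(inherits(run, "plv_run"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", path, call. = FALSE)
  }
  files <- character(0)
  wcsv <- function(x, name) {
    p <- file.path(path, name)
    readr::write_csv(x, p)
    files <<- c(files, p)
  }
  wcsv(run$partition, "partition.csv")
  wcsv(run$binwise, "stats_binwise.csv")
  wcsv(run$nodal, "stats_nodal.csv")
  wcsv(run$correlations, "correlations.csv")
  wcsv(run$qexp_by_channel, "qexp_rt_by_channel.csv")

  echo <- config_echo(run$config)
  jsonlite::write_json(echo, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, file.path(path, "config.json"))

  if (!is.null(run$decoder)) {
    d <- run$decoder
    jsonlite::write_json(
      list(auc = d$auc, p_value = d$p_value, folds = d$folds,
           n_perm = d$n_perm, seed = d$seed, null = d$null,
           features = d$feature_names, n_trials = d$n_trials,
           redraws = d$redraws),
      file.path(path, "decoder.json"), auto_unbox = TRUE, digits = NA)
    wcsv(tibble::tibble(perm = seq_along(d$null_aucs), auc = d$null_aucs),
         "decoder_null_aucs.csv")
    files <- c(files, file.path(path, "decoder.json"))
  }

  sm <- file.path(path, "summary.txt")
  lines <- c(
    "Network control-signal analysis summary",
    sprintf("config hash: %s; seed: %d", echo$config_hash, run$config$seed),
    sprintf("trials analysed (delay %d ms): %d", run$config$delay_filter_ms,
            run$n_trials),
    sprintf("fast/slow tercile sizes: %d/%d",
            sum(run$partition$performance_class == "fast"),
            sum(run$partition$performance_class == "slow")),
    sprintf("RT fast vs slow (one-sided rank sum): z = %.3f, p = %.3g",
            run$rt_contrast$statistic, run$rt_contrast$p_value),
    sprintf("bin-wise global strength contrasts (%d tests, Bonferroni threshold %.4g):",
            nrow(run$binwise), run$binwise$corrected_threshold[1]),
    sprintf("  %s: z = %.3f, p = %.3g%s", run$binwise$bin, run$binwise$z,
            run$binwise$p_value, ifelse(run$binwise$significant, " *", "")),
    sprintf("designated communicability channel: %s",
            run$channel_labels[run$designated_channel]),
    sprintf("%s vs RT: r = %.3f, p = %.3g", run$correlations$feature,
            run$correlations$r, run$correlations$p_value),
    if (!is.null(run$decoder)) {
      sprintf("decoder (%d-fold SVM, %d null draws): AUC = %.3f, p = %.4g",
              run$decoder$folds, run$decoder$n_perm, run$decoder$auc,
              run$decoder$p_value)
    } else "decoder: disabled",
    "", "log:", paste(" ", run$log)
  )
  writeLines(lines, sm)
  files <- c(files, sm)
  invisible(files)
}
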