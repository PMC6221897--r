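#' Read a trial event table
#'
#' Expects a CSV with columns `trial_id`, `cue_time_s`, `delay_ms`,
#' `go_time_s`, `keypress_time_s`. The reaction time (RT, ms) is derived as
#' keypress minus go. Rows with a keypress at or before the go signal are
#' invalid (negative RT) and excluded with a warning. Rows are returned sorted
#' by cue time.
#'
#' @param path CSV file path.
#' @return A tibble with the input columns plus `rt_ms`.
#' @export
read_events <- function(path) {
  ev <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_double()))
  required <- c("trial_id", "cue_time_s", "delay_ms", "go_time_s", "keypress_time_s")
  missing <- setdiff(required, names(ev))
  if (length(missing) > 0) {
    stop("event table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ev$rt_ms <- (ev$keypress_time_s - ev$go_time_s) * 1000
  bad <- ev$rt_ms <= 0 | is.na(ev$rt_ms)
  if (any(bad)) {
    warning(sum(bad), " trial(s) excluded: keypress at or before go signal",
            call. = FALSE)
    ev <- ev[!bad, , drop = FALSE]
  }
  ev[order(ev$cue_time_s), , drop = FALSE]
}

#' Epoch a continuous recording around cue onset
#'
#' Cuts one epoch per event row whose delay matches `delay_filter_ms`. Times
#' are in seconds with the cue at 0 and half-open sample bins: the epoch covers
#' samples in `[cue + window[1] - buffer, cue + window[2] + buffer)`. The
#' buffer is retained in the output so that downstream filtering can trim its
#' edge artifacts; phase/power extraction removes it.
#'
#' @param recording A `plv_recording`.
#' @param events Event tibble from [read_events()] or [simulate_session()]
#'   (must carry `rt_ms`; if absent it is derived).
#' @param window_s Epoch window relative to cue, seconds, e.g. `c(-0.5, 1.5)`.
#' @param delay_filter_ms Keep only trials with this instructed delay (ms).
#' @param buffer_s Extra seconds kept on each side for filter edge handling.
#' @return An object of class `plv_epochs`: list with `data` (trial x channel
#'   x time array), `time_s` (relative to cue, includes the buffer),
#'   `sampling_rate`, `channel_labels`, `rts_ms`, `trial_id`, `delay_ms`,
#'   `window_s`, `buffer_s`.
#' @export
epoch_trials <- function(recording, events, window_s = c(-0.5, 1.5),
                         delay_filter_ms = 1500, buffer_s = 0.5) {
  stopifnot(inherits(recording, "plv_recording"))
  if (!"rt_ms" %in% names(events)) {
    events$rt_ms <- (events$keypress_time_s - events$go_time_s) * 1000
  }
  keep <- events$delay_ms == delay_filter_ms & events$rt_ms > 0
  ev <- events[keep, , drop = FALSE]
  fs <- recording$sampling_rate
  n_time <- ncol(recording$data)
  n_samp <- round((window_s[2] - window_s[1] + 2 * buffer_s) * fs)

  starts <- floor((ev$cue_time_s + window_s[1] - buffer_s) * fs + 1e-9) + 1
  in_bounds <- starts >= 1 & (starts + n_samp - 1) <= n_time
  if (any(!in_bounds)) {
    warning(sum(!in_bounds),
            " trial(s) dropped: epoch window exceeds recording bounds",
            call. = FALSE)
    ev <- ev[in_bounds, , drop = FALSE]
    starts <- starts[in_bounds]
  }
  if (nrow(ev) == 0) {
    stop("no trials retained after delay filtering and bounds checks", call. = FALSE)
  }

  nc <- nrow(recording$data)
  data <- array(0, dim = c(nrow(ev), nc, n_samp))
  for (i in seq_len(nrow(ev))) {
    data[i, , ] <- recording$data[, starts[i]:(starts[i] + n_samp - 1)]
  }
  time_s <- window_s[1] - buffer_s + (0:(n_samp - 1)) / fs

  structure(
    list(data = data, time_s = time_s, sampling_rate = fs,
         channel_labels = recording$channel_labels,
         rts_ms = ev$rt_ms, trial_id = ev$trial_id, delay_ms = delay_filter_ms,
         window_s = window_s, buffer_s = buffer_s, band = NULL),
    class = "plv_epochs"
  )
}

#' @export
print.plv_epochs <- function(x, ...) {
  cat(sprintf("<plv_epochs> %d trials x %d channels x %d samples @ %g Hz",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sampling_rate))
  if (!is.null(x$band)) cat(sprintf(" [band %g-%g Hz]", x$band[1], x$band[2]))
  cat("\n")
  invisible(x)
}
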