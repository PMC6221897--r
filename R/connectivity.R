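#' Default analysis time bins
#'
#' The four contiguous 500-ms bins used throughout: pre-cue (-500..0 ms),
#' early delay (0..500), mid delay (500..1000) and late delay (1000..1500),
#' relative to cue onset, half-open.
#'
#' @return A 4 x 2 matrix of bin edges in ms with informative row names.
#' @export
default_bins <- function() {
  m <- rbind(c(-500, 0), c(0, 500), c(500, 1000), c(1000, 1500))
  rownames(m) <- c("pre_cue", "early_delay", "mid_delay", "late_delay")
  colnames(m) <- c("start_ms", "end_ms")
  m
}

#' Single-trial phase-locking-value networks in time bins
#'
#' For trial r, bin b and channel pair (i, j) the PLV is the magnitude of the
#' time-averaged unit phasor of the phase difference,
#' `| mean_t exp(1i * (phi_i(t) - phi_j(t))) |`, over the T samples in the bin.
#' The result is symmetric by construction with the diagonal set to 0 (no
#' self-edges), all values in \[0, 1\].
#'
#' @param phases A `plv_phase` object (see [analytic_phase()]).
#' @param bins_ms Matrix of half-open bin edges in ms relative to cue, one row
#'   per bin (default [default_bins()]). Each bin must contain at least 32
#'   samples and lie within the trimmed epoch.
#' @return Object of class `plv_conn`: list with `plv` (trial x bin x channel x
#'   channel array), `bins_ms`, `band`, `channel_labels`, `rts_ms`, `trial_id`.
#' @export
single_trial_plv <- function(phases, bins_ms = default_bins()) {
  stopifnot(inherits(phases, "plv_phase"))
  bins_ms <- check_bins(bins_ms)
  nb <- nrow(bins_ms)
  idx <- lapply(seq_len(nb), function(b) bin_sample_index(phases$time_s, bins_ms[b, ]))
  n_in_bin <- vapply(idx, length, 0L)
  if (any(n_in_bin < 32)) {
    stop("bin(s) with fewer than 32 samples: ",
         paste(which(n_in_bin < 32), collapse = ", "), call. = FALSE)
  }
  d <- dim(phases$phase)
  nt <- d[1]; nc <- d[2]
  if (anyNA(phases$phase)) {
    bad <- which(apply(is.na(phases$phase), c(1, 2), any), arr.ind = TRUE)
    warning("NaN phases propagate to PLV for trial/channel: ",
            paste(apply(bad, 1, paste, collapse = "/"), collapse = "; "),
            call. = FALSE)
  }
  plv <- array(0, dim = c(nt, nb, nc, nc))
  for (r in seq_len(nt)) {
    for (b in seq_len(nb)) {
      z <- exp(1i * phases$phase[r, , idx[[b]], drop = FALSE])
      dim(z) <- c(nc, length(idx[[b]]))
      m <- Mod(z %*% Conj(t(z))) / length(idx[[b]])
      m <- (m + t(m)) / 2
      diag(m) <- 0
      plv[r, b, , ] <- m
    }
  }
  structure(
    list(plv = plv, bins_ms = bins_ms, band = phases$band,
         channel_labels = phases$channel_labels,
         rts_ms = phases$rts_ms, trial_id = phases$trial_id),
    class = "plv_conn"
  )
}

#' @export
print.plv_conn <- function(x, ...) {
  d <- dim(x$plv)
  cat(sprintf("<plv_conn> %d trials x %d bins x %d x %d channels\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}
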