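#' Tidy the permutation-null distribution of a decoder result
#'
#' @param x A `plv_decoder`.
#' @param ... Unused.
#' @return Tibble with one row per null draw: `perm`, `null_auc`.
#' @method tidy plv_decoder
#' @export
tidy.plv_decoder <- function(x, ...) {
  tibble::tibble(perm = seq_along(x$null_aucs), null_auc = x$null_aucs)
}

#' One-row summary of a decoder result
#'
#' @param x A `plv_decoder`.
#' @param ... Unused.
#' @return Tibble with `auc`, `p_value`, `folds`, `n_perm`, `n_trials`, `seed`.
#' @method glance plv_decoder
#' @export
glance.plv_decoder <- function(x, ...) {
  tibble::tibble(auc = x$auc, p_value = x$p_value, folds = x$folds,
                 n_perm = x$n_perm, n_trials = x$n_trials, seed = x$seed)
}

#' Tidy the headline statistics of a pipeline run
#'
#' @param x A `plv_run`.
#' @param ... Unused.
#' @return Tibble with one row per reported test: `test`, `scope`,
#'   `statistic`, `p_value`.
#' @method tidy plv_run
#' @export
tidy.plv_run <- function(x, ...) {
  rows <- list(
    tibble::tibble(test = "rank_sum_rt_fast_vs_slow", scope = "behaviour",
                   statistic = x$rt_contrast$statistic,
                   p_value = x$rt_contrast$p_value),
    tibble::tibble(test = paste0("rank_sum_strength_", x$binwise$bin),
                   scope = "global_strength", statistic = x$binwise$z,
                   p_value = x$binwise$p_value),
    tibble::tibble(test = paste0("pearson_", x$correlations$feature),
                   scope = "single_trial", statistic = x$correlations$r,
                   p_value = x$correlations$p_value)
  )
  if (!is.null(x$decoder)) {
    rows <- c(rows, list(tibble::tibble(
      test = "decoder_auc", scope = "decoder",
      statistic = x$decoder$auc, p_value = x$decoder$p_value)))
  }
  dplyr::bind_rows(rows)
}

#' One-row summary of a pipeline run
#'
#' @param x A `plv_run`.
#' @param ... Unused.
#' @return Tibble with trial counts, the pre-cue contrast, the strength-RT
#'   correlation and the decoder result.
#' @method glance plv_run
#' @export
glance.plv_run <- function(x, ...) {
  tibble::tibble(
    n_trials = x$n_trials,
    n_channels = length(x$channel_labels),
    precue_strength_z = x$binwise$z[1],
    precue_strength_p = x$binwise$p_value[1],
    strength_rt_r = x$correlations$r[1],
    strength_rt_p = x$correlations$p_value[1],
    decoder_auc = if (is.null(x$decoder)) NA_real_ else x$decoder$auc,
    decoder_p = if (is.null(x$decoder)) NA_real_ else x$decoder$p_value
  )
}
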