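#' Plot global network strength per time bin, split by performance class
#'
#' @param object A `plv_netfeat`.
#' @param partition Output of [partition_terciles()] for the same trials; when
#'   omitted all trials are pooled.
#' @param ... Unused.
#' @return A ggplot object: box plots of single-trial global strength per bin.
#' @method autoplot plv_netfeat
#' @export
autoplot.plv_netfeat <- function(object, partition = NULL, ...) {
  df <- as_tibble.plv_netfeat(object)
  df <- dplyr::distinct(df, .data$trial_id, .data$bin, .data$global_strength)
  df$bin <- factor(df$bin, levels = bin_names(object$bins_ms))
  if (!is.null(partition)) {
    lk <- tibble::tibble(trial_id = object$trial_id,
                         class = partition$performance_class)
    df <- dplyr::left_join(df, lk, by = "trial_id")
    df <- dplyr::filter(df, .data$class %in% c("fast", "slow"))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin,
                                          y = .data$global_strength,
                                          fill = .data$class))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin,
                                          y = .data$global_strength))
  }
  p + ggplot2::geom_boxplot() +
    ggplot2::labs(x = "time bin (relative to cue)",
                  y = "global network strength (PLV)") +
    ggplot2::theme_minimal()
}

#' Plot the decoder permutation-null distribution with the observed AUC
#'
#' @param object A `plv_decoder`.
#' @param ... Unused.
#' @return A ggplot object: histogram of null AUCs with the observed AUC marked.
#' @method autoplot plv_decoder
#' @export
autoplot.plv_decoder <- function(object, ...) {
  df <- tidy.plv_decoder(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_auc)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$auc, colour = "red",
                        linewidth = 1) +
    ggplot2::labs(
      x = "null AUC (random labels)", y = "count",
      title = sprintf("observed AUC = %.3f, p = %.4g",
                      object$auc, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot single-trial pre-cue feature against reaction time
#'
#' @param run A `plv_run`.
#' @param feature `"strength"` (pre-cue global strength) or `"qexp"`
#'   (designated-channel communicability).
#' @return A ggplot scatter with a least-squares line.
#' @export
plot_feature_vs_rt <- function(run, feature = c("strength", "qexp")) {
  feature <- match.arg(feature)
  x <- if (feature == "strength") {
    run$netfeat$global_strength[, 1]
  } else {
    run$netfeat$nodal_qexp[, 1, run$designated_channel]
  }
  df <- tibble::tibble(feature = x, rt_ms = run$netfeat$rts_ms)
  lab <- if (feature == "strength") "pre-cue global network strength" else
    sprintf("pre-cue communicability (%s)",
            run$channel_labels[run$designated_channel])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$rt_ms)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red") +
    ggplot2::labs(x = lab, y = "reaction time (ms)") +
    ggplot2::theme_minimal()
}
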