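#' Tercile partition of trials by reaction time and by chronological order
#'
#' Ranks trials by RT; the `floor(n/3)` fastest are labelled `fast`, the
#' `floor(n/3)` slowest `slow`, the remainder `middle`. Ties straddling a
#' boundary are resolved chronologically (the earlier trial takes the
#' lower-rank class) with a message. The same sizes define `early`/`late`
#' classes over the chronological index.
#'
#' @param rts Reaction times (ms), one per trial, in chronological order.
#' @return Tibble with `trial`, `rt_ms`, `performance_class`
#'   (fast/middle/slow) and `order_class` (early/middle/late).
#' @export
partition_terciles <- function(rts) {
  n <- length(rts)
  if (n < 6) stop("need at least 6 trials to partition into terciles", call. = FALSE)
  k <- floor(n / 3)
  ord <- order(rts, seq_along(rts))   # ties broken by chronological index
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  boundary_tie <-
    (any(ranks == k) && any(rts[ranks == k] %in% rts[ranks == k + 1])) ||
    (any(ranks == n - k) && any(rts[ranks == n - k] %in% rts[ranks == n - k + 1]))
  if (boundary_tie) {
    message("RT tie at a tercile boundary resolved by chronological order")
  }
  perf <- rep("middle", n)
  perf[ranks <= k] <- "fast"
  perf[ranks > n - k] <- "slow"
  ordc <- rep("middle", n)
  ordc[seq_len(k)] <- "early"
  ordc[(n - k + 1):n] <- "late"
  tibble::tibble(
    trial = seq_len(n), rt_ms = rts,
    performance_class = factor(perf, levels = c("fast", "middle", "slow")),
    order_class = factor(ordc, levels = c("early", "middle", "late"))
  )
}

#' Wilcoxon rank-sum test with normal approximation
#'
#' Mann-Whitney/Wilcoxon rank-sum with tie-corrected variance and continuity
#' correction, reporting the z statistic (as printed in the field's results
#' sections) alongside the p-value. The z is signed so that positive means `x`
#' tends larger than `y`.
#'
#' @param x,y Numeric samples (each n >= 3).
#' @param sided `"two"` or `"one"`.
#' @param direction For one-sided tests, the alternative: `"greater"` (x > y)
#'   or `"less"` (x < y). Must be declared explicitly; no direction inference.
#' @return One-row tibble: `test`, `statistic` (z), `p_value`, `sidedness`,
#'   `n_x`, `n_y`.
#' @export
rank_sum <- function(x, y, sided = c("two", "one"),
                     direction = c("greater", "less")) {
  sided <- match.arg(sided)
  if (sided == "one") direction <- match.arg(direction)
  if (length(x) < 3 || length(y) < 3) {
    stop("each sample must have at least 3 observations", call. = FALSE)
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    z <- 0
  } else {
    cc <- 0.5 * sign(u - mu)   # continuity correction toward the null
    z <- (u - mu - cc) / sqrt(sigma2)
  }
  p <- if (sided == "two") {
    min(1, 2 * pnorm(-abs(z)))
  } else if (direction == "greater") {
    pnorm(-z)
  } else {
    pnorm(z)
  }
  tibble::tibble(
    test = "wilcoxon_rank_sum", statistic = z, p_value = p,
    sidedness = sided, n_x = nx, n_y = ny
  )
}

#' Per-channel Welch two-sample t contrasts
#'
#' Welch (unequal-variance) two-sample t-test of each channel's feature between
#' two trial groups, with Welch-Satterthwaite degrees of freedom. The channel
#' with the maximum |t| is recorded in the `max_channel` attribute. Channels
#' with zero variance in both groups get t = 0, p = 1 with a warning.
#'
#' @param features trial x channel numeric matrix.
#' @param labels Factor/character per trial with exactly the two levels
#'   compared; the contrast is `first level - second level`.
#' @param levels The two group labels, in contrast order.
#' @return Tibble with `channel`, `t`, `df`, `p_value`; attribute
#'   `max_channel` holds the index of the maximum |t|.
#' @export
nodal_contrast_t <- function(features, labels,
                             levels = c("fast", "slow")) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  a <- features[labels == levels[1], , drop = FALSE]
  b <- features[labels == levels[2], , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2) {
    stop("each group needs at least 2 trials", call. = FALSE)
  }
  nc <- ncol(features)
  tt <- df <- pv <- numeric(nc)
  degenerate <- 0L
  for (ch in seq_len(nc)) {
    if (stats::var(a[, ch]) == 0 && stats::var(b[, ch]) == 0) {
      tt[ch] <- 0; df[ch] <- nrow(a) + nrow(b) - 2; pv[ch] <- 1
      degenerate <- degenerate + 1L
    } else {
      res <- t.test(a[, ch], b[, ch], var.equal = FALSE)
      tt[ch] <- unname(res$statistic)
      df[ch] <- unname(res$parameter)
      pv[ch] <- res$p.value
    }
  }
  if (degenerate > 0) {
    warning(degenerate, " channel(s) with zero variance in both groups; p set to 1",
            call. = FALSE)
  }
  out <- tibble::tibble(channel = seq_len(nc), t = tt, df = df, p_value = pv)
  attr(out, "max_channel") <- which.max(abs(tt))
  out
}

#' Pearson correlation between a single-trial feature and reaction time
#'
#' @param feature Per-trial scalar feature (n >= 4, non-constant).
#' @param rts Reaction times, same length.
#' @return One-row tibble: `test`, `r`, `df`, `p_value` (two-sided, from the
#'   t-distribution transform of r).
#' @export
correlate_rt <- function(feature, rts) {
  if (length(feature) != length(rts) || length(feature) < 4) {
    stop("need matched feature/RT vectors with n >= 4", call. = FALSE)
  }
  if (stats::var(feature) == 0) {
    stop("feature has zero variance; correlation undefined", call. = FALSE)
  }
  res <- cor.test(feature, rts, method = "pearson")
  tibble::tibble(
    test = "pearson", r = unname(res$estimate),
    df = unname(res$parameter), p_value = res$p.value
  )
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni <- function(alpha, m) {
  if (length(m) != 1 || is.na(m) || m < 1) stop("m must be a positive count", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  alpha / m
}
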