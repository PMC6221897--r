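stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Cross-validated linear-SVM AUC for fast/slow classification
#'
#' Stratified k-fold cross-validation: within each fold the features are
#' standardised using training-fold statistics only, a linear-kernel
#' maximum-margin classifier (cost 1) is trained, and its continuous decision
#' values on the held-out trials are pooled across folds; the AUC is computed
#' from the pooled decision values against the true labels (fast = positive
#' class), so chance is 0.5 regardless of fold composition.
#'
#' @param features Data frame with a `class` column (values `fast`/`slow`) and
#'   numeric feature columns; no missing values.
#' @param k Number of folds (>= 2).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so callers controlling the stream stay reproducible).
#' @return Scalar AUC in \[0, 1\], with attribute `decision_values`.
#' @export
crossval_auc <- function(features, k = 10, seed = NULL) {
  stopifnot(is.data.frame(features), "class" %in% names(features), k >= 2)
  if (!is.null(seed)) set.seed(seed)
  y <- factor(as.character(features$class), levels = c("slow", "fast"))
  if (any(is.na(y)) || nlevels(droplevels(y)) < 2) {
    stop("both classes (fast, slow) must be present", call. = FALSE)
  }
  x <- as.matrix(features[setdiff(names(features), "class")])
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  if (min(table(y)) < max(2, floor(k / 2))) {
    stop("too few trials per class for ", k, "-fold stratification", call. = FALSE)
  }

  folds <- stratified_folds(y, k)
  # guard: every training fold must contain both classes
  for (attempt in 1:10) {
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(y[folds != f])) == 2
    }, TRUE))
    if (ok) break
    if (attempt == 10) stop("could not stratify folds with both classes", call. = FALSE)
    folds <- stratified_folds(y, k)
  }

  dec <- numeric(length(y))
  for (f in seq_len(k)) {
    te <- folds == f
    if (!any(te)) next
    mu <- colMeans(x[!te, , drop = FALSE])
    sdev <- apply(x[!te, , drop = FALSE], 2, stats::sd)
    sdev[sdev == 0] <- 1
    xtr <- sweep(sweep(x[!te, , drop = FALSE], 2, mu), 2, sdev, "/")
    xte <- sweep(sweep(x[te, , drop = FALSE], 2, mu), 2, sdev, "/")
    fit <- e1071::svm(xtr, droplevels(y[!te]), kernel = "linear", cost = 1,
                      scale = FALSE)
    dv <- attr(stats::predict(fit, xte, decision.values = TRUE),
               "decision.values")
    # e1071 orients the decision value toward the first training label seen;
    # normalise so larger value = "fast"
    if (grepl("^slow", colnames(dv)[1])) dv <- -dv
    dec[te] <- as.numeric(dv)
  }
  auc <- as.numeric(pROC::auc(
    response = y, predictor = dec,
    levels = c("slow", "fast"), direction = "<", quiet = TRUE
  ))
  attr(auc, "decision_values") <- dec
  auc
}

#' Permutation-null significance test for the cross-validated decoder
#'
#' Recomputes the cross-validated AUC `n_perm` times with class labels randomly
#' generated as fair Bernoulli draws over trials (a label-permutation null that
#' preserves class balance is available via `null = "permute"`). Draws that
#' produce a single class are redrawn (count logged). The p-value uses the
#' add-one rule `p = (1 + #{null >= auc}) / (1 + n_perm)`, so it can never be
#' exactly zero.
#'
#' @inheritParams crossval_auc
#' @param n_perm Number of null draws (>= 100).
#' @param null `"bernoulli"` (default) or `"permute"`.
#' @param seed Integer seed; the result is bit-reproducible given
#'   `(seed, n_perm, k)`.
#' @return Object of class `plv_decoder`: list with `auc`, `null_aucs`
#'   (length `n_perm`), `p_value`, `folds`, `n_perm`, `seed`, `null`,
#'   `feature_names`, `n_trials`, `redraws`.
#' @export
permutation_test <- function(features, k = 10, n_perm = 1000,
                             null = c("bernoulli", "permute"), seed = 1) {
  null <- match.arg(null)
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  set.seed(seed)
  observed <- crossval_auc(features, k = k, seed = NULL)
  n <- nrow(features)
  null_aucs <- numeric(n_perm)
  redraws <- 0L
  for (j in seq_len(n_perm)) {
    repeat {
      lab <- if (null == "bernoulli") {
        ifelse(rbinom(n, 1, 0.5) == 1, "fast", "slow")
      } else {
        sample(as.character(features$class))
      }
      if (length(unique(lab)) == 2 && min(table(lab)) >= max(2, floor(k / 2))) break
      redraws <- redraws + 1L
    }
    perm <- features
    perm$class <- lab
    null_aucs[j] <- as.numeric(crossval_auc(perm, k = k, seed = NULL))
  }
  p <- (1 + sum(null_aucs >= as.numeric(observed))) / (1 + n_perm)
  structure(
    list(auc = as.numeric(observed), null_aucs = null_aucs, p_value = p,
         folds = k, n_perm = n_perm, seed = seed, null = null,
         feature_names = setdiff(names(features), "class"),
         n_trials = n, redraws = redraws),
    class = "plv_decoder"
  )
}

#' @export
print.plv_decoder <- function(x, ...) {
  cat(sprintf(
    "<plv_decoder> AUC = %.3f, permutation p = %.4g (%d folds, %d null draws)\n",
    x$auc, x$p_value, x$folds, x$n_perm))
  cat("features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' Build the decoder feature matrix from network features
#'
#' Default feature space: pre-cue global network strength and the pre-cue
#' nodal communicability of a designated channel, restricted to the fast and
#' slow trial terciles.
#'
#' @param netfeat A `plv_netfeat` with communicability computed.
#' @param partition Output of [partition_terciles()] for the same trials.
#' @param channel Designated channel index (e.g. the maximum fast-slow
#'   communicability contrast).
#' @param bin Bin index to draw features from (default 1, the pre-cue bin).
#' @return Tibble with `class`, `global_strength`, `qexp`.
#' @export
decoder_features <- function(netfeat, partition, channel, bin = 1) {
  stopifnot(inherits(netfeat, "plv_netfeat"), !is.null(netfeat$nodal_qexp))
  keep <- partition$performance_class %in% c("fast", "slow")
  tibble::tibble(
    class = as.character(partition$performance_class[keep]),
    global_strength = netfeat$global_strength[keep, bin],
    qexp = netfeat$nodal_qexp[keep, bin, channel]
  )
}
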