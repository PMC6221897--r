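check_adjacency <- function(adj, tol = 1e-9) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  if (max(abs(adj - t(adj))) > tol) {
    stop("adjacency matrix is not symmetric", call. = FALSE)
  }
  if (any(adj < 0)) stop("negative edge weights are not allowed", call. = FALSE)
  adj
}

#' Nodal strength of a weighted network
#'
#' Strength of node k under the mean-edge convention:
#' `s_k = sum_{j != k} w_kj / (N - 1)`, i.e. the average synchrony between that
#' node and all others. With `convention = "sum"` the plain row sum is
#' returned instead.
#'
#' @param adj Symmetric, zero-diagonal channel x channel matrix with weights in
#'   \[0, 1\].
#' @param convention `"mean"` (default) or `"sum"`.
#' @return Numeric vector of per-node strengths.
#' @export
nodal_strength <- function(adj, convention = c("mean", "sum")) {
  convention <- match.arg(convention)
  adj <- check_adjacency(adj)
  s <- rowSums(adj) - diag(adj)
  if (convention == "mean") s <- s / (nrow(adj) - 1)
  unname(s)
}

#' Global network strength
#'
#' The average edge weight across all N(N-1)/2 pairwise nodal interactions;
#' identically the mean of the nodal strengths under the mean-edge convention.
#'
#' @inheritParams nodal_strength
#' @return Scalar global strength.
#' @export
global_strength <- function(adj) {
  adj <- check_adjacency(adj)
  mean(adj[upper.tri(adj)])
}

#' Communicability matrix (Qexp)
#'
#' The matrix exponential of the degree-normalised adjacency,
#' `Qexp = expm(D^{-1/2} A D^{-1/2})` with `D = diag(row sums)` (the
#' Crofts-Higham normalisation for weighted networks), computed exactly via the
#' eigen-decomposition of the symmetric normalised matrix. Entry (i, j) sums
#' all walks between i and j down-weighted by 1/length!, so it quantifies
#' multi-path information flow. `normalize = "none"` gives the plain `expm(A)`.
#' Isolated nodes (zero row sum) have their normaliser floored at `eps` with a
#' warning.
#'
#' @param adj Symmetric non-negative channel x channel matrix, zero diagonal.
#' @param normalize `"degree"` (default, Crofts-Higham) or `"none"`.
#' @param eps Floor applied to zero row sums.
#' @return Symmetric communicability matrix (diagonal >= 1).
#' @export
communicability_matrix <- function(adj, normalize = c("degree", "none"),
                                   eps = 1e-12) {
  normalize <- match.arg(normalize)
  adj <- check_adjacency(adj)
  m <- if (normalize == "degree") {
    d <- rowSums(adj)
    if (any(d <= 0)) {
      warning(sum(d <= 0), " isolated node(s): degree floored at eps", call. = FALSE)
      d[d <= 0] <- eps
    }
    di <- 1 / sqrt(d)
    adj * tcrossprod(di)
  } else {
    adj
  }
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  q <- e$vectors %*% (exp(e$values) * t(e$vectors))
  (q + t(q)) / 2
}

#' Nodal communicability
#'
#' Average communicability of node k with all other nodes: the mean of row k of
#' the Qexp matrix excluding the diagonal entry.
#'
#' @param qexp Output of [communicability_matrix()].
#' @return Numeric vector of per-node communicability.
#' @export
nodal_communicability <- function(qexp) {
  stopifnot(is.matrix(qexp), nrow(qexp) == ncol(qexp))
  unname((rowSums(qexp) - diag(qexp)) / (nrow(qexp) - 1))
}

#' Network features for every trial and time bin
#'
#' Computes global strength, nodal strength and nodal communicability from each
#' single-trial PLV adjacency matrix.
#'
#' @param conn A `plv_conn` (see [single_trial_plv()]).
#' @param normalize Communicability normalisation, see
#'   [communicability_matrix()].
#' @param qexp Compute communicability (set `FALSE` to skip the matrix
#'   exponentials when only strength is needed).
#' @return Object of class `plv_netfeat`: list with `global_strength` (trial x
#'   bin matrix), `nodal_strength` (trial x bin x channel array), `nodal_qexp`
#'   (same shape, or `NULL`), `bins_ms`, `channel_labels`, `rts_ms`,
#'   `trial_id`.
#' @export
network_features <- function(conn, normalize = "degree", qexp = TRUE) {
  stopifnot(inherits(conn, "plv_conn"))
  d <- dim(conn$plv)
  nt <- d[1]; nb <- d[2]; nc <- d[3]
  gs <- matrix(0, nt, nb)
  ns <- array(0, dim = c(nt, nb, nc))
  nq <- if (qexp) array(0, dim = c(nt, nb, nc)) else NULL
  for (r in seq_len(nt)) {
    for (b in seq_len(nb)) {
      a <- conn$plv[r, b, , ]
      s <- nodal_strength(a)
      ns[r, b, ] <- s
      gs[r, b] <- mean(s)
      if (qexp) {
        nq[r, b, ] <- nodal_communicability(
          communicability_matrix(a, normalize = normalize)
        )
      }
    }
  }
  structure(
    list(global_strength = gs, nodal_strength = ns, nodal_qexp = nq,
         bins_ms = conn$bins_ms, channel_labels = conn$channel_labels,
         rts_ms = conn$rts_ms, trial_id = conn$trial_id),
    class = "plv_netfeat"
  )
}

bin_names <- function(bins_ms) {
  if (!is.null(rownames(bins_ms))) return(rownames(bins_ms))
  paste0("bin_", seq_len(nrow(bins_ms)))
}

#' Long-format tibble of network features
#'
#' @param x A `plv_netfeat`.
#' @param ... Unused.
#' @return Tibble with columns `trial_id`, `rt_ms`, `bin`, `channel`,
#'   `strength`, `qexp` (if computed), plus per-(trial, bin) `global_strength`.
#' @importFrom tibble as_tibble
#' @method as_tibble plv_netfeat
#' @export
as_tibble.plv_netfeat <- function(x, ...) {
  d <- dim(x$nodal_strength)
  bins <- bin_names(x$bins_ms)
  grid <- expand.grid(trial = seq_len(d[1]), bin = seq_len(d[2]),
                      channel = seq_len(d[3]))
  out <- tibble::tibble(
    trial_id = x$trial_id[grid$trial],
    rt_ms = x$rts_ms[grid$trial],
    bin = bins[grid$bin],
    channel = x$channel_labels[grid$channel],
    strength = x$nodal_strength[as.matrix(grid)],
    global_strength = x$global_strength[cbind(grid$trial, grid$bin)]
  )
  if (!is.null(x$nodal_qexp)) out$qexp <- x$nodal_qexp[as.matrix(grid)]
  out
}
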