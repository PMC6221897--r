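test_that("tercile partition gives floor(n/3) extreme groups with the chronological tie rule", {
  p57 <- partition_terciles(rnorm(57, 400, 80) + 100)
  expect_equal(sum(p57$performance_class == "fast"), 19)
  expect_equal(sum(p57$performance_class == "slow"), 19)
  expect_equal(sum(p57$order_class == "early"), 19)
  expect_equal(sum(p57$order_class == "late"), 19)

  p6 <- partition_terciles(c(1, 2, 3, 4, 5, 6))
  expect_equal(which(p6$performance_class == "fast"), c(1, 2))
  expect_equal(which(p6$performance_class == "slow"), c(5, 6))

  expect_message(p9 <- partition_terciles(rep(5, 9)), "tie")
  expect_equal(as.vector(table(p9$performance_class)), c(3, 3, 3))
  expect_equal(which(p9$performance_class == "fast"), 1:3)

  expect_error(partition_terciles(c(1, 2, 3)), "at least 6")
})

test_that("tercile labels per trial do not depend on input order when RTs are distinct", {
  set.seed(5)
  rts <- sample(seq(200, 800, by = 7))
  base <- partition_terciles(rts)
  p <- sample(length(rts))
  perm <- partition_terciles(rts[p])
  expect_equal(as.character(perm$performance_class),
               as.character(base$performance_class)[p])
})

# exact rank-sum enumeration over all assignments of ranks to the x sample
rank_sum_exact_p <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(n, nx)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- mean(u_all)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

test_that("rank-sum z and p behave on the canonical cases", {
  same <- rank_sum(c(1, 5, 9, 9), c(1, 5, 9, 9))
  expect_equal(same$statistic, 0)
  expect_gte(same$p_value, 0.95)

  sep <- rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_lt(abs(sep$p_value - 0.1), 0.05)   # exact enumeration p = 0.1
  expect_equal(rank_sum_exact_p(c(1, 2, 3), c(4, 5, 6)), 0.1)

  # one-sided p decreases monotonically as y shifts away
  x <- c(3, 5, 2, 8, 4)
  ps <- vapply(c(0, 2, 5, 10), function(s) {
    rank_sum(x, c(4, 6, 7, 3) + s, sided = "one", direction = "less")$p_value
  }, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("rank-sum approximation matches exact enumeration for small tie-free samples", {
  set.seed(19)
  for (i in 1:20) {
    nx <- sample(3:5, 1)
    ny <- sample(3:5, 1)
    xy <- sample(1:50, nx + ny)            # distinct values: no ties
    x <- xy[seq_len(nx)]
    y <- xy[-seq_len(nx)]
    approx_p <- rank_sum(x, y)$p_value
    exact_p <- rank_sum_exact_p(x, y)
    expect_lt(abs(approx_p - exact_p), 0.05)
  }
})

test_that("rank-sum agrees with the reference normal-approximation implementation", {
  set.seed(29)
  for (i in 1:10) {
    x <- rnorm(15)
    y <- rnorm(12, 0.5)
    ours <- rank_sum(x, y)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("per-channel Welch contrasts reproduce hand-computed t and df", {
  f <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  labels <- c("fast", "fast", "fast", "slow", "slow", "slow")
  res <- nodal_contrast_t(f, labels)
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)

  same <- nodal_contrast_t(matrix(c(1, 2, 1, 2), ncol = 1),
                           c("fast", "fast", "slow", "slow"))
  expect_equal(same$t, 0)

  expect_warning(
    degen <- nodal_contrast_t(matrix(rep(3, 6), ncol = 1), labels),
    "zero variance"
  )
  expect_equal(degen$p_value, 1)
})

test_that("the count of significant channels grows with effect size", {
  set.seed(39)
  count_sig <- function(effect) {
    mean(vapply(1:20, function(i) {
      f <- matrix(rnorm(38 * 10), 38, 10)
      f[1:19, ] <- f[1:19, ] + effect
      res <- nodal_contrast_t(f, rep(c("fast", "slow"), each = 19))
      sum(res$p_value < 0.05)
    }, 0))
  }
  expect_gt(count_sig(1.5), count_sig(0) + 3)
})

test_that("Pearson RT correlation handles the canonical cases", {
  rts <- c(300, 450, 280, 520, 410)
  expect_equal(correlate_rt(rts, rts)$r, 1)
  expect_equal(correlate_rt(-rts + 1000, rts)$r, -1)
  hand <- correlate_rt(c(0, 1, 2, 3, 4), c(0, 2, 1, 3, 4))
  expect_equal(hand$r, 0.9, tolerance = 1e-12)
  expect_equal(hand$df, 3)
  expect_error(correlate_rt(rep(1, 5), rts), "zero variance")
})

test_that("Bonferroni threshold is alpha over m", {
  expect_identical(bonferroni(0.05, 4), 0.0125)
  expect_identical(bonferroni(0.05, 1), 0.05)
  expect_identical(bonferroni(0.01, 10), 0.001)
  expect_error(bonferroni(0.05, 0), "positive count")
  expect_error(bonferroni(1.2, 4), "alpha")
})
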