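test_that("welch_t matches the closed-form statistic and t.test", {
  x <- c(4.1, 5.2, 6.3, 5.8); y <- c(7.4, 8.1, 6.9)
  w <- welch_t(x, y)
  # independent evaluation of the Welch/Satterthwaite formulas
  se2 <- var(x) / 4 + var(y) / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 4)^2 / 3 + (var(y) / 3)^2 / 2)
  expect_equal(w$t, t_hand, tolerance = 1e-12)
  expect_equal(w$df, df_hand, tolerance = 1e-12)
  expect_equal(w$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)

  set.seed(99)
  for (i in 1:1000) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    x <- rnorm(nx); y <- rnorm(ny, sd = runif(1, 0.5, 2))
    w <- welch_t(x, y)
    tt <- t.test(x, y)
    expect_equal(w$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(w$df, unname(tt$parameter), tolerance = 1e-9)
    expect_equal(w$p, tt$p.value, tolerance = 1e-12)
  }
})

test_that("welch_t degenerate conventions", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$t, 0, tolerance = 1e-15)
  expect_equal(welch_t(c(5, 5), c(5, 5)), list(t = 0, df = 2, p = 1))
  w <- welch_t(c(1, 2, 3) + 10, c(1.0001, 2.0001, 2.9999))
  expect_lt(w$p, 1e-3)
  expect_equal(welch_t(c(2, 2), c(1, 1))$p, 0)
})

# brute-force permutation p for one protein: enumerate every assignment of
# the pooled values into groups of the original sizes and count the
# assignments at least as extreme as the observed one, extremeness measured
# on the Welch p scale (|t| values at different Satterthwaite df are not
# directly comparable)
brute_force_perm_p <- function(x, y) {
  pooled <- c(x, y)
  idx <- utils::combn(length(pooled), length(x), simplify = FALSE)
  p_obs <- welch_t(x, y)$p
  hits <- vapply(idx, function(i) {
    welch_t(pooled[i], pooled[-i])$p <= p_obs + 1e-12
  }, logical(1))
  mean(hits)
}

test_that("exhaustive permutation q equals the brute-force permutation p", {
  x <- c(10.2, 11.1, 9.8); y <- c(12.5, 13.0, 12.2)
  vals <- matrix(c(x, y), nrow = 1)
  res <- permutation_fdr(vals, c("A", "A", "A", "B", "B", "B"))
  expect_true(attr(res, "exhaustive"))
  expect_equal(attr(res, "n_permutations"), choose(6, 3))
  expect_equal(res$q, brute_force_perm_p(x, y))

  # a second, less extreme instance
  x2 <- c(3.2, 4.9, 4.0); y2 <- c(4.5, 5.1, 3.9)
  res2 <- permutation_fdr(matrix(c(x2, y2), nrow = 1),
                          c("A", "A", "A", "B", "B", "B"))
  expect_equal(res2$q, brute_force_perm_p(x2, y2))
})

test_that("q values are permutation-invariant for duplicated proteins and monotone in p", {
  set.seed(14)
  vals <- matrix(rnorm(8 * 30), 30, 8)
  vals <- rbind(vals, vals[5, ])  # duplicate row as row 31
  labels <- rep(c("A", "B"), each = 4)
  res <- permutation_fdr(vals, labels)
  expect_equal(res$q[31], res$q[5])
  o <- order(res$p)
  expect_false(is.unsorted(res$q[o]))
  expect_true(all(res$q >= 0 & res$q <= 1))
})

test_that("null simulations rarely pass q < 0.05", {
  set.seed(77)
  vals <- matrix(rnorm(8 * 1000), 1000, 8)
  res <- permutation_fdr(vals, rep(c("A", "B"), each = 4))
  mc_err <- sqrt(0.05 * 0.95 / 1000)
  expect_lte(mean(res$q < 0.05), 0.05 + 2 * mc_err)
})

test_that("geometric fold change and its log identity", {
  expect_equal(geometric_fold_change(c(3, 3), c(3, 3))$fc, 1)
  expect_equal(geometric_fold_change(c(2, 8), c(1, 1))$fc, 4)
  set.seed(21)
  for (i in 1:20) {
    a <- rexp(5) + 0.1; b <- rexp(4) + 0.1
    g <- geometric_fold_change(a, b)
    expect_equal(g$log2fc, mean(log2(a)) - mean(log2(b)), tolerance = 1e-12)
    expect_equal(log2(g$fc), g$log2fc, tolerance = 1e-12)
  }
  expect_error(geometric_fold_change(c(1, 0), c(1, 1)), "positive")
})

test_that("volcano classification treats boundaries as non-significant", {
  expect_equal(classify_volcano(1.5, 0.01), "high_in_A")
  expect_equal(classify_volcano(-2, 0.01), "high_in_B")
  expect_equal(classify_volcano(1.0, 0.01), "NS")    # boundary log2FC
  expect_equal(classify_volcano(-1.0, 0.01), "NS")
  expect_equal(classify_volcano(2, 0.05), "NS")      # boundary q
  expect_equal(classify_volcano(-2, 0.2), "NS")
  expect_equal(classify_volcano(c(1.2, -1.2, 0), c(0.01, 0.01, 0.01)),
               c("high_in_A", "high_in_B", "NS"))
})

test_that("p cut-off line sits at the largest passing p", {
  expect_equal(p_cutoff_for_q(c(0.01, 0.02), c(0.01, 0.02)), 0.02)
  expect_true(is.na(p_cutoff_for_q(c(0.5, 0.6), c(0.5, 0.6))))
  p <- c(0.001, 0.04, 0.2, 0.03, 0.6)
  q <- c(0.01, 0.049, 0.3, 0.02, 0.7)
  # linear-scan oracle
  expect_equal(p_cutoff_for_q(p, q), max(p[q < 0.05]))
  expect_equal(p_cutoff_for_q(p, q), 0.04)
  expect_error(p_cutoff_for_q(1:3, 1:2), "lengths differ")
})

test_that("correlation matrix: identity, antithesis and closed form", {
  x <- c(1, 3, 2, 5, 4)
  m <- cbind(a = x, b = -x, c = c(2, 4, 3, 7, 6))
  cm <- correlation_matrix(m)
  expect_equal(diag(cm$r), c(a = 1, b = 1, c = 1))
  expect_equal(cm$r["a", "b"], -1)
  # closed-form Pearson for the 5-point pair (a, c)
  r_hand <- sum((x - mean(x)) * (m[, 3] - mean(m[, 3]))) /
    sqrt(sum((x - mean(x))^2) * sum((m[, 3] - mean(m[, 3]))^2))
  expect_equal(cm$r["a", "c"], r_hand, tolerance = 1e-12)
  # insufficient overlap flags NA instead of crashing
  m2 <- cbind(a = c(1, 2, NA, NA, NA), b = c(NA, NA, 1, 2, 3))
  cm2 <- correlation_matrix(m2)
  expect_true(is.na(cm2$r["a", "b"]))
  expect_equal(cm2$n["a", "b"], 0L)
})

test_that("paired t-test conventions and closed form", {
  expect_equal(paired_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(paired_t(c(1, 2, 3), c(2, 3, 4))$p, 0)  # constant shift
  before <- c(3.1, 4.5, 2.8, 5.0); after <- c(4.0, 4.9, 3.5, 6.1)
  pt_ <- paired_t(before, after)
  tt <- t.test(after, before, paired = TRUE)
  expect_equal(pt_$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(pt_$p, tt$p.value, tolerance = 1e-12)
  expect_error(paired_t(1:3, 1:4), "equal-length")
})
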