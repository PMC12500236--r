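test_that("total-intensity normalization matches the hand-computed scheme", {
  # two samples, totals 100 and 200, one group: average 150, factors 1.5/0.75
  m <- matrix(c(40, 60, 80, 120), 2,
              dimnames = list(c("A", "B"), c("s1", "s2")))
  tab <- protein_quant(
    m, tibble::tibble(protein_id = c("A", "B")),
    tibble::tibble(sample = c("s1", "s2"), model = "m", treatment = "t",
                   fraction = "f", replicate = 1:2))
  out <- total_intensity_normalize(tab, character(0))
  expect_equal(unname(sample_totals(out)), c(150, 150))
  expect_equal(unname(out$intensities[, "s1"]), c(60, 90))  # x1.5
  expect_equal(unname(out$intensities[, "s2"]), c(60, 90))  # x0.75
})

test_that("single-sample groups are an identity transform", {
  tab <- toy_quant()
  tab$samples$treatment <- c("a", "b", "c", "d")  # each its own group
  out <- total_intensity_normalize(tab, "treatment")
  expect_equal(out$intensities, tab$intensities)
})

test_that("grouped normalization equalizes totals within but not between groups", {
  # 5-protein toy, 4 samples in 2 groups of 2; hand-computed group averages
  m <- matrix(c(1, 2, 3, 4,
                2, 2, 2, 2,
                3, 1, 0, 5,
                4, 3, 2, 1,
                0, 2, 3, 8), nrow = 5, byrow = TRUE,
              dimnames = list(paste0("P", 1:5), paste0("s", 1:4)))
  # totals: 10, 10, 10, 20 -> group1 avg 10, group2 avg 15
  tab <- protein_quant(
    m, tibble::tibble(protein_id = paste0("P", 1:5)),
    tibble::tibble(sample = paste0("s", 1:4), model = "m",
                   treatment = rep(c("labeled", "vehicle"), each = 2),
                   fraction = "eluate", replicate = c(1, 2, 1, 2)))
  out <- total_intensity_normalize(tab, "treatment")
  tot <- unname(sample_totals(out))
  expect_equal(tot, c(10, 10, 15, 15))
  # zeros stay zero
  expect_equal(out$intensities["P5", "s1"], c(P5 = 0), ignore_attr = TRUE)
})

test_that("normalization conserves group means, is idempotent and scale-equivariant", {
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(stats::rexp(40) * sample(c(0, 1), 40, TRUE, c(0.2, 0.8)),
                nrow = 8)
    m[1, ] <- m[1, ] + 1  # no zero-total samples
    dimnames(m) <- list(paste0("P", 1:8), paste0("s", 1:5))
    tab <- protein_quant(
      m, tibble::tibble(protein_id = rownames(m)),
      tibble::tibble(sample = colnames(m), model = "m",
                     treatment = c("a", "a", "b", "b", "b"),
                     fraction = "f", replicate = c(1, 2, 1, 2, 3)))
    out <- total_intensity_normalize(tab, "treatment")
    pre <- sample_totals(tab)
    post <- sample_totals(out)
    grp <- tab$samples$treatment
    for (g in unique(grp)) {
      expect_equal(unname(post[grp == g]),
                   rep(mean(pre[grp == g]), sum(grp == g)),
                   tolerance = 1e-9)
    }
    # idempotent
    again <- total_intensity_normalize(out, "treatment")
    expect_equal(again$intensities, out$intensities, tolerance = 1e-12)
    # scale equivariance: multiplying one sample by c > 0 changes only the
    # group-average target, so the normalized tables agree exactly after
    # rescaling each group to a common total (sample proportions are
    # invariant)
    m_scaled <- tab$intensities
    m_scaled[, 2] <- m_scaled[, 2] * 7.3
    out2 <- total_intensity_normalize(
      protein_quant(m_scaled, tab$proteins, tab$samples), "treatment")
    for (g in unique(grp)) {
      cols <- which(grp == g)
      f <- sample_totals(out2)[cols[1]] / sample_totals(out)[cols[1]]
      expect_equal(out2$intensities[, cols],
                   out$intensities[, cols] * unname(f), tolerance = 1e-12)
    }
  }
})

test_that("normalization refuses zero-total samples by name", {
  tab <- toy_quant()
  tab$intensities[, "s3"] <- 0
  t2 <- protein_quant(tab$intensities, tab$proteins, tab$samples)
  expect_error(total_intensity_normalize(t2), "s3")
})

test_that("prefilter partitions proteins by per-group detection", {
  m <- matrix(c(5, 6, 7, 0, 0,    # 3 nonzero | 0 nonzero -> qualitative
                1, 2, 3, 4, 5,    # all nonzero -> testable
                0, 2, 3, 4, 0),   # 2 | 1 -> qualitative at k=2
              nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), paste0("s", 1:5)))
  tab <- protein_quant(
    m, tibble::tibble(protein_id = c("A", "B", "C")),
    tibble::tibble(sample = paste0("s", 1:5), model = "m",
                   treatment = c(rep("labeled", 3), rep("vehicle", 2)),
                   fraction = "eluate", replicate = c(1:3, 1:2)))
  ga <- paste0("s", 1:3); gb <- paste0("s", 4:5)
  res <- prefilter_min_nonzero(tab, ga, gb, k = 2)
  expect_equal(res$testable$proteins$protein_id, "B")
  expect_setequal(res$qualitative$proteins$protein_id, c("A", "C"))
  # partition: union is the input, intersection empty
  expect_setequal(c(res$testable$proteins$protein_id,
                    res$qualitative$proteins$protein_id),
                  tab$proteins$protein_id)
  # degenerate threshold
  res0 <- prefilter_min_nonzero(tab, ga, gb, k = 0)
  expect_equal(nrow(res0$testable$intensities), 3)
  expect_error(prefilter_min_nonzero(tab, ga, "s4", k = 2), "fewer than")
})

test_that("Grubbs test flags the single gross outlier", {
  # independent closed-form critical value, computed in the test
  n <- 4; alpha <- 0.05
  tq <- qt(1 - alpha / (2 * n), n - 2)
  crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  x <- c(1, 1, 1, 10)
  g <- max(abs(x - mean(x))) / sd(x)
  expect_gt(g, crit)  # the example really is significant at alpha=0.05
  expect_equal(grubbs_outliers(x), 4L)
  expect_equal(grubbs_critical(n), crit)
})

test_that("Grubbs handles constants, ties and symmetric extremes", {
  expect_equal(grubbs_outliers(c(3, 3, 3, 3)), integer(0))
  expect_error(grubbs_outliers(c(1, 2)), "at least 3")
  # symmetric pair: brute-force max deviation is shared; lower index wins,
  # and at most one value is flagged per pass
  x <- c(-10, 0, 0, 0, 10)
  dev <- abs(x - mean(x))
  expect_equal(which.max(dev), 1L)  # tie broken toward lower index
  out <- grubbs_outliers(x, alpha = 0.5)
  expect_lte(length(out), 1)
  if (length(out) == 1) expect_equal(out, 1L)
})

test_that("Grubbs type-I error stays near alpha on Gaussian nulls", {
  set.seed(202)
  n <- 8; draws <- 10000
  x <- matrix(rnorm(n * draws), draws, n)
  g <- apply(x, 1, function(v) max(abs(v - mean(v))) / sd(v))
  rate <- mean(g > grubbs_critical(n, 0.05))
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / draws))
})
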