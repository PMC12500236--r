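#' Welch's two-sample t-test
#'
#' Welch statistic with Satterthwaite degrees of freedom and two-tailed p
#' value. When both groups have zero variance and equal means the degenerate
#' convention `t = 0, p = 1` is returned; zero variance with unequal means
#' yields `t = +/-Inf, p = 0`.
#'
#' @param x,y Numeric vectors (length >= 2 each).
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("welch_t needs at least 2 values per group", call. = FALSE)
  }
  vx <- stats::var(x); vy <- stats::var(y)
  nx <- length(x); ny <- length(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = nx + ny - 2, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = nx + ny - 2, p = 0))
  }
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

# Vectorized Welch |t| over the rows of a matrix given a two-level label
# vector; rows with zero pooled variance get t = 0 (equal means) or Inf.
welch_t_rows <- function(values, is_a) {
  a <- values[, is_a, drop = FALSE]
  b <- values[, !is_a, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- ifelse(se2 > 0, (ma - mb) / sqrt(se2),
                  ifelse(ma == mb, 0, sign(ma - mb) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               na + nb - 2)
  p <- ifelse(is.finite(tstat), 2 * stats::pt(-abs(tstat), df),
              ifelse(tstat == 0, 1, 0))
  list(t = unname(tstat), df = unname(df), p = unname(p))
}

#' Permutation-based FDR (q values) for a two-group comparison
#'
#' Computes the observed Welch test per protein, builds the null
#' distribution of test statistics by permuting the group labels (all
#' distinct assignments when their count is at most `n_permutations`,
#' otherwise a seeded random subset of that size), and estimates, at each
#' observed significance threshold c (on the p scale, which orders proteins
#' identically to |t| at common df while honoring per-protein Satterthwaite
#' df), the false discovery rate as (average permutation count of null
#' p <= c) / (observed count of p <= c). The q value of a protein is the
#' minimum estimated FDR over thresholds at or above its own p — the
#' smallest FDR at which the protein is still called significant — which
#' makes q monotone non-decreasing in p; q is clipped to [0, 1].
#'
#' @param values Numeric matrix (proteins x samples) of complete (imputed)
#'   log2 intensities.
#' @param labels Character/factor vector over columns with exactly two
#'   levels; the first level encountered is group A.
#' @param n_permutations Maximum number of permutations (default 10000).
#' @param seed Integer seed used when subsampling permutations.
#' @return Tibble with per-protein `t`, `df`, `p`, `q` and the number of
#'   permutations used as attribute `n_permutations`.
#' @export
permutation_fdr <- function(values, labels, n_permutations = 10000,
                            seed = 1L) {
  stopifnot(is.matrix(values), length(labels) == ncol(values))
  lev <- unique(as.character(labels))
  if (length(lev) != 2) stop("labels must have exactly two levels",
                             call. = FALSE)
  is_a <- as.character(labels) == lev[1]
  n <- length(labels); na <- sum(is_a)
  n_distinct <- choose(n, na)
  if (n_distinct < 2) stop("fewer than 2 distinct permutations",
                           call. = FALSE)
  obs <- welch_t_rows(values, is_a)

  if (n_distinct <= n_permutations) {
    assign_idx <- utils::combn(n, na, simplify = FALSE)
  } else {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit({
      if (!is.null(old_seed)) {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    })
    set.seed(seed)
    assign_idx <- replicate(n_permutations, sort(sample.int(n, na)),
                            simplify = FALSE)
  }
  n_perm <- length(assign_idx)
  n_prot <- nrow(values)
  null_p <- numeric(n_perm * n_prot)
  for (k in seq_len(n_perm)) {
    perm_a <- rep(FALSE, n); perm_a[assign_idx[[k]]] <- TRUE
    null_p[((k - 1) * n_prot + 1):(k * n_prot)] <-
      welch_t_rows(values, perm_a)$p
  }
  q <- perm_fdr_from_p(obs$p, null_p, n_perm)
  out <- tibble::tibble(t = obs$t, df = obs$df, p = obs$p, q = pmin(q, 1))
  attr(out, "n_permutations") <- n_perm
  attr(out, "exhaustive") <- n_distinct <= n_permutations
  out
}

# FDR-ratio q values from observed and pooled-null p values. At each
# observed threshold c: FDR(c) = (mean null count of p <= c) /
# (observed count of p <= c); q_i = min over c >= p_i, enforced by a
# reverse cumulative minimum over the p-sorted order.
perm_fdr_from_p <- function(obs_p, null_p, n_perm) {
  ord <- order(obs_p)
  thresholds <- obs_p[ord]
  null_sorted <- sort(null_p)
  fp <- findInterval(thresholds, null_sorted) / n_perm
  fdr <- pmin(fp / seq_along(thresholds), 1)
  q_sorted <- rev(cummin(rev(fdr)))
  q <- numeric(length(obs_p))
  q[ord] <- q_sorted
  q
}

#' Geometric-mean fold change
#'
#' `FC = geomean(A) / geomean(B)`; its log2 equals the difference of mean
#' log2 intensities, so the computation commutes with back-transformation of
#' imputed log2 values to the decimal scale.
#'
#' @param a,b Numeric vectors of positive decimal intensities.
#' @return List with `fc` and `log2fc`.
#' @export
geometric_fold_change <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) {
    stop("geometric fold change requires positive intensities", call. = FALSE)
  }
  l2 <- mean(log2(a)) - mean(log2(b))
  list(fc = 2^l2, log2fc = l2)
}

#' Volcano classification
#'
#' Assigns each protein of a two-group comparison to `"high_in_A"`
#' (`log2fc > fc_threshold` and `q < q_threshold`), `"high_in_B"`
#' (`log2fc < -fc_threshold` and `q < q_threshold`) or `"NS"`. Boundary
#' values (`log2fc == +/-fc_threshold` or `q == q_threshold`) are
#' non-significant: the significant classes use strict inequalities.
#'
#' @param log2fc,q Numeric vectors (recycled to common length).
#' @param fc_threshold Log2 fold-change threshold (default 1).
#' @param q_threshold q-value threshold (default 0.05).
#' @return Character vector of categories.
#' @export
classify_volcano <- function(log2fc, q, fc_threshold = 1, q_threshold = 0.05) {
  ifelse(q < q_threshold & log2fc > fc_threshold, "high_in_A",
         ifelse(q < q_threshold & log2fc < -fc_threshold, "high_in_B", "NS"))
}

#' p-value cut-off line for a q threshold
#'
#' The volcano p cut-off is drawn at the largest p among proteins whose q
#' value falls below the threshold; `NA` when no protein passes.
#'
#' @param p,q Paired numeric vectors.
#' @param q_threshold q threshold (default 0.05).
#' @return A single p value or `NA`.
#' @export
p_cutoff_for_q <- function(p, q, q_threshold = 0.05) {
  if (length(p) != length(q)) stop("p and q lengths differ", call. = FALSE)
  pass <- q < q_threshold
  if (!any(pass)) return(NA_real_)
  max(p[pass])
}

#' Pairwise Pearson correlation matrix over samples
#'
#' Correlates the log2 intensity profiles of every pair of samples using
#' pairwise-complete proteins; each pair additionally gets a p value from
#' the t-transform of r. Pairs sharing fewer than `min_overlap` observed
#' proteins are flagged `NA`.
#'
#' @param matrix_ A `log2_matrix` (missing values allowed) or a plain
#'   numeric matrix with `NA` for missing.
#' @param min_overlap Minimum shared observed proteins per pair (default 3).
#' @return List with matrices `r`, `p` and `n` (shared-protein counts);
#'   diagonal r is 1.
#' @export
correlation_matrix <- function(matrix_, min_overlap = 3) {
  vals <- if (inherits(matrix_, "log2_matrix")) matrix_$values else matrix_
  ns <- ncol(vals)
  r <- matrix(NA_real_, ns, ns, dimnames = list(colnames(vals),
                                                colnames(vals)))
  pm <- r
  nm <- matrix(0L, ns, ns, dimnames = dimnames(r))
  diag(r) <- 1
  diag(pm) <- 0
  for (i in seq_len(ns)) {
    nm[i, i] <- sum(!is.na(vals[, i]))
    if (i == ns) break
    for (j in (i + 1):ns) {
      ok <- !is.na(vals[, i]) & !is.na(vals[, j])
      nm[i, j] <- nm[j, i] <- sum(ok)
      if (sum(ok) < min_overlap) next
      rij <- stats::cor(vals[ok, i], vals[ok, j])
      r[i, j] <- r[j, i] <- rij
      nn <- sum(ok)
      tt <- rij * sqrt((nn - 2) / max(1 - rij^2, 1e-15))
      pm[i, j] <- pm[j, i] <- 2 * stats::pt(-abs(tt), nn - 2)
    }
  }
  list(r = r, p = pm, n = nm)
}

#' Paired t-test
#'
#' One-sample t-test on the within-pair differences, two-tailed. A constant
#' nonzero difference (zero variance) is reported as `t = +/-Inf, p = 0`;
#' identical vectors give `t = 0, p = 1`.
#'
#' @param before,after Numeric vectors of equal length >= 2.
#' @return List with `t`, `df`, `p`, `mean_difference`.
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after)) {
    stop("paired_t requires equal-length vectors", call. = FALSE)
  }
  if (length(before) < 2) stop("paired_t needs n >= 2", call. = FALSE)
  d <- after - before
  md <- mean(d)
  sdd <- stats::sd(d)
  n <- length(d)
  if (sdd == 0) {
    if (md == 0) return(list(t = 0, df = n - 1, p = 1, mean_difference = 0))
    return(list(t = sign(md) * Inf, df = n - 1, p = 0, mean_difference = md))
  }
  tt <- md / (sdd / sqrt(n))
  list(t = tt, df = n - 1, p = 2 * stats::pt(-abs(tt), n - 1),
       mean_difference = md)
}
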