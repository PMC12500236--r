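#' Total-intensity normalization
#'
#' Scales every intensity by (group-average total) / (sample total):
#' within each normalization group K, the normalized intensity of protein X
#' in sample i is `X_i * Sum_average / Sum_i`, where `Sum_i` is sample i's
#' summed intensity and `Sum_average` the arithmetic mean of the totals over
#' the group's samples. After normalization every sample total in a group
#' equals the group-average pre-normalization total; zeros stay zero.
#'
#' Three groupings cover the schemes used in labeled-versus-vehicle and
#' cross-model analyses: normalize separately per treatment arm
#' (`group_by = c("model", "treatment")`), across a selected set of samples
#' (e.g. all labeled eluates), or across all samples
#' (`group_by = character(0)`).
#'
#' Totals are computed over all proteins present in `table`; restrict the
#' table (e.g. to human proteins) *before* normalizing when a species-specific
#' analysis is wanted.
#'
#' @param table A [protein_quant].
#' @param group_by Character vector of sample-metadata columns that define
#'   the normalization groups; `character(0)` puts all samples in one group.
#' @return A normalized [protein_quant].
#' @export
total_intensity_normalize <- function(table,
                                      group_by = c("model", "treatment",
                                                   "fraction")) {
  stopifnot(inherits(table, "protein_quant"))
  totals <- sample_totals(table)
  if (any(totals <= 0)) {
    bad <- names(totals)[totals <= 0][1]
    stop("sample has zero total intensity: ", bad, call. = FALSE)
  }
  meta <- table$samples
  key <- if (length(group_by) == 0) {
    rep("all", nrow(meta))
  } else {
    missing_cols <- setdiff(group_by, names(meta))
    if (length(missing_cols) > 0) {
      stop("unknown grouping column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    do.call(paste, c(meta[group_by], sep = "\r"))
  }
  group_avg <- tapply(totals, key, mean)
  scale <- as.numeric(group_avg[key]) / totals
  out <- sweep(table$intensities, 2, scale, `*`)
  protein_quant(out, table$proteins, table$samples)
}

#' Detection prefilter for differential testing
#'
#' Splits the proteins of a two-group comparison into a `testable` set (at
#' least `k` nonzero values in *both* groups, eligible for t-testing) and a
#' `qualitative` remainder (fewer than `k` nonzero values in either group),
#' which cannot be assigned a p value but is retained for group-mean
#' summaries rather than silently dropped.
#'
#' @param table A [protein_quant] containing exactly the samples of the two
#'   comparison groups.
#' @param group_a,group_b Character vectors of sample identifiers naming the
#'   two groups (must partition or subset `table`'s samples disjointly).
#' @param k Minimum nonzero count per group (default 2).
#' @return List with [protein_quant] elements `testable` and `qualitative`;
#'   together they partition the input proteins.
#' @export
prefilter_min_nonzero <- function(table, group_a, group_b, k = 2) {
  stopifnot(inherits(table, "protein_quant"))
  all_samples <- table$samples$sample
  for (g in list(group_a, group_b)) {
    if (!all(g %in% all_samples)) {
      stop("unknown sample(s): ",
           paste(setdiff(g, all_samples), collapse = ", "), call. = FALSE)
    }
  }
  if (length(intersect(group_a, group_b)) > 0) {
    stop("comparison groups overlap", call. = FALSE)
  }
  if (length(group_a) < k || length(group_b) < k) {
    stop("a comparison group has fewer than k = ", k, " samples",
         call. = FALSE)
  }
  nz_a <- rowSums(table$intensities[, group_a, drop = FALSE] > 0)
  nz_b <- rowSums(table$intensities[, group_b, drop = FALSE] > 0)
  testable <- nz_a >= k & nz_b >= k
  subset_rows <- function(keep) {
    protein_quant(table$intensities[keep, , drop = FALSE],
                  table$proteins[keep, ], table$samples)
  }
  list(testable = subset_rows(testable),
       qualitative = subset_rows(!testable))
}

#' Grubbs critical value
#'
#' Two-sided single-outlier critical value at level `alpha` for sample size
#' `n`, from the t-distribution:
#' `G_crit = (n-1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n - 2)`.
#'
#' @param n Sample size (>= 3).
#' @param alpha Significance level.
#' @return The critical value of the Grubbs statistic.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  stopifnot(n >= 3)
  tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
}

#' Grubbs outlier test
#'
#' Two-sided single-Grubbs test: the statistic
#' `G = max |x - mean(x)| / sd(x)` is compared against [grubbs_critical()].
#' At most one index is flagged per pass (ties broken toward the lower
#' index); with `iterate = TRUE` the test is repeated on the reduced sample
#' until no further rejection (or fewer than 3 values remain).
#'
#' @param values Numeric vector, length >= 3.
#' @param alpha Significance level (default 0.05).
#' @param iterate Repeat until no outlier is found (default `FALSE`).
#' @return Integer vector of outlier indices into `values` (possibly empty).
#' @export
grubbs_outliers <- function(values, alpha = 0.05, iterate = FALSE) {
  if (length(values) < 3) {
    stop("Grubbs test requires at least 3 values", call. = FALSE)
  }
  idx_all <- seq_along(values)
  flagged <- integer(0)
  repeat {
    active <- setdiff(idx_all, flagged)
    if (length(active) < 3) break
    x <- values[active]
    s <- stats::sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    g <- max(dev) / s
    if (g <= grubbs_critical(length(x), alpha)) break
    flagged <- c(flagged, active[which.max(dev)])
    if (!iterate) break
  }
  flagged
}
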