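#' Log2 transform with explicit missingness
#'
#' Converts a [protein_quant] intensity matrix to log2 scale: zero
#' intensities (non-detections) become explicit `NA` missing values,
#' positive intensities become their log2.
#'
#' @param table A [protein_quant].
#' @return A `log2_matrix`: list with `values` (proteins x samples, `NA` =
#'   missing), `imputed` (logical matrix, all `FALSE` at this stage),
#'   `proteins` and `samples` carried over from the table.
#' @export
log2_transform <- function(table) {
  stopifnot(inherits(table, "protein_quant"))
  values <- table$intensities
  values[values == 0] <- NA_real_
  values <- log2(values)
  structure(
    list(values = values,
         imputed = matrix(FALSE, nrow(values), ncol(values),
                          dimnames = dimnames(values)),
         proteins = table$proteins, samples = table$samples),
    class = "log2_matrix")
}

#' @export
print.log2_matrix <- function(x, ...) {
  cat("<log2_matrix> ", nrow(x$values), " proteins x ", ncol(x$values),
      " samples; ", sum(is.na(x$values)), " missing, ",
      sum(x$imputed), " imputed\n", sep = "")
  invisible(x)
}

#' Parameters for QRILC imputation
#'
#' @param tune Shrinkage applied to the estimated censoring probability when
#'   placing the upper truncation point of the imputation distribution: the
#'   truncation sits at the estimated complete-distribution quantile
#'   `missing_fraction + tune`. Default 0.001.
#' @param fit_range Quantile range of the *observed* values used for the
#'   quantile regression (default `c(0.001, 0.5)`: the lower half, where
#'   censoring distorts least symmetric information is retained).
#' @param n_quantiles Number of quantile knots in the regression.
#' @param min_observed Minimum observed values per sample required to fit.
#' @param seed Integer seed for the truncated-normal draws.
#' @return A list of class `qrilc_params`.
#' @export
qrilc_params <- function(tune = 0.001, fit_range = c(0.001, 0.5),
                         n_quantiles = 100, min_observed = 20, seed = 1L) {
  if (fit_range[1] <= 0 || fit_range[2] >= 1 || fit_range[1] >= fit_range[2]) {
    stop("`fit_range` must be an increasing pair inside (0, 1)",
         call. = FALSE)
  }
  structure(list(tune = tune, fit_range = fit_range,
                 n_quantiles = n_quantiles, min_observed = min_observed,
                 seed = as.integer(seed)),
            class = "qrilc_params")
}

#' QRILC: quantile-regression imputation of left-censored missing data
#'
#' Missing log2 intensities are treated as left-censored low-abundance
#' values. Per sample, the mean and standard deviation of the complete
#' (uncensored) log2 distribution are estimated by regressing the observed
#' lower-tail quantiles against the standard-normal quantiles of their
#' complete-distribution positions: with missing fraction `pi`, the observed
#' quantile at probability `p` sits at complete-distribution probability
#' `pi + (1 - pi) * p`, so a least-squares fit of observed quantiles on
#' `qnorm(pi + (1 - pi) * p)` yields intercept `mu` and slope `sigma`.
#' Each missing cell is then drawn from `N(mu, sigma)` truncated *above* at
#' the estimated censoring point `mu + sigma * qnorm(pi + tune)`.
#'
#' @param matrix_ A `log2_matrix` from [log2_transform()].
#' @param params A [qrilc_params()].
#' @return A `log2_matrix` with no missing values; `imputed` flags exactly
#'   the cells that were missing. Matrices without missing cells are
#'   returned unchanged.
#' @export
qrilc_impute <- function(matrix_, params = qrilc_params()) {
  stopifnot(inherits(matrix_, "log2_matrix"))
  vals <- matrix_$values
  if (!anyNA(vals)) return(matrix_)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(params$seed)
  imputed <- matrix_$imputed
  for (j in seq_len(ncol(vals))) {
    x <- vals[, j]
    miss <- is.na(x)
    if (!any(miss)) next
    obs <- x[!miss]
    if (length(obs) < params$min_observed) {
      stop("sample ", colnames(vals)[j], " has only ", length(obs),
           " observed values (need >= ", params$min_observed,
           "); filter sparse samples or proteins first", call. = FALSE)
    }
    pi_miss <- mean(miss)
    p <- seq(params$fit_range[1], params$fit_range[2],
             length.out = params$n_quantiles)
    y <- stats::quantile(obs, p, names = FALSE, type = 7)
    zq <- stats::qnorm(pi_miss + (1 - pi_miss) * p)
    fit <- stats::lm.fit(cbind(1, zq), y)
    mu <- fit$coefficients[1]
    sigma <- max(fit$coefficients[2], 1e-8)
    p_upper <- min(max(pi_miss + params$tune, 1e-6), 1 - 1e-6)
    upper_z <- stats::qnorm(p_upper)
    # inverse-cdf draw from N(mu, sigma) truncated above at mu+sigma*upper_z
    u <- stats::runif(sum(miss)) * stats::pnorm(upper_z)
    draws <- mu + sigma * stats::qnorm(pmax(u, 1e-12))
    vals[miss, j] <- draws
    imputed[miss, j] <- TRUE
  }
  structure(
    list(values = vals, imputed = imputed,
         proteins = matrix_$proteins, samples = matrix_$samples),
    class = "log2_matrix")
}

#' Estimated per-sample censoring points of a QRILC fit
#'
#' Returns, for each sample of a `log2_matrix`, the upper truncation point
#' the QRILC procedure would use; handy for checking that imputed values
#' never exceed it.
#'
#' @inheritParams qrilc_impute
#' @return Named numeric vector (NA for samples without missing values).
#' @export
qrilc_censoring_points <- function(matrix_, params = qrilc_params()) {
  vals <- matrix_$values
  out <- rep(NA_real_, ncol(vals))
  names(out) <- colnames(vals)
  for (j in seq_len(ncol(vals))) {
    x <- vals[, j]
    miss <- is.na(x)
    if (!any(miss)) next
    obs <- x[!miss]
    pi_miss <- mean(miss)
    p <- seq(params$fit_range[1], params$fit_range[2],
             length.out = params$n_quantiles)
    y <- stats::quantile(obs, p, names = FALSE, type = 7)
    zq <- stats::qnorm(pi_miss + (1 - pi_miss) * p)
    fit <- stats::lm.fit(cbind(1, zq), y)
    p_upper <- min(max(pi_miss + params$tune, 1e-6), 1 - 1e-6)
    out[j] <- fit$coefficients[1] +
      max(fit$coefficients[2], 1e-8) * stats::qnorm(p_upper)
  }
  out
}
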