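# Shared fixtures, built in code.

# A tiny hand-built quantification table. Intensities are chosen so that
# per-sample totals and per-group means are easy to verify by hand.
toy_quant <- function(intensities = NULL) {
  if (is.null(intensities)) {
    intensities <- matrix(
      c(10, 20, 5, 15,
        30, 40, 0, 25,
        60, 140, 95, 60),
      nrow = 3, byrow = TRUE,
      dimnames = list(c("COL1A1_HUMAN", "MMP14_HUMAN", "ALB_RAT"),
                      c("s1", "s2", "s3", "s4")))
  }
  protein_quant(
    intensities,
    proteins = tibble::tibble(
      protein_id = rownames(intensities),
      gene = sub("_.*$", "", rownames(intensities)),
      species = infer_species(rownames(intensities))),
    samples = {
      ns <- ncol(intensities)
      half <- ceiling(ns / 2)
      tibble::tibble(
        sample = colnames(intensities),
        model = "dECM-tumor",
        treatment = rep(c("labeled", "vehicle"),
                        c(half, ns - half)),
        fraction = "eluate",
        replicate = unlist(lapply(c(half, ns - half), seq_len)))
    })
}

# Small, fast simulation config for unit tests (the full-size study preset
# is exercised in the acceptance suite).
small_sim_config <- function(seed = 1, ...) {
  proteome_sim_config(n_proteins = 400, seed = seed, ...)
}

# Mean pairwise r^2 among sample pairs selected by a model predicate.
mean_pairwise_r2 <- function(corr, models, same_model = TRUE) {
  sel <- if (same_model) outer(models, models, "==") else
    outer(models, models, "!=")
  sel <- sel & upper.tri(corr$r)
  mean(corr$r[sel]^2)
}

# builds a log2_matrix of iid N(mu, sd) per sample with values below each
# sample's censor quantile removed (hard censoring: the regime QRILC models)
censored_gaussian_matrix <- function(n_prot, n_samp, mu, sd, q, seed) {
  set.seed(seed)
  vals <- matrix(rnorm(n_prot * n_samp, mu, sd), n_prot, n_samp,
                 dimnames = list(sprintf("P%05d", 1:n_prot),
                                 sprintf("s%02d", 1:n_samp)))
  for (j in seq_len(n_samp)) {
    thr <- quantile(vals[, j], q)
    vals[vals[, j] < thr, j] <- NA
  }
  structure(list(values = vals,
                 imputed = matrix(FALSE, n_prot, n_samp,
                                  dimnames = dimnames(vals)),
                 proteins = tibble::tibble(protein_id = rownames(vals)),
                 samples = tibble::tibble(sample = colnames(vals))),
            class = "log2_matrix")
}

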