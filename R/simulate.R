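#' Configuration for the synthetic proteome generator
#'
#' Builds the parameter set that [simulate_proteome()] turns into a full
#' labeled-versus-vehicle enrichment experiment: two tissue models
#' (a scaffold-based `"dECM-tumor"` and a scaffold-free `"tumoroid"`), each
#' with `input` (bulk ECM extract) and `eluate` (affinity-enriched) fractions
#' under `labeled` and `vehicle` treatments. The defaults are the study
#' conditions this package targets: 5 labeled / 3 vehicle dECM-tumor eluates
#' and 5 / 5 tumoroid eluates; 5.3- and 9.0-fold detection enrichment; 23.4-
#' and 11.0-fold intensity enrichment; 87.5% human and 30% rat eluate/input
#' recovery; 0.36% and 0.81% contaminant intensity shares; a matrisome
#' category shift from collagen-dominated inputs to regulator/secreted-factor
#' enriched eluates; and replicate log2-profile correlations of R^2 ~ 0.94
#' within and ~ 0.49 between models.
#'
#' @param n_proteins Number of protein groups in the simulated universe.
#' @param n_replicates Named list with entries `"dECM-tumor"` and
#'   `"tumoroid"`, each a named vector `c(labeled =, vehicle =)`; applied to
#'   both the input and eluate fractions of that model.
#' @param detection_enrichment Named vector per model: fold increase in the
#'   number of detected protein groups, labeled vs vehicle eluates.
#' @param intensity_enrichment Named vector per model: fold increase in total
#'   eluate intensity, labeled vs vehicle.
#' @param species_mix Named vector per model: human fraction of total input
#'   intensity (the remainder is rat; the tumoroid model is human-only).
#' @param human_recovery,rat_recovery Named vectors per model: pooled
#'   eluate/input intensity recovery fraction for each species.
#' @param contaminant_share Named vector per model: fraction of total input
#'   intensity carried by actin/tubulin/histone family proteins.
#' @param n_contaminants Number of contaminant-family protein groups.
#' @param matrisome_profile Data frame with columns `category`, `input_prop`,
#'   `eluate_prop`: intensity proportions of each matrisome category (plus
#'   `none`) in inputs and eluates; each column must sum to 1.
#' @param abundance_meanlog,abundance_sdlog Mean and total standard deviation
#'   of protein log2 abundance across the universe.
#' @param within_model_r2,between_model_r2 Targeted squared Pearson
#'   correlation between observed log2 eluate profiles of replicates from the
#'   same model and from different models. Variance components are derived
#'   from these targets with a deterministic correction for the attenuation
#'   caused by left-censored dropout (see [simulate_proteome()]).
#' @param noise_sdlog Replicate noise (log2 sd). `NULL` (default) derives it
#'   from `within_model_r2`; setting it overrides the derived value and the
#'   realized correlations will drift from their targets accordingly.
#' @param censor_quantile Depth of left-censoring: the per-sample intensity
#'   quantile around which dropout is centered.
#' @param censor_softness Logistic scale (log2 units) of the soft censoring
#'   boundary; smaller values approach a hard threshold.
#' @param seed Integer seed; identical configurations with identical seeds
#'   produce byte-identical tables.
#'
#' @return A list of class `proteome_sim_config`.
#' @seealso [simulate_proteome()]
#' @export
proteome_sim_config <- function(n_proteins = 2000,
                                n_replicates = list(
                                  "dECM-tumor" = c(labeled = 5, vehicle = 3),
                                  "tumoroid" = c(labeled = 5, vehicle = 5)
                                ),
                                detection_enrichment = c("dECM-tumor" = 5.3,
                                                         "tumoroid" = 9.0),
                                intensity_enrichment = c("dECM-tumor" = 23.4,
                                                         "tumoroid" = 11.0),
                                species_mix = c("dECM-tumor" = 0.966,
                                                "tumoroid" = 1.0),
                                human_recovery = c("dECM-tumor" = 0.875,
                                                   "tumoroid" = 0.875),
                                rat_recovery = c("dECM-tumor" = 0.30,
                                                 "tumoroid" = 0.30),
                                contaminant_share = c("dECM-tumor" = 0.0036,
                                                      "tumoroid" = 0.0081),
                                n_contaminants = 25,
                                matrisome_profile = default_matrisome_profile(),
                                abundance_meanlog = 23,
                                abundance_sdlog = 2.5,
                                within_model_r2 = 0.94,
                                between_model_r2 = 0.49,
                                noise_sdlog = NULL,
                                censor_quantile = 0.15,
                                censor_softness = 0.3,
                                seed = 1L) {
  cfg <- list(
    n_proteins = n_proteins, n_replicates = n_replicates,
    detection_enrichment = detection_enrichment,
    intensity_enrichment = intensity_enrichment,
    species_mix = species_mix,
    human_recovery = human_recovery, rat_recovery = rat_recovery,
    contaminant_share = contaminant_share, n_contaminants = n_contaminants,
    matrisome_profile = tibble::as_tibble(matrisome_profile),
    abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
    within_model_r2 = within_model_r2, between_model_r2 = between_model_r2,
    noise_sdlog = noise_sdlog,
    censor_quantile = censor_quantile, censor_softness = censor_softness,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "proteome_sim_config"
  cfg
}

#' Default matrisome category profile of the simulator
#'
#' Intensity proportions per category for the input (bulk ECM) and eluate
#' (enriched newly synthesized ECM) fractions. The eluate/input proportion
#' ratios encoded here are a collagen depletion to 0.26, a 2.0-fold gain of
#' ECM regulators and ECM-affiliated proteins, a 2.9-fold gain of
#' proteoglycans and a 9.2-fold gain of secreted factors, reflecting the
#' suppression of pre-existing structural scaffold proteins by the labeling
#' chemistry.
#'
#' @return Tibble with columns `category`, `input_prop`, `eluate_prop`.
#' @export
default_matrisome_profile <- function() {
  tibble::tibble(
    category = c("collagens", "ECM glycoproteins", "proteoglycans",
                 "ECM regulators", "ECM-affiliated proteins",
                 "secreted factors", "none"),
    input_prop = c(0.400, 0.080, 0.030, 0.060, 0.030, 0.012, 0.388),
    eluate_prop = c(0.104, 0.100, 0.087, 0.120, 0.060, 0.1104, 0.4186)
  )
}

sim_models <- c("dECM-tumor", "tumoroid")

validate_sim_config <- function(cfg) {
  err <- function(field, msg) {
    stop("invalid simulation config: `", field, "` ", msg, call. = FALSE)
  }
  if (!is.numeric(cfg$n_proteins) || cfg$n_proteins < 10) {
    err("n_proteins", "must be a number >= 10")
  }
  for (m in sim_models) {
    reps <- cfg$n_replicates[[m]]
    if (is.null(reps) || !all(c("labeled", "vehicle") %in% names(reps))) {
      err("n_replicates", paste0("must name labeled and vehicle arms for ", m))
    }
    if (any(reps < 2)) err("n_replicates", "must be >= 2 per arm")
  }
  for (field in c("detection_enrichment", "intensity_enrichment")) {
    v <- cfg[[field]]
    if (!all(sim_models %in% names(v)) || any(v <= 0)) {
      err(field, "must be positive and named per model")
    }
  }
  for (field in c("species_mix", "human_recovery", "rat_recovery",
                  "contaminant_share")) {
    v <- cfg[[field]]
    if (!all(sim_models %in% names(v)) || any(v < 0) || any(v > 1)) {
      err(field, "must be a fraction in [0, 1] named per model")
    }
  }
  prof <- cfg$matrisome_profile
  if (!all(c("category", "input_prop", "eluate_prop") %in% names(prof))) {
    err("matrisome_profile", "needs category, input_prop, eluate_prop columns")
  }
  if (abs(sum(prof$input_prop) - 1) > 1e-6 ||
      abs(sum(prof$eluate_prop) - 1) > 1e-6) {
    err("matrisome_profile", "proportions must sum to 1 per fraction")
  }
  if (!"none" %in% prof$category) {
    err("matrisome_profile", "must include a `none` (non-matrisome) category")
  }
  for (field in c("within_model_r2", "between_model_r2", "censor_quantile")) {
    v <- cfg[[field]]
    if (!is.numeric(v) || v < 0 || v >= 1) err(field, "must lie in [0, 1)")
  }
  if (cfg$between_model_r2 > cfg$within_model_r2) {
    err("between_model_r2", "cannot exceed within_model_r2")
  }
  if (cfg$abundance_sdlog <= 0) err("abundance_sdlog", "must be positive")
  if (cfg$censor_softness <= 0) err("censor_softness", "must be positive")
  invisible(cfg)
}

# Correlation observed between two jointly Gaussian log2 profiles after
# soft left-censoring of each margin: computed by numeric integration of the
# bivariate normal with logistic observation weights. Used to invert the
# dropout attenuation so that configured correlation targets refer to the
# emitted (post-dropout, pairwise-complete) data.
censored_pair_correlation <- function(rho, censor_quantile, softness_sd,
                                      n_grid = 161) {
  if (censor_quantile <= 0) return(rho)
  z <- seq(-6, 6, length.out = n_grid)
  thr <- stats::qnorm(censor_quantile)
  w <- stats::plogis((z - thr) / softness_sd)  # P(observed | value)
  # bivariate standard normal density on the grid
  d <- 1 - rho^2
  fz <- outer(z, z, function(x, y) {
    exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * d)) / (2 * pi * sqrt(d))
  })
  wt <- fz * outer(w, w)
  W <- sum(wt)
  mx <- sum(wt * z) / W            # symmetric in x and y
  exx <- sum(wt * z^2) / W
  exy <- sum(wt * outer(z, z)) / W
  (exy - mx^2) / (exx - mx^2)
}

# Invert the attenuation: latent rho whose censored observed correlation
# equals `target`. Deterministic (no randomness involved).
latent_rho_for_observed <- function(target, censor_quantile, softness_sd) {
  if (censor_quantile <= 0 || target <= 0) return(target)
  f <- function(r) censored_pair_correlation(r, censor_quantile, softness_sd) -
    target
  upper <- 0.9995
  if (f(upper) < 0) return(upper)
  stats::uniroot(f, lower = target, upper = upper, tol = 1e-5)$root
}

contaminant_gene_pool <- function() {
  c("ACTB", "ACTG1", "ACTA2", "ACTC1", "ACTG2",
    "TUBB", "TUBA1A", "TUBA1B", "TUBB4B", "TUBA4A",
    "HIST1H1B", "HIST1H1C", "HIST1H2BK", "HIST2H2AC", "HIST1H4A",
    "H2AFZ", "H2BC12", "H3C1", "H4C3")
}

#' Generate a synthetic labeled-versus-vehicle enrichment experiment
#'
#' Produces a [protein_quant] table covering both tissue models, both
#' fractions (input, eluate) and both treatments (labeled, vehicle), together
#' with the generating ground truth. The generator works on per-protein truth
#' means that are calibrated exactly to the configured summary statistics:
#'
#' * input intensities are lognormal with a shared protein effect, a
#'   model-specific effect and replicate noise; rat and contaminant-family
#'   intensity shares are scaled to `species_mix` and `contaminant_share`;
#' * labeled-eluate means are the input means reweighted per matrisome
#'   category to the eluate profile and rescaled per species so the pooled
#'   eluate/input recovery equals `human_recovery` / `rat_recovery`;
#' * vehicle-eluate means are a uniform random subset of the labeled proteome
#'   (size = detectable count / `detection_enrichment`), scaled so total
#'   vehicle intensity equals labeled / `intensity_enrichment`;
#' * each emitted sample adds lognormal replicate noise and then undergoes
#'   soft left-censoring around its own `censor_quantile` intensity quantile
#'   (dropout probability decreasing in intensity), with censored cells
#'   emitted as 0.
#'
#' The variance split between shared, model-specific and replicate components
#' is derived from `within_model_r2` / `between_model_r2` after numerically
#' inverting the correlation attenuation induced by the censoring step, so
#' the targets describe correlations measured on the emitted data.
#'
#' @param config A [proteome_sim_config()].
#' @return A list with elements `table` (a [protein_quant]) and `truth`
#'   (tibble of per-protein truth with attributes `precensor_totals`,
#'   `components` and `config`).
#' @export
simulate_proteome <- function(config) {
  stopifnot(inherits(config, "proteome_sim_config"))
  validate_sim_config(config)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- as.integer(config$n_proteins)
  prof <- config$matrisome_profile
  sigma_t <- config$abundance_sdlog

  ## ---- variance components ---------------------------------------------
  # category log2 offsets shared across models (same profile for both)
  d_cat <- log2(prof$eluate_prop / prof$input_prop)
  e_d <- sum(prof$input_prop * d_cat)
  var_d <- sum(prof$input_prop * d_cat^2) - e_d^2
  soft_sd <- config$censor_softness / sigma_t
  r_w <- latent_rho_for_observed(sqrt(config$within_model_r2),
                                 config$censor_quantile, soft_sd)
  r_b <- latent_rho_for_observed(sqrt(config$between_model_r2),
                                 config$censor_quantile, soft_sd)
  var_total <- sigma_t^2
  var_b <- max(r_b * var_total - var_d, 0.01 * var_total)
  var_u <- max((r_w - r_b) * var_total, 0)
  var_e <- if (is.null(config$noise_sdlog)) {
    max((1 - r_w) * var_total, 1e-4)
  } else {
    config$noise_sdlog^2
  }

  ## ---- protein universe -------------------------------------------------
  n_cont <- min(config$n_contaminants, n)
  contaminant <- c(rep(TRUE, n_cont), rep(FALSE, n - n_cont))
  species <- ifelse(
    stats::runif(n) < config$species_mix[["dECM-tumor"]], "human", "rat")
  species[contaminant] <- "human"   # intracellular contaminants follow cells
  category <- sample(prof$category, n, replace = TRUE, prob = prof$input_prop)
  category[contaminant] <- "none"
  pool <- contaminant_gene_pool()
  gene <- sprintf("G%04d", seq_len(n))
  gene[contaminant] <- pool[((seq_len(n_cont) - 1) %% length(pool)) + 1]
  protein_id <- sprintf("SIM%04d_%s", seq_len(n),
                        ifelse(species == "human", "HUMAN", "RAT"))
  division <- ifelse(
    category %in% c("collagens", "ECM glycoproteins", "proteoglycans"),
    "core matrisome",
    ifelse(category == "none", "non-matrisome", "matrisome-associated"))

  b <- stats::rnorm(n, 0, sqrt(var_b))
  u <- list("dECM-tumor" = stats::rnorm(n, 0, sqrt(var_u)),
            "tumoroid" = stats::rnorm(n, 0, sqrt(var_u)))

  truth <- tibble::tibble(protein_id, gene, species, division, category,
                          contaminant)

  ## ---- per-model truth means -------------------------------------------
  arm_means <- list()
  detectable <- list()
  for (m in sim_models) {
    present <- if (m == "tumoroid") species == "human" else rep(TRUE, n)
    inp <- ifelse(present, 2^(config$abundance_meanlog + b + u[[m]]), 0)
    # exact intensity-share calibration. First the matrisome category shares
    # of the input (so eluate/input proportion ratios reproduce the profile
    # rather than the sampling noise of small heavy-tailed categories), then
    # contaminant and rat shares, with the non-contaminant human block
    # defining the scale.
    tot0 <- sum(inp)
    for (k in seq_len(nrow(prof))) {
      in_cat <- present & category == prof$category[k]
      if (!any(in_cat) || sum(inp[in_cat]) == 0) next
      inp[in_cat] <- inp[in_cat] * prof$input_prop[k] * tot0 /
        sum(inp[in_cat])
    }
    grp_h <- present & !contaminant & species == "human"
    grp_r <- present & !contaminant & species == "rat"
    gamma <- config$contaminant_share[[m]]
    rat_share <- if (any(grp_r)) 1 - config$species_mix[[m]] else 0
    h_share <- 1 - gamma - rat_share
    total <- sum(inp[grp_h]) / h_share
    inp[contaminant & present] <- inp[contaminant & present] *
      gamma * total / sum(inp[contaminant & present])
    if (any(grp_r)) {
      inp[grp_r] <- inp[grp_r] * rat_share * total / sum(inp[grp_r])
    }

    # eluate: reweight categories to the eluate profile, exactly
    elu <- inp
    for (k in seq_len(nrow(prof))) {
      in_cat <- present & category == prof$category[k]
      if (!any(in_cat)) next
      elu[in_cat] <- inp[in_cat] * prof$eluate_prop[k] * sum(inp) /
        sum(inp[in_cat])
    }
    # species recovery: pooled eluate/input recovery exact per species
    for (sp in c("human", "rat")) {
      in_sp <- present & species == sp
      if (!any(in_sp)) next
      rec <- if (sp == "human") config$human_recovery[[m]] else
        config$rat_recovery[[m]]
      elu[in_sp] <- elu[in_sp] * rec * sum(inp[in_sp]) / sum(elu[in_sp])
    }

    # vehicle eluate: uniform background subset with exact intensity fold
    det_idx <- which(elu > 0)
    n_veh <- max(2L, round(length(det_idx) / config$detection_enrichment[[m]]))
    veh_idx <- sort(sample(det_idx, n_veh))
    veh <- numeric(n)
    veh[veh_idx] <- elu[veh_idx]
    veh[veh_idx] <- veh[veh_idx] * sum(elu) /
      (config$intensity_enrichment[[m]] * sum(veh))

    arm_means[[m]] <- list(input = inp, eluate_labeled = elu,
                           eluate_vehicle = veh)
    detectable[[m]] <- present
  }

  ## ---- emit samples -----------------------------------------------------
  sample_meta <- list()
  columns <- list()
  precensor <- c()
  sd_e <- sqrt(var_e)
  for (m in sim_models) {
    for (fr in c("input", "eluate")) {
      for (tr in c("labeled", "vehicle")) {
        n_rep <- config$n_replicates[[m]][[tr]]
        mu <- if (fr == "input") {
          arm_means[[m]]$input
        } else if (tr == "labeled") {
          arm_means[[m]]$eluate_labeled
        } else {
          arm_means[[m]]$eluate_vehicle
        }
        for (j in seq_len(n_rep)) {
          sid <- paste(gsub("[^A-Za-z0-9]", "", m), fr, tr, j, sep = ".")
          x <- numeric(n)
          det <- mu > 0
          x[det] <- 2^(log2(mu[det]) + stats::rnorm(sum(det), 0, sd_e))
          precensor[sid] <- sum(x)
          # soft left-censoring around the sample's own intensity quantile
          lx <- log2(x[det])
          thr <- stats::quantile(lx, config$censor_quantile, names = FALSE)
          p_miss <- stats::plogis((thr - lx) / config$censor_softness)
          drop <- stats::runif(sum(det)) < p_miss
          x[det][drop] <- 0
          columns[[sid]] <- x
          sample_meta[[sid]] <- tibble::tibble(
            sample = sid, model = m, treatment = tr, fraction = fr,
            replicate = j)
        }
      }
    }
  }
  intensities <- do.call(cbind, columns)
  rownames(intensities) <- protein_id
  samples <- dplyr::bind_rows(sample_meta)
  proteins <- tibble::tibble(protein_id, gene, species, division, category,
                             contaminant)
  table <- protein_quant(intensities, proteins, samples)

  ## ---- truth ------------------------------------------------------------
  truth$mean_input_decm <- arm_means[["dECM-tumor"]]$input
  truth$mean_eluate_labeled_decm <- arm_means[["dECM-tumor"]]$eluate_labeled
  truth$mean_eluate_vehicle_decm <- arm_means[["dECM-tumor"]]$eluate_vehicle
  truth$mean_input_tumoroid <- arm_means[["tumoroid"]]$input
  truth$mean_eluate_labeled_tumoroid <- arm_means[["tumoroid"]]$eluate_labeled
  truth$mean_eluate_vehicle_tumoroid <- arm_means[["tumoroid"]]$eluate_vehicle
  shared <- truth$mean_eluate_labeled_decm > 0 &
    truth$mean_eluate_labeled_tumoroid > 0
  truth$true_log2fc_model <- ifelse(
    shared,
    log2(truth$mean_eluate_labeled_decm) -
      log2(truth$mean_eluate_labeled_tumoroid),
    NA_real_)
  attr(truth, "precensor_totals") <- precensor
  attr(truth, "components") <- c(var_shared = var_b + var_d,
                                 var_model = var_u, var_noise = var_e,
                                 latent_r_within = r_w, latent_r_between = r_b)
  attr(truth, "config") <- config
  list(table = table, truth = truth)
}
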