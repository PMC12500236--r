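#' Enrichment quality control: labeled versus vehicle eluates
#'
#' Reproduces the pull-down quality metrics of a chemoselective enrichment
#' experiment. Per model, eluate samples are summarized by their identified
#' protein-group counts and their total (pre-normalization) intensities;
#' each arm is screened for outlier samples with Grubbs's test
#' (`alpha = 0.05`) and the labeled/vehicle fold ratios of the cleaned arm
#' means are reported. Across the four eluate arms
#' (model x treatment) a one-way ANOVA with Tukey HSD contrasts the counts
#' and intensities. Species-resolved eluate/input recovery and the
#' contaminant share of the inputs complete the report.
#'
#' @param table A [protein_quant] containing eluate (and, for the recovery
#'   metrics, input) samples of one or both models.
#' @param species_filter Restrict the count/intensity metrics to one species
#'   before summarizing (default `"human"`, the directly labeled species);
#'   `NULL` uses all proteins.
#' @param grubbs_alpha Significance level of the per-arm outlier screen.
#' @return List with `per_sample` (sample summaries and outlier flags),
#'   `folds` (per model: detection and intensity fold), `anova` (Tukey HSD
#'   tables for counts and intensities), `species_recovery` and
#'   `contaminant_share` (per model; `NULL` when inputs are absent).
#' @export
run_enrichment_qc <- function(table, species_filter = "human",
                              grubbs_alpha = 0.05) {
  stopifnot(inherits(table, "protein_quant"))
  eluates <- filter_samples(table, .data$fraction == "eluate")
  if (nrow(eluates$samples) == 0) stop("no eluate samples", call. = FALSE)
  metric_table <- if (!is.null(species_filter)) {
    filter_proteins(eluates, .data$species == species_filter)
  } else {
    eluates
  }
  per_sample <- metric_table$samples
  per_sample$protein_groups <- as.numeric(protein_group_counts(metric_table))
  per_sample$total_intensity <- as.numeric(sample_totals(metric_table))

  arms <- split(seq_len(nrow(per_sample)),
                paste(per_sample$model, per_sample$treatment))
  per_sample$count_outlier <- FALSE
  per_sample$intensity_outlier <- FALSE
  for (idx in arms) {
    if (length(idx) >= 3) {
      oc <- grubbs_outliers(per_sample$protein_groups[idx],
                            alpha = grubbs_alpha)
      oi <- grubbs_outliers(per_sample$total_intensity[idx],
                            alpha = grubbs_alpha)
      per_sample$count_outlier[idx[oc]] <- TRUE
      per_sample$intensity_outlier[idx[oi]] <- TRUE
    }
  }

  models <- unique(per_sample$model)
  folds <- lapply(models, function(m) {
    sub <- per_sample[per_sample$model == m, ]
    lab_c <- sub$protein_groups[sub$treatment == "labeled" &
                                  !sub$count_outlier]
    veh_c <- sub$protein_groups[sub$treatment == "vehicle" &
                                  !sub$count_outlier]
    lab_i <- sub$total_intensity[sub$treatment == "labeled" &
                                   !sub$intensity_outlier]
    veh_i <- sub$total_intensity[sub$treatment == "vehicle" &
                                   !sub$intensity_outlier]
    if (length(lab_c) == 0 || length(veh_c) == 0) {
      stop("model ", m, " is missing a labeled or vehicle eluate arm",
           call. = FALSE)
    }
    tibble::tibble(model = m,
                   detection_fold = mean(lab_c) / mean(veh_c),
                   intensity_fold = mean(lab_i) / mean(veh_i))
  })
  folds <- dplyr::bind_rows(folds)

  arm_factor <- factor(paste(per_sample$model, per_sample$treatment))
  anova_res <- NULL
  if (nlevels(arm_factor) >= 2) {
    fit_c <- stats::aov(per_sample$protein_groups ~ arm_factor)
    fit_i <- stats::aov(per_sample$total_intensity ~ arm_factor)
    anova_res <- list(counts = stats::TukeyHSD(fit_c),
                      intensities = stats::TukeyHSD(fit_i))
  }

  recovery <- NULL
  contam <- NULL
  if ("input" %in% table$samples$fraction) {
    recovery <- lapply(models, function(m) {
      el <- filter_samples(table, .data$model == m,
                           .data$fraction == "eluate",
                           .data$treatment == "labeled")
      inp <- filter_samples(table, .data$model == m,
                            .data$fraction == "input",
                            .data$treatment == "labeled")
      out <- species_recovery(el, inp)
      out$model <- m
      out
    })
    recovery <- dplyr::bind_rows(recovery)
    contam <- contaminant_share(
      filter_samples(table, .data$fraction == "input"))
  }

  list(per_sample = per_sample, folds = folds, anova = anova_res,
       species_recovery = recovery, contaminant_share = contam)
}

#' Differential comparison of two sample groups
#'
#' Executes the full differential track on an annotated quantification
#' table: total-intensity normalization, detection prefilter, log2
#' transform, optional QRILC imputation, Welch t-tests with
#' permutation-based FDR, geometric-mean fold changes and volcano
#' classification. Proteins failing the prefilter are returned as a
#' qualitative table of group means rather than dropped.
#'
#' @param table A [protein_quant] restricted to (or containing) the samples
#'   of the comparison.
#' @param group_a,group_b Character vectors of sample identifiers. Group A
#'   is the volcano's right-hand (positive log2FC) side.
#' @param normalize_within `"group"` normalizes each comparison group to its
#'   own average total (the labeled-versus-vehicle scheme); `"together"`
#'   normalizes all compared samples jointly (the cross-model scheme);
#'   `"none"` skips normalization.
#' @param k Prefilter threshold: minimum nonzero values per group.
#' @param impute Impute missing values with QRILC before testing (the
#'   cross-model usage); without imputation, group statistics use observed
#'   values only.
#' @param n_permutations,seed Permutation-FDR settings.
#' @param fc_threshold,q_threshold Volcano thresholds.
#' @param qrilc QRILC parameters ([qrilc_params()]); its seed is replaced by
#'   `seed`.
#' @return List with `results` (per-protein tibble: log2FC, t, p, q, volcano
#'   class, imputation counts), `qualitative` (group means of untestable
#'   proteins), `class_counts`, `p_cutoff`, `correlation` (pairwise Pearson
#'   over the compared samples' observed log2 values) and `n_permutations`.
#' @export
run_differential <- function(table, group_a, group_b,
                             normalize_within = c("group", "together",
                                                  "none"),
                             k = 2, impute = FALSE,
                             n_permutations = 10000, seed = 1L,
                             fc_threshold = 1, q_threshold = 0.05,
                             qrilc = qrilc_params()) {
  stopifnot(inherits(table, "protein_quant"))
  normalize_within <- match.arg(normalize_within)
  used <- filter_samples(table, .data$sample %in% c(group_a, group_b),
                         drop_empty = TRUE)
  used$samples$comparison_group <- ifelse(used$samples$sample %in% group_a,
                                          "A", "B")
  normed <- switch(normalize_within,
                   group = total_intensity_normalize(used, "comparison_group"),
                   together = total_intensity_normalize(used, character(0)),
                   none = used)
  split <- prefilter_min_nonzero(normed, group_a, group_b, k = k)
  lm2 <- log2_transform(split$testable)
  if (impute) {
    qrilc$seed <- as.integer(seed)
    lm2_complete <- qrilc_impute(lm2, qrilc)
  } else {
    lm2_complete <- lm2
  }
  is_a <- lm2_complete$samples$sample %in% group_a
  vals <- lm2_complete$values

  if (impute) {
    fdr_tab <- permutation_fdr(vals, ifelse(is_a, "A", "B"),
                               n_permutations = n_permutations, seed = seed)
    l2fc <- unname(rowMeans(vals[, is_a, drop = FALSE]) -
                     rowMeans(vals[, !is_a, drop = FALSE]))
  } else {
    # observed-only statistics (prefilter guarantees >= k per group)
    fdr_tab <- permutation_fdr_na(vals, is_a, n_permutations, seed)
    l2fc <- unname(apply(vals[, is_a, drop = FALSE], 1, mean, na.rm = TRUE) -
                     apply(vals[, !is_a, drop = FALSE], 1, mean,
                           na.rm = TRUE))
  }
  classes <- classify_volcano(l2fc, fdr_tab$q, fc_threshold, q_threshold)
  res <- tibble::tibble(
    protein_id = lm2_complete$proteins$protein_id,
    gene = lm2_complete$proteins$gene,
    species = lm2_complete$proteins$species,
    category = lm2_complete$proteins$category,
    log2fc = l2fc, fc = 2^l2fc,
    t = fdr_tab$t, p = fdr_tab$p, q = fdr_tab$q,
    volcano_class = classes,
    n_imputed_a = unname(rowSums(lm2_complete$imputed[, is_a, drop = FALSE])),
    n_imputed_b = unname(rowSums(lm2_complete$imputed[, !is_a,
                                                      drop = FALSE])))

  qual_mat <- split$qualitative$intensities
  qa <- colnames(qual_mat) %in% group_a
  qualitative <- tibble::tibble(
    protein_id = split$qualitative$proteins$protein_id,
    gene = split$qualitative$proteins$gene,
    mean_a = unname(rowMeans(qual_mat[, qa, drop = FALSE])),
    mean_b = unname(rowMeans(qual_mat[, !qa, drop = FALSE])))

  list(results = res,
       qualitative = qualitative,
       class_counts = table(factor(classes, levels = c("high_in_A",
                                                       "high_in_B", "NS"))),
       p_cutoff = p_cutoff_for_q(res$p, res$q, q_threshold),
       correlation = correlation_matrix(lm2),
       n_permutations = attr(fdr_tab, "n_permutations"))
}

# Permutation FDR tolerating NA cells: Welch statistics computed on observed
# values per group. Rows are required to have >= 2 observed values per group
# under the original labels (the prefilter contract); permuted labelings
# that leave a row with fewer than 2 observed values in a group contribute
# no null statistic for that row.
permutation_fdr_na <- function(values, is_a, n_permutations, seed) {
  n <- length(is_a); na_count <- sum(is_a)
  n_distinct <- choose(n, na_count)
  welch_rows_na <- function(mask_a) {
    t_row <- numeric(nrow(values)); p_row <- numeric(nrow(values))
    ok <- rep(TRUE, nrow(values))
    for (r in seq_len(nrow(values))) {
      x <- values[r, mask_a]; y <- values[r, !mask_a]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 2 || length(y) < 2) {
        ok[r] <- FALSE; t_row[r] <- NA; p_row[r] <- NA
        next
      }
      w <- welch_t(x, y)
      t_row[r] <- w$t; p_row[r] <- w$p
    }
    list(t = t_row, p = p_row, ok = ok)
  }
  obs <- welch_rows_na(is_a)
  if (any(!obs$ok)) {
    stop("a protein has fewer than 2 observed values in a group; ",
         "apply prefilter_min_nonzero first", call. = FALSE)
  }
  if (n_distinct <= n_permutations) {
    assign_idx <- utils::combn(n, na_count, simplify = FALSE)
  } else {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit({
      if (!is.null(old_seed)) {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    })
    set.seed(seed)
    assign_idx <- replicate(n_permutations, sort(sample.int(n, na_count)),
                            simplify = FALSE)
  }
  null_p <- numeric(0)
  for (idx in assign_idx) {
    mask <- rep(FALSE, n); mask[idx] <- TRUE
    np <- welch_rows_na(mask)$p
    null_p <- c(null_p, np[!is.na(np)])
  }
  n_perm <- length(assign_idx)
  q <- perm_fdr_from_p(obs$p, null_p, n_perm)
  out <- tibble::tibble(t = obs$t, df = NA_real_, p = obs$p, q = pmin(q, 1))
  attr(out, "n_permutations") <- n_perm
  out
}

#' Batch immunofluorescence quantification
#'
#' Runs the DAPI-map pipeline over a batch of images: split channels, build
#' the tissue mask from the blue channel, measure in/out mean intensities of
#' the signal channels and their normalized values. Images that fail to
#' process are skipped with a warning and recorded in the report.
#'
#' @param images Named list of images (arrays or channel lists accepted by
#'   [split_channels()]), or a directory of PNG files.
#' @param threshold,min_size,disk_radius,stretch_percentiles DAPI-map
#'   parameters, see [build_dapi_map()].
#' @param reference_channel Channel used for reference normalization of the
#'   other channel (`"green"`, `"red"` or `NULL` for area normalization
#'   only).
#' @return List with `report` (one row per image: mask parameters, tissue
#'   area, per-channel in/out means, normalized signals), `masks` (list of
#'   `tissue_map`s) and `skipped` (character vector of failed images).
#' @export
run_image_quant <- function(images, threshold = 0.15, min_size = 50,
                            disk_radius = 25,
                            stretch_percentiles = c(0.01, 0.99),
                            reference_channel = NULL) {
  if (is.character(images)) {
    if (!dir.exists(images)) stop("image directory not found: ", images,
                                  call. = FALSE)
    files <- list.files(images, pattern = "\\.png$", full.names = TRUE,
                        ignore.case = TRUE)
    if (length(files) == 0) stop("no PNG images in ", images, call. = FALSE)
    images <- lapply(files, function(f) try(png::readPNG(f), silent = TRUE))
    names(images) <- basename(files)
  }
  ids <- names(images)
  if (is.null(ids)) ids <- sprintf("image%02d", seq_along(images))
  rows <- list(); masks <- list(); skipped <- character(0)
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (inherits(img, "try-error")) {
      warning("skipping unreadable image: ", ids[i])
      skipped <- c(skipped, ids[i])
      next
    }
    res <- try({
      chans <- split_channels(img)
      tm <- build_dapi_map(chans$blue, threshold = threshold,
                           min_size = min_size, disk_radius = disk_radius,
                           stretch_percentiles = stretch_percentiles)
      reg_r <- region_mean_intensity(chans$red, tm)
      reg_g <- region_mean_intensity(chans$green, tm)
      row <- tibble::tibble(
        image = ids[i], threshold = threshold, min_size = min_size,
        disk_radius = disk_radius, tissue_area = tm$area,
        red_in = reg_r$inside_mean, red_out = reg_r$outside_mean,
        green_in = reg_g$inside_mean, green_out = reg_g$outside_mean,
        red_area_norm = normalized_signal(reg_r, mode = "area"),
        green_area_norm = normalized_signal(reg_g, mode = "area"))
      if (!is.null(reference_channel)) {
        sig <- if (reference_channel == "green") reg_r else reg_g
        ref <- if (reference_channel == "green") reg_g else reg_r
        row$reference_norm <- normalized_signal(sig, ref, mode = "reference")
      }
      masks[[ids[i]]] <- tm
      row
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      warning("skipping image that failed processing: ", ids[i])
      skipped <- c(skipped, ids[i])
      next
    }
    rows[[length(rows) + 1]] <- res
  }
  list(report = dplyr::bind_rows(rows), masks = masks, skipped = skipped)
}
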