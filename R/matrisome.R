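#' Matrisome category summary for an input/eluate pair
#'
#' For each matrisome category (plus the non-matrisome remainder), counts
#' the protein groups identified in each fraction (nonzero in at least
#' `min_nonzero` samples of that fraction) and computes the category's share
#' of total protein intensity, averaged over the fraction's samples. The
#' eluate/input ratios of counts and intensity proportions quantify how the
#' enrichment chemistry reshapes the ECM profile (collagen depletion,
#' regulator/secreted-factor gain).
#'
#' @param table An annotated [protein_quant] containing both fractions.
#' @param fractions Length-2 character vector naming the eluate-like and
#'   input-like fraction (default `c("eluate", "input")`).
#' @param min_nonzero Samples a protein must be nonzero in to count as
#'   identified (default 1).
#' @return Tibble with one row per category: counts, mean intensity
#'   proportions per fraction, `count_difference` (eluate - input) and
#'   `proportion_ratio` (eluate / input, `NA` when the input proportion is
#'   zero).
#' @export
category_summary <- function(table, fractions = c("eluate", "input"),
                             min_nonzero = 1) {
  stopifnot(inherits(table, "protein_quant"))
  have <- unique(table$samples$fraction)
  absent <- setdiff(fractions, have)
  if (length(absent) > 0) {
    stop("fraction(s) absent from sample metadata: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  cats <- unique(c(table$proteins$category))
  per_fraction <- function(fr) {
    idx <- table$samples$fraction == fr
    mat <- table$intensities[, idx, drop = FALSE]
    identified <- rowSums(mat > 0) >= min_nonzero
    # per-sample proportion of each category, averaged over samples
    totals <- colSums(mat)
    props <- vapply(cats, function(cc) {
      rows <- table$proteins$category == cc
      mean(colSums(mat[rows, , drop = FALSE]) / totals)
    }, numeric(1))
    counts <- vapply(cats, function(cc) {
      sum(identified & table$proteins$category == cc)
    }, numeric(1))
    list(counts = unname(counts), props = unname(props))
  }
  el <- per_fraction(fractions[1])
  inp <- per_fraction(fractions[2])
  tibble::tibble(
    category = cats,
    eluate_count = el$counts,
    input_count = inp$counts,
    eluate_proportion = el$props,
    input_proportion = inp$props,
    count_difference = el$counts - inp$counts,
    proportion_ratio = ifelse(inp$props > 0, el$props / inp$props, NA_real_))
}

#' Species-resolved eluate/input recovery
#'
#' Quantifies how much of each species' input protein intensity survives the
#' enrichment: `recovery_percent = 100 * (species eluate sum) / (species
#' input sum)` over pooled sample sums (per-sample means behind
#' `per_sample = TRUE`), plus each species' share of the total eluate
#' intensity. For a labeling chemistry driven by the metabolically active
#' (human) cells, human recovery is expected near the input level and
#' scaffold-species (rat) recovery strongly reduced.
#'
#' @param eluate_table,input_table [protein_quant] tables of the two
#'   fractions, normalized comparably; species labels must be present.
#' @param per_sample Average per-sample sums instead of pooling (default
#'   `FALSE`: pooled sums).
#' @return Tibble with one row per species: `eluate_sum`, `input_sum`,
#'   `recovery_percent` (`NA`-flagged when the species has zero input
#'   intensity) and `eluate_share_percent` (shares sum to 100).
#' @export
species_recovery <- function(eluate_table, input_table, per_sample = FALSE) {
  stopifnot(inherits(eluate_table, "protein_quant"),
            inherits(input_table, "protein_quant"))
  species <- sort(unique(c(eluate_table$proteins$species,
                           input_table$proteins$species)))
  sum_by_species <- function(tab, sp) {
    rows <- tab$proteins$species == sp
    mat <- tab$intensities[rows, , drop = FALSE]
    if (per_sample) mean(colSums(mat)) else sum(mat)
  }
  el <- unname(vapply(species, sum_by_species, numeric(1),
                      tab = eluate_table))
  inp <- unname(vapply(species, sum_by_species, numeric(1),
                       tab = input_table))
  tibble::tibble(
    species = species,
    eluate_sum = el,
    input_sum = inp,
    recovery_percent = ifelse(inp > 0, 100 * el / inp, NA_real_),
    eluate_share_percent = 100 * el / sum(el))
}

#' Default contaminant-family gene patterns
#'
#' Curated gene-symbol prefixes for the major intracellular contaminant
#' families surveyed in ECM preparations: actins, tubulins and histones
#' (classic HIST* symbols plus the H1/H2A/H2B/H3/H4 cluster nomenclature).
#'
#' @return Named list of regular expressions per family.
#' @export
contaminant_patterns <- function() {
  list(
    actin = "^ACT",
    tubulin = "^TUB",
    histone = "^(HIST|H1[0-9-]|H2A|H2B|H3[C0-9-]|H4[C0-9-]|H1F|H2AF|H3F)")
}

#' Intracellular contaminant share of input intensity
#'
#' Sums the intensity of proteins whose gene symbols match the
#' actin/tubulin/histone family patterns and reports it as a percentage of
#' total intensity, per model. A low share supports the selectivity of the
#' ECM extraction.
#'
#' @param input_table A [protein_quant] of input samples (gene symbols
#'   required).
#' @param patterns Named list of regular expressions (default
#'   [contaminant_patterns()]).
#' @return Tibble with one row per model: `contaminant_sum`, `total_sum`,
#'   `share_percent`.
#' @export
contaminant_share <- function(input_table, patterns = contaminant_patterns()) {
  stopifnot(inherits(input_table, "protein_quant"))
  genes <- toupper(input_table$proteins$gene)
  is_contam <- Reduce(`|`, lapply(patterns, grepl, x = genes))
  models <- unique(input_table$samples$model)
  rows <- lapply(models, function(m) {
    idx <- input_table$samples$model == m
    mat <- input_table$intensities[, idx, drop = FALSE]
    total <- sum(mat)
    contam <- sum(mat[is_contam, , drop = FALSE])
    tibble::tibble(model = m, contaminant_sum = contam, total_sum = total,
                   share_percent = if (total > 0) 100 * contam / total else 0)
  })
  dplyr::bind_rows(rows)
}
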