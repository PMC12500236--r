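#' Protein quantification table
#'
#' The central container of the package: a proteins x samples matrix of
#' label-free quantification (LFQ) intensities together with per-protein
#' annotations and per-sample metadata. Zero encodes "not observed"
#' (the convention of MetaMorpheus-style protein-group exports); values are
#' only converted to explicit missingness at the log2 stage.
#'
#' @param intensities Numeric matrix (proteins x samples), non-negative, with
#'   unique rownames (protein accessions) and colnames (sample identifiers).
#' @param proteins Data frame of per-protein annotations with at least a
#'   `protein_id` column matching `rownames(intensities)`. Optional columns
#'   `gene`, `species`, `division`, `category` are filled with defaults when
#'   absent.
#' @param samples Data frame of per-sample metadata with a `sample` column
#'   matching `colnames(intensities)` and columns `model`, `treatment`,
#'   `fraction`, `replicate`.
#'
#' @return An object of class `protein_quant`: a list with elements
#'   `intensities`, `proteins` and `samples`.
#' @export
protein_quant <- function(intensities, proteins, samples) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  }
  # R drops zero-length dimnames to NULL, so empty margins pass name checks
  row_ids <- rownames(intensities)
  col_ids <- colnames(intensities)
  if (is.null(row_ids) && nrow(intensities) == 0) row_ids <- character(0)
  if (is.null(col_ids) && ncol(intensities) == 0) col_ids <- character(0)
  if (is.null(row_ids) || is.null(col_ids)) {
    stop("`intensities` must have protein rownames and sample colnames",
         call. = FALSE)
  }
  if (anyNA(intensities)) {
    stop("`intensities` must not contain NA; encode non-detection as 0",
         call. = FALSE)
  }
  if (any(intensities < 0)) {
    stop("`intensities` must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(row_ids)) {
    dup <- row_ids[duplicated(row_ids)][1]
    stop("duplicate protein_id: ", dup, call. = FALSE)
  }
  proteins <- tibble::as_tibble(proteins)
  samples <- tibble::as_tibble(samples)
  if (!"protein_id" %in% names(proteins)) {
    stop("`proteins` must have a protein_id column", call. = FALSE)
  }
  if (!identical(as.character(proteins$protein_id), row_ids)) {
    stop("`proteins$protein_id` must match rownames(intensities) in order",
         call. = FALSE)
  }
  required_meta <- c("sample", "model", "treatment", "fraction", "replicate")
  missing_meta <- setdiff(required_meta, names(samples))
  if (length(missing_meta) > 0) {
    stop("sample metadata is missing column(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  if (!identical(as.character(samples$sample), col_ids)) {
    stop("`samples$sample` must match colnames(intensities) in order",
         call. = FALSE)
  }
  if (!"gene" %in% names(proteins)) proteins$gene <- proteins$protein_id
  if (!"species" %in% names(proteins)) proteins$species <- "unknown"
  if (!"division" %in% names(proteins)) proteins$division <- "non-matrisome"
  if (!"category" %in% names(proteins)) proteins$category <- "none"
  structure(
    list(intensities = intensities, proteins = proteins, samples = samples),
    class = "protein_quant"
  )
}

#' @export
print.protein_quant <- function(x, ...) {
  cat("<protein_quant> ", nrow(x$intensities), " proteins x ",
      ncol(x$intensities), " samples\n", sep = "")
  nz <- mean(x$intensities > 0)
  cat(sprintf("  nonzero cells: %.1f%%\n", 100 * nz))
  arms <- dplyr::count(x$samples, .data$model, .data$treatment, .data$fraction)
  cat("  arms:\n")
  for (i in seq_len(nrow(arms))) {
    cat(sprintf("    %s / %s / %s: n=%d\n", arms$model[i], arms$treatment[i],
                arms$fraction[i], arms$n[i]))
  }
  invisible(x)
}

#' @export
dim.protein_quant <- function(x) dim(x$intensities)

#' Subset a protein_quant by sample metadata
#'
#' @param table A `protein_quant`.
#' @param ... Logical expressions evaluated on the sample metadata
#'   (as in [dplyr::filter()]).
#' @param drop_empty Drop proteins with all-zero intensities in the retained
#'   samples (default `FALSE`).
#' @return A `protein_quant` restricted to the matching samples.
#' @export
filter_samples <- function(table, ..., drop_empty = FALSE) {
  stopifnot(inherits(table, "protein_quant"))
  keep <- dplyr::filter(table$samples, ...)
  idx <- match(keep$sample, table$samples$sample)
  out <- protein_quant(table$intensities[, idx, drop = FALSE],
                       table$proteins, keep)
  if (drop_empty) {
    nz <- rowSums(out$intensities > 0) > 0
    out <- protein_quant(out$intensities[nz, , drop = FALSE],
                         out$proteins[nz, ], out$samples)
  }
  out
}

#' Subset a protein_quant by protein annotations
#'
#' @param table A `protein_quant`.
#' @param ... Logical expressions evaluated on the protein annotation table.
#' @return A `protein_quant` restricted to the matching proteins.
#' @export
filter_proteins <- function(table, ...) {
  stopifnot(inherits(table, "protein_quant"))
  keep <- dplyr::filter(table$proteins, ...)
  idx <- match(keep$protein_id, table$proteins$protein_id)
  protein_quant(table$intensities[idx, , drop = FALSE], keep, table$samples)
}

#' Per-sample total intensities
#'
#' @param table A `protein_quant`.
#' @return Named numeric vector of per-sample summed intensities.
#' @export
sample_totals <- function(table) {
  stopifnot(inherits(table, "protein_quant"))
  colSums(table$intensities)
}

#' Per-sample detected protein-group counts
#'
#' A protein group counts as identified in a sample when its intensity is
#' nonzero there.
#'
#' @param table A `protein_quant`.
#' @return Named integer vector of per-sample nonzero-protein counts.
#' @export
protein_group_counts <- function(table) {
  stopifnot(inherits(table, "protein_quant"))
  colSums(table$intensities > 0)
}
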