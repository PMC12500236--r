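#' Read a quantified-protein table with sample metadata
#'
#' Ingests a wide label-free quantification export (one protein group per
#' row, one intensity column per sample, in the style of MetaMorpheus
#' "AllQuantifiedProteinGroups" output) together with a sample-metadata
#' table, and assembles a validated [protein_quant]. Zeros encode
#' non-detection. When the quant table has no `species` column, species is
#' inferred from the accession suffix convention (`*_HUMAN` / `*_RAT`,
#' otherwise `unknown`); for ambiguous protein groups (semicolon-separated
#' accessions) the first-listed accession decides.
#'
#' @param path TSV file with columns `protein_id`, optionally `gene` and
#'   `species`, and one numeric column per sample.
#' @param metadata_path CSV file with columns `sample`, `model`,
#'   `treatment`, `fraction`, `replicate`; every intensity column of the
#'   quant table must appear in `sample`.
#' @return A [protein_quant].
#' @export
read_quant_table <- function(path, metadata_path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(raw)) {
    stop("quant table must have a protein_id column", call. = FALSE)
  }
  meta <- utils::read.csv(metadata_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  required_meta <- c("sample", "model", "treatment", "fraction", "replicate")
  missing_meta <- setdiff(required_meta, names(meta))
  if (length(missing_meta) > 0) {
    stop("sample metadata is missing column(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  annot_cols <- intersect(c("protein_id", "gene", "species"), names(raw))
  sample_cols <- setdiff(names(raw), annot_cols)
  unmapped <- setdiff(sample_cols, meta$sample)
  if (length(unmapped) > 0) {
    stop("intensity column(s) without metadata: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(raw$protein_id)) {
    stop("duplicate protein_id: ",
         raw$protein_id[duplicated(raw$protein_id)][1], call. = FALSE)
  }
  intensities <- as.matrix(raw[sample_cols])
  if (!is.numeric(intensities)) {
    stop("intensity columns must be numeric", call. = FALSE)
  }
  if (any(intensities < 0)) {
    stop("negative intensity found; non-detection must be encoded as 0",
         call. = FALSE)
  }
  rownames(intensities) <- raw$protein_id
  proteins <- tibble::tibble(protein_id = raw$protein_id)
  proteins$gene <- if ("gene" %in% names(raw)) raw$gene else raw$protein_id
  proteins$species <- if ("species" %in% names(raw)) {
    raw$species
  } else {
    infer_species(raw$protein_id)
  }
  meta <- meta[match(sample_cols, meta$sample), , drop = FALSE]
  protein_quant(intensities, proteins, tibble::as_tibble(meta))
}

#' Infer species from accession suffixes
#'
#' Applies the `*_HUMAN` / `*_RAT` suffix convention to (possibly
#' semicolon-separated) accession strings; the first-listed accession of an
#' ambiguous group decides.
#'
#' @param accessions Character vector of protein accessions.
#' @return Character vector with values `"human"`, `"rat"` or `"unknown"`.
#' @export
infer_species <- function(accessions) {
  first <- sub(";.*$", "", accessions)
  ifelse(grepl("_HUMAN$", first), "human",
         ifelse(grepl("_RAT$", first), "rat", "unknown"))
}

#' Read a matrisome annotation table
#'
#' @param path CSV with columns `accession`, `division`, `category`.
#' @return Tibble with those columns.
#' @export
read_matrisome_annotation <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("accession", "division", "category")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols) > 0) {
    stop("annotation is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(ann[need])
}

#' Attach matrisome annotations to a quantification table
#'
#' Every protein receives a matrisome `division` and `category` by accession
#' lookup (falling back to gene-symbol lookup for accessions not in the
#' annotation); proteins absent from the annotation are
#' `non-matrisome` / `none`.
#'
#' @param table A [protein_quant].
#' @param annotation Tibble from [read_matrisome_annotation()] (columns
#'   `accession`, `division`, `category`).
#' @return The table with updated `division` and `category` columns.
#' @export
attach_annotations <- function(table, annotation) {
  stopifnot(inherits(table, "protein_quant"))
  annotation <- tibble::as_tibble(annotation)
  hit <- match(table$proteins$protein_id, annotation$accession)
  fallback <- match(table$proteins$gene, annotation$accession)
  hit[is.na(hit)] <- fallback[is.na(hit)]
  proteins <- table$proteins
  proteins$division <- ifelse(is.na(hit), "non-matrisome",
                              annotation$division[hit])
  proteins$category <- ifelse(is.na(hit), "none", annotation$category[hit])
  protein_quant(table$intensities, proteins, table$samples)
}

#' Write a quantification table (and metadata) to disk
#'
#' Writes the intensity matrix as TSV (stable column order: `protein_id`,
#' `gene`, `species`, then samples in table order) and the sample metadata
#' as CSV, such that [read_quant_table()] round-trips the object.
#'
#' @param table A [protein_quant].
#' @param path Output TSV path for the quant table.
#' @param metadata_path Output CSV path for sample metadata.
#' @param overwrite Refuse to clobber existing files unless `TRUE`.
#' @return Invisibly, the paths written.
#' @export
write_quant_table <- function(table, path, metadata_path,
                              overwrite = FALSE) {
  stopifnot(inherits(table, "protein_quant"))
  for (f in c(path, metadata_path)) {
    if (file.exists(f) && !overwrite) {
      stop("refusing to overwrite ", f, " (set overwrite = TRUE)",
           call. = FALSE)
    }
  }
  df <- data.frame(protein_id = table$proteins$protein_id,
                   gene = table$proteins$gene,
                   species = table$proteins$species,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(table$intensities, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(as.data.frame(table$samples), metadata_path,
                   row.names = FALSE, quote = FALSE)
  invisible(c(path, metadata_path))
}

#' Write analysis result tables as provenance-stamped CSV
#'
#' Each data frame in `tables` is written to `<out_dir>/<name>.csv` with a
#' leading comment line recording the run seed and a hash of the
#' configuration, so re-runs are auditable. Column order is preserved as
#' given.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed to stamp into the header.
#' @param config_hash Configuration digest string to stamp (any stable
#'   identifier; see [config_fingerprint()]).
#' @param overwrite Refuse to clobber existing files unless `TRUE`.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir, seed = NA, config_hash = "",
                          overwrite = FALSE) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    if (file.exists(f) && !overwrite) {
      stop("refusing to overwrite ", f, " (set overwrite = TRUE)",
           call. = FALSE)
    }
    con <- file(f, "w")
    writeLines(sprintf("# seed=%s config=%s", seed, config_hash), con)
    utils::write.csv(as.data.frame(tables[[nm]]), con, row.names = FALSE)
    close(con)
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' Stable fingerprint of a configuration object
#'
#' Deterministic short digest of a (nested) configuration list, computed
#' from its deparsed representation; used to stamp output files.
#'
#' @param config Any R object.
#' @return A character scalar.
#' @export
config_fingerprint <- function(config) {
  txt <- paste(deparse(config, control = "all"), collapse = "")
  # simple polynomial rolling hash; stability matters, cryptography does not
  h <- 0
  for (v in utf8ToInt(txt)) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}

#' Read back a results CSV written by [write_results()]
#'
#' @param path CSV path.
#' @return Tibble (the header comment is skipped).
#' @export
read_results <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE))
}
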