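# TSV readers/writers for the pipeline's tabular interchange formats.
# All files are plain tab-separated text with a header row.

#' Write / read a gene catalog TSV
#'
#' Columns: `gene_id`, `length_bp`, `msp_id`, `is_marker`, `is_core`,
#' `ko_ids`, `cazy_families` (annotation columns semicolon-joined, empty when
#' unannotated).
#'
#' @param catalog a `gene_catalog`.
#' @param path file path.
#' @return `read_catalog_tsv` returns a validated `gene_catalog`.
#' @export
write_catalog_tsv <- function(catalog, path) {
  utils::write.table(as.data.frame(catalog), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_catalog_tsv
#' @export
read_catalog_tsv <- function(path) {
  catalog <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  catalog$is_marker <- as.logical(catalog$is_marker)
  catalog$is_core <- as.logical(catalog$is_core)
  if (!"ko_ids" %in% names(catalog)) catalog$ko_ids <- NA_character_
  if (!"cazy_families" %in% names(catalog)) catalog$cazy_families <- NA_character_
  catalog$ko_ids <- as.character(catalog$ko_ids)
  catalog$cazy_families <- as.character(catalog$cazy_families)
  catalog$msp_id <- as.character(catalog$msp_id)
  class(catalog) <- c("gene_catalog", "data.frame")
  validate_catalog(catalog)
  catalog
}

#' Write / read a numeric matrix TSV
#'
#' Row identifiers in the first column (`id`), sample ids as remaining column
#' headers. Used for gene count, frequency, MSP and functional matrices.
#'
#' @param mat numeric matrix with row and column names.
#' @param path file path.
#' @return `read_matrix_tsv` returns the matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), as.data.frame(mat, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param stage optional stage tag to attach (`"raw"`, `"downsized"`,
#'   `"frequency"`).
#' @export
read_matrix_tsv <- function(path, stage = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  if (!is.null(stage)) attr(mat, "stage") <- stage
  mat
}

#' Write / read alignment records TSV
#'
#' Columns: `sample_id`, `read_id`, `gene_ids` (candidate genes
#' semicolon-joined; one id for unique reads).
#'
#' @param alignments an `alignment_records` data.frame.
#' @param path file path.
#' @return `read_alignments_tsv` returns an `alignment_records` data.frame
#'   with a `gene_ids` list column.
#' @export
write_alignments_tsv <- function(alignments, path) {
  df <- data.frame(sample_id = alignments$sample_id,
                   read_id = alignments$read_id,
                   gene_ids = vapply(alignments$gene_ids, paste, "",
                                     collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignments_tsv
#' @export
read_alignments_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$gene_ids <- strsplit(df$gene_ids, ";", fixed = TRUE)
  class(df) <- c("alignment_records", "data.frame")
  df
}

#' Write / read a crossover design TSV
#' @param design a `crossover_design`.
#' @param path file path.
#' @return `read_design_tsv` returns a `crossover_design`.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  design <- utils::read.delim(path, stringsAsFactors = FALSE)
  design$phase <- design_phase(design)
  class(design) <- c("crossover_design", "data.frame")
  design
}

#' Write / read a long clinical table TSV
#' @param clinical long clinical data.frame (`subject_id`, `visit`,
#'   `variable`, `time_min`, `value`).
#' @param path file path.
#' @return `read_clinical_tsv` returns the data.frame.
#' @export
write_clinical_tsv <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_clinical_tsv
#' @export
read_clinical_tsv <- function(path) {
  cl <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  cl$time_min <- as.numeric(cl$time_min)
  cl
}

#' Write / read a module-definition TSV
#' @param modules a `module_set` data.frame (`module_id`, `kind`, `items`
#'   semicolon-joined).
#' @param path file path.
#' @return `read_modules_tsv` returns a `module_set`.
#' @export
write_modules_tsv <- function(modules, path) {
  utils::write.table(as.data.frame(modules), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_modules_tsv
#' @export
read_modules_tsv <- function(path) {
  mods <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(mods) <- c("module_set", "data.frame")
  mods
}
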