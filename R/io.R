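#' Tabular dialect
#'
#' All files are tab-delimited UTF-8 with a header row and '.' as decimal
#' separator.  Readers validate eagerly and name the offending column, gene
#' or line in error messages; writers produce files their paired reader
#' round-trips exactly.
#'
#' @name ironvirt_io
NULL

read_tsv_checked <- function(path, required) {
  if (!file.exists(path))
    stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  df
}

parse_numeric_col <- function(df, col, path) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  bad <- is.na(x) & !(df[[col]] %in% c("NA", ""))
  if (any(bad))
    stop("unparseable ", col, " in ", path, " at line(s): ",
         paste(which(bad) + 1L, collapse = ", "))   # +1 for the header
  x
}

#' Read / write a per-comparison differential expression table
#'
#' @param path TSV path with columns `gene_id`, `log2fc`, `p_value`.
#' @param comparison Optional one-row comparison spec attached to the table.
#' @return [read_comparison_table()]: a [comparison_table()];
#'   [write_comparison_table()]: the path, invisibly.
#' @export
read_comparison_table <- function(path, comparison = NULL) {
  df <- read_tsv_checked(path, c("gene_id", "log2fc", "p_value"))
  comparison_table(df$gene_id,
                   parse_numeric_col(df, "log2fc", path),
                   parse_numeric_col(df, "p_value", path),
                   comparison = comparison)
}

#' @rdname read_comparison_table
#' @param table A [comparison_table()] to write.
#' @export
write_comparison_table <- function(table, path) {
  utils::write.table(as.data.frame(table)[c("gene_id", "log2fc", "p_value")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a comparison manifest
#'
#' @param path Manifest TSV with columns `comparison_id`, `tissue`,
#'   `numerator_line`, `numerator_iron`, `denominator_line`,
#'   `denominator_iron` and optionally `number`.
#' @return A validated comparison spec `data.frame`.
#' @export
read_comparison_manifest <- function(path) {
  df <- read_tsv_checked(path, c("comparison_id", "tissue", "numerator_line",
                                 "numerator_iron", "denominator_line",
                                 "denominator_iron"))
  if ("number" %in% names(df)) {
    df$number <- as.integer(df$number)
  } else if (all(grepl("^c[1-7]$", df$comparison_id))) {
    df$number <- as.integer(sub("^c", "", df$comparison_id))
  }
  df$comparison_class <-
    ifelse(df$numerator_line == df$denominator_line, "intra_line",
           "inter_line")
  validate_comparison_spec(df)
  df
}

#' @rdname read_comparison_manifest
#' @param spec Comparison spec `data.frame` to write.
#' @export
write_comparison_manifest <- function(spec, path) {
  utils::write.table(spec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a ternary regulation matrix with its measured mask
#'
#' The matrix TSV has genes as rows (`gene_id` column) and comparison ids as
#' columns with cells in `{-1, 0, 1}`; the parallel mask TSV holds
#' `TRUE`/`FALSE`.
#'
#' @param path Matrix TSV path.
#' @param mask_path Mask TSV path (written next to `path` by the writer).
#' @param manifest Comparison spec `data.frame` covering the matrix columns.
#' @return A `regulation_matrix`.
#' @export
read_regulation_matrix <- function(path, mask_path, manifest) {
  df <- read_tsv_checked(path, "gene_id")
  ids <- setdiff(names(df), "gene_id")
  calls <- as.matrix(vapply(df[ids], function(col) {
    v <- suppressWarnings(as.integer(col))
    if (any(is.na(v)) || !all(v %in% c(-1L, 0L, 1L)))
      stop("matrix cells must be -1/0/1 in ", path)
    v
  }, integer(nrow(df))))
  if (nrow(df) == 1) calls <- matrix(calls, nrow = 1, dimnames = list(NULL, ids))
  rownames(calls) <- normalize_agi(df$gene_id)
  md <- read_tsv_checked(mask_path, "gene_id")
  if (!identical(normalize_agi(md$gene_id), rownames(calls)))
    stop("mask gene order differs from matrix in ", mask_path)
  measured <- as.matrix(vapply(md[ids], function(col) {
    v <- toupper(col) %in% "TRUE"
    v
  }, logical(nrow(md))))
  if (nrow(md) == 1)
    measured <- matrix(measured, nrow = 1, dimnames = list(NULL, ids))
  rownames(measured) <- rownames(calls)
  manifest <- manifest[match(ids, manifest$comparison_id), , drop = FALSE]
  if (anyNA(manifest$comparison_id))
    stop("manifest does not cover all matrix columns in ", path)
  new_regulation_matrix(rownames(calls), manifest, calls, measured)
}

#' @rdname read_regulation_matrix
#' @param matrix A `regulation_matrix` to write.
#' @export
write_regulation_matrix <- function(matrix, path, mask_path) {
  df <- data.frame(gene_id = matrix$genes, matrix$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  md <- data.frame(gene_id = matrix$genes, matrix$measured,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(md, mask_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a gene-by-study ternary matrix with its study manifest
#'
#' @param path Matrix TSV: `gene_id` column then one column per study with
#'   cells in `{-1, 0, 1}`.
#' @param manifest_path Study manifest TSV with columns `study_id`, `label`,
#'   `induced_only`, `tissue`.
#' @return A [study_matrix()]; a -1 in an induced-only study's column is
#'   rejected naming the study and gene.
#' @export
read_study_matrix <- function(path, manifest_path) {
  sm <- read_tsv_checked(manifest_path,
                         c("study_id", "label", "induced_only", "tissue"))
  studies <- study_meta(sm$study_id, sm$label,
                        toupper(sm$induced_only) %in% "TRUE", sm$tissue)
  df <- read_tsv_checked(path, "gene_id")
  ids <- setdiff(names(df), "gene_id")
  values <- matrix(0L, nrow(df), length(ids),
                   dimnames = list(normalize_agi(df$gene_id), ids))
  for (j in seq_along(ids)) {
    v <- suppressWarnings(as.integer(df[[ids[j]]]))
    bad <- is.na(v) | !v %in% c(-1L, 0L, 1L)
    if (any(bad))
      stop("cell not in {-1,0,1} in ", path, ", study ", ids[j],
           ", gene(s): ", paste(rownames(values)[bad], collapse = ", "))
    values[, j] <- v
  }
  study_matrix(values, studies)
}

#' @rdname read_study_matrix
#' @param matrix A [study_matrix()] to write.
#' @export
write_study_matrix <- function(matrix, path, manifest_path) {
  df <- data.frame(gene_id = matrix$genes, matrix$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(matrix$studies, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Published cross-study marker compendium
#'
#' Loads the ternary calls of the 25 most stable iron-deficiency marker
#' genes (12 up-, 13 down-regulated) across the 14 published wild-type
#' -Fe vs +Fe transcriptome analyses, two of which are induced-only, as
#' shipped with the package.
#'
#' @return A [study_matrix()] of 25 genes by 14 studies.
#' @export
marker_compendium <- function() {
  read_study_matrix(
    system.file("extdata", "marker_compendium.tsv", package = "ironvirt",
                mustWork = TRUE),
    system.file("extdata", "marker_compendium_studies.tsv",
                package = "ironvirt", mustWork = TRUE))
}
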