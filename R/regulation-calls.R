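#' Thresholds for calling differential expression
#'
#' A probe is considered differentially expressed when its p-value is at or
#' below `p_threshold` and its linear fold change is at least `fc_threshold`
#' in either direction.  The fold-change cutoff is applied on the log2 scale
#' as `|log2fc| >= log2(fc_threshold)`; both bounds are inclusive.
#'
#' @param fc_threshold Linear fold-change cutoff, must be greater than 1.
#'   Default 1.5.
#' @param p_threshold P-value cutoff in (0, 1).  Default 0.05.
#' @return An object of class `call_config`.
#' @export
#' @examples
#' call_config()
#' call_config(fc_threshold = 2)
call_config <- function(fc_threshold = 1.5, p_threshold = 0.05) {
  stopifnot(is.numeric(fc_threshold), length(fc_threshold) == 1,
            is.finite(fc_threshold), fc_threshold > 1,
            is.numeric(p_threshold), length(p_threshold) == 1,
            p_threshold > 0, p_threshold < 1)
  structure(list(fc_threshold = fc_threshold, p_threshold = p_threshold),
            class = "call_config")
}

#' Build a per-comparison differential expression table
#'
#' @param gene_id Character vector of AGI codes (normalized via
#'   [normalize_agi()]; must be unique after normalization).
#' @param log2fc Numeric vector of log2 fold changes (finite).
#' @param p_value Numeric vector of p-values in \[0, 1\].
#' @param comparison A one-row `data.frame` describing the comparison
#'   (a row of [canonical_comparisons()]), or `NULL`.
#' @return A `comparison_table`: a `data.frame` with columns `gene_id`,
#'   `log2fc`, `p_value` and a `comparison` attribute.
#' @export
comparison_table <- function(gene_id, log2fc, p_value, comparison = NULL) {
  gene_id <- normalize_agi(gene_id)
  if (length(gene_id) != length(log2fc) || length(gene_id) != length(p_value))
    stop("gene_id, log2fc and p_value must have equal length")
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id in comparison table: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  bad_fc <- !is.finite(log2fc)
  if (any(bad_fc))
    stop("non-finite log2fc for gene(s): ",
         paste(gene_id[bad_fc], collapse = ", "))
  bad_p <- !is.finite(p_value) | p_value < 0 | p_value > 1
  if (any(bad_p))
    stop("p_value outside [0, 1] for gene(s): ",
         paste(gene_id[bad_p], collapse = ", "))
  out <- data.frame(gene_id = gene_id, log2fc = as.numeric(log2fc),
                    p_value = as.numeric(p_value), stringsAsFactors = FALSE)
  attr(out, "comparison") <- comparison
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Ternary regulation calls for one comparison
#'
#' Converts log2 fold changes and p-values into calls in `{-1, 0, +1}`:
#' `+1` (up) when `p <= p_threshold` and `log2fc >= log2(fc_threshold)`,
#' `-1` (down) when `p <= p_threshold` and `log2fc <= -log2(fc_threshold)`,
#' `0` otherwise.
#'
#' @param table A [comparison_table()].
#' @param config A [call_config()].
#' @return Named integer vector of calls, one per gene.
#' @export
#' @examples
#' tab <- comparison_table(c("AT1G01010", "AT1G01020"),
#'                         log2fc = c(0.60, 0.50), p_value = c(0.01, 0.001))
#' call_regulation(tab)  # 0.60 >= log2(1.5) so the first gene is called up
call_regulation <- function(table, config = call_config()) {
  stopifnot(inherits(table, "comparison_table"), inherits(config, "call_config"))
  lfc_min <- log2(config$fc_threshold)
  sig <- table$p_value <= config$p_threshold
  calls <- integer(nrow(table))
  calls[sig & table$log2fc >= lfc_min] <- 1L
  calls[sig & table$log2fc <= -lfc_min] <- -1L
  names(calls) <- table$gene_id
  calls
}

#' Assemble a ternary regulation matrix from comparison tables
#'
#' Combines per-comparison call vectors into a gene-by-comparison matrix over
#' the union of all gene identifiers (or a supplied universe).  Genes absent
#' from a table -- e.g. not present on that platform -- are recorded as
#' unmeasured (`measured = FALSE`) and carry call 0, so downstream set logic
#' can distinguish "not regulated" from "not measured".
#'
#' @param tables List of [comparison_table()] objects, each carrying a
#'   comparison attribute with a unique `comparison_id`.
#' @param config A [call_config()].
#' @param gene_universe Optional character vector of AGI codes fixing row
#'   order; defaults to the sorted union of all table genes.
#' @return A `regulation_matrix`: list with elements `genes`, `comparisons`
#'   (the manifest `data.frame`), `calls` (integer matrix in `{-1,0,1}`) and
#'   `measured` (logical matrix).
#' @export
assemble_matrix <- function(tables, config = call_config(),
                            gene_universe = NULL) {
  if (length(tables) == 0)
    stop("no comparison tables supplied")
  specs <- lapply(tables, function(t) {
    cmp <- attr(t, "comparison")
    if (is.null(cmp))
      stop("comparison table lacks a comparison attribute")
    cmp
  })
  manifest <- do.call(rbind, specs)
  if (anyDuplicated(manifest$comparison_id))
    stop("duplicate comparison_id: ",
         paste(unique(manifest$comparison_id[
           duplicated(manifest$comparison_id)]), collapse = ", "))
  if (is.null(gene_universe)) {
    gene_universe <- sort(unique(unlist(lapply(tables, `[[`, "gene_id"))))
  } else {
    gene_universe <- normalize_agi(gene_universe)
    if (anyDuplicated(gene_universe))
      stop("duplicate gene_id in gene_universe")
  }
  n <- length(gene_universe)
  k <- length(tables)
  calls <- matrix(0L, n, k,
                  dimnames = list(gene_universe, manifest$comparison_id))
  measured <- matrix(FALSE, n, k,
                     dimnames = list(gene_universe, manifest$comparison_id))
  for (j in seq_len(k)) {
    cj <- call_regulation(tables[[j]], config)
    idx <- match(names(cj), gene_universe)
    keep <- !is.na(idx)
    calls[idx[keep], j] <- cj[keep]
    measured[idx[keep], j] <- TRUE
  }
  new_regulation_matrix(gene_universe, manifest, calls, measured)
}

new_regulation_matrix <- function(genes, comparisons, calls, measured) {
  stopifnot(nrow(calls) == length(genes),
            identical(dim(calls), dim(measured)),
            all(calls %in% c(-1L, 0L, 1L)),
            all(calls[!measured] == 0L))
  structure(list(genes = genes, comparisons = comparisons,
                 calls = calls, measured = measured),
            class = "regulation_matrix")
}

#' @export
print.regulation_matrix <- function(x, ...) {
  cat(sprintf("regulation_matrix: %d genes x %d comparisons (%s)\n",
              length(x$genes), nrow(x$comparisons),
              paste(unique(x$comparisons$tissue), collapse = "+")))
  cat(sprintf("  calls: %d up, %d down, %d zero; %d unmeasured cells\n",
              sum(x$calls == 1L), sum(x$calls == -1L), sum(x$calls == 0L),
              sum(!x$measured)))
  invisible(x)
}

#' Genes regulated in at least one of a set of comparisons
#'
#' @param matrix A `regulation_matrix`.
#' @param comparisons Character vector of comparison ids (default: all).
#' @param direction `"up"`, `"down"` or `"any"`.
#' @return Character vector of gene ids (in matrix row order).
#' @export
regulated_set <- function(matrix, comparisons = NULL,
                          direction = c("any", "up", "down")) {
  stopifnot(inherits(matrix, "regulation_matrix"))
  direction <- match.arg(direction)
  if (is.null(comparisons)) comparisons <- colnames(matrix$calls)
  unknown <- setdiff(comparisons, colnames(matrix$calls))
  if (length(unknown))
    stop("unknown comparison_id: ", paste(unknown, collapse = ", "))
  sub <- matrix$calls[, comparisons, drop = FALSE]
  hit <- switch(direction,
                up   = rowSums(sub == 1L) > 0,
                down = rowSums(sub == -1L) > 0,
                any  = rowSums(sub != 0L) > 0)
  matrix$genes[hit]
}

#' Extract the call vector for one comparison
#'
#' @param matrix A `regulation_matrix`.
#' @param number Comparison number (1-7) per the canonical numbering, or a
#'   comparison id string.
#' @return Named integer vector of calls.
#' @export
matrix_calls <- function(matrix, number) {
  stopifnot(inherits(matrix, "regulation_matrix"))
  if (is.numeric(number)) {
    idx <- match(number, matrix$comparisons$number)
    if (is.na(idx))
      stop("no comparison with number ", number)
    id <- matrix$comparisons$comparison_id[idx]
  } else {
    id <- number
    if (!id %in% colnames(matrix$calls))
      stop("unknown comparison_id: ", id)
  }
  calls <- matrix$calls[, id]
  names(calls) <- matrix$genes
  calls
}

#' Venn partition of named gene sets
#'
#' Tallies the genes in every non-empty membership region of 2--4 named sets,
#' as displayed in a Venn diagram.
#'
#' @param sets Named list of 2 to 4 character vectors.
#' @return Named integer vector over all `2^k - 1` regions; names join the
#'   member set names with `"&"` (e.g. `"A&B"` is "in A and B only").
#' @export
#' @examples
#' venn_partition(list(A = c("a", "b"), B = c("b", "c")))
venn_partition <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be a named list")
  k <- length(sets)
  if (k < 2 || k > 4)
    stop("venn_partition supports 2 to 4 sets, got ", k)
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  # one region per non-empty subset of set names
  region_key <- apply(membership, 1, function(m)
    paste(names(sets)[m], collapse = "&"))
  all_regions <- unlist(lapply(seq_len(k), function(m) {
    combn(names(sets), m, paste, collapse = "&")
  }))
  counts <- table(factor(region_key, levels = all_regions))
  out <- as.integer(counts)
  names(out) <- all_regions
  out
}
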