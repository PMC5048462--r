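#' Study metadata for a cross-study ternary matrix
#'
#' @param study_id Character vector of unique study tokens.
#' @param label Free-text labels (default: the ids).
#' @param induced_only Logical: does the study report only up-regulated
#'   genes?  Such studies can never contribute a -1 call and are excluded
#'   from the denominator when scoring down-regulated genes.
#' @param tissue `"roots"`, `"seedlings"` or `"mixed"` per study.
#' @return A `data.frame` with one row per study.
#' @export
study_meta <- function(study_id, label = study_id,
                       induced_only = FALSE, tissue = "mixed") {
  study_id <- as.character(study_id)
  if (anyDuplicated(study_id))
    stop("duplicate study_id: ",
         paste(unique(study_id[duplicated(study_id)]), collapse = ", "))
  n <- length(study_id)
  out <- data.frame(study_id = study_id,
                    label = rep_len(as.character(label), n),
                    induced_only = rep_len(as.logical(induced_only), n),
                    tissue = rep_len(as.character(tissue), n),
                    stringsAsFactors = FALSE)
  bad <- !out$tissue %in% c("roots", "seedlings", "mixed")
  if (any(bad))
    stop("tissue must be roots/seedlings/mixed, got: ",
         paste(unique(out$tissue[bad]), collapse = ", "))
  out
}

#' Gene-by-study ternary regulation matrix
#'
#' Each cell records whether a study found the gene up-regulated (+1),
#' down-regulated (-1) or unregulated/below-threshold (0) under iron
#' deficiency in wild type.
#'
#' @param values Integer matrix in `{-1, 0, 1}`, genes as rows (rownames =
#'   AGI codes), studies as columns (colnames = study ids).
#' @param studies A [study_meta()] `data.frame` covering every column.
#' @return A `study_matrix` object.
#' @export
study_matrix <- function(values, studies) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(rownames(values)))
    stop("values must have gene rownames")
  rownames(values) <- normalize_agi(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene rows: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (!all(values %in% c(-1L, 0L, 1L)))
    stop("study matrix cells must be -1, 0 or 1")
  if (is.null(colnames(values)))
    colnames(values) <- studies$study_id
  missing <- setdiff(colnames(values), studies$study_id)
  if (length(missing))
    stop("study manifest does not cover column(s): ",
         paste(missing, collapse = ", "))
  studies <- studies[match(colnames(values), studies$study_id), , drop = FALSE]
  rownames(studies) <- NULL
  for (j in which(studies$induced_only)) {
    bad <- values[, j] == -1L
    if (any(bad))
      stop("induced-only study '", studies$study_id[j],
           "' contains down-calls for gene(s): ",
           paste(rownames(values)[bad], collapse = ", "))
  }
  structure(list(genes = rownames(values), studies = studies, values = values),
            class = "study_matrix")
}

#' @export
print.study_matrix <- function(x, ...) {
  cat(sprintf("study_matrix: %d genes x %d studies (%d induced-only)\n",
              length(x$genes), nrow(x$studies), sum(x$studies$induced_only)))
  invisible(x)
}

#' Thresholds and denominators for the virtual dataset
#'
#' The consistency score of a gene across studies is built from three
#' quantities: ABS (number of studies calling the gene regulated in either
#' direction), SUM (signed sum of its ternary calls) and RAT = |SUM|/ABS
#' (uniformity of direction).  The ranking score is
#' VIRT = (SUM / N) * RAT, where N is the total number of analyses eligible
#' for the gene's direction: all studies for up-regulated genes, studies that
#' can report down-regulation (i.e. not induced-only) for down-regulated
#' genes.  |VIRT| approximates the probability of finding the gene regulated
#' in its majority direction.  A gene is retained when |SUM| >= `sum_min`,
#' RAT >= `rat_min` and |VIRT| >= `virt_min` (all inclusive).
#'
#' @param sum_min Minimum |SUM| (default 2: regulated at least twice more
#'   often in one direction than the other).
#' @param rat_min Minimum RAT in (0, 1\] (default 0.5).
#' @param virt_min Minimum |VIRT| in (0, 1\] (default 0.25).
#' @param n_total_up Denominator for up-regulated genes; `NULL` (default)
#'   derives it as the number of studies in the matrix.
#' @param n_total_down Denominator for down-regulated genes; `NULL` derives
#'   it as the number of non-induced-only studies.
#' @return A `virt_config` object.
#' @export
#' @examples
#' virt_config()                       # denominators derived from the matrix
#' virt_config(n_total_up = 14, n_total_down = 12)
virt_config <- function(sum_min = 2, rat_min = 0.5, virt_min = 0.25,
                        n_total_up = NULL, n_total_down = NULL) {
  stopifnot(sum_min >= 1, rat_min > 0, rat_min <= 1,
            virt_min > 0, virt_min <= 1)
  structure(list(sum_min = sum_min, rat_min = rat_min, virt_min = virt_min,
                 n_total_up = n_total_up, n_total_down = n_total_down),
            class = "virt_config")
}

resolve_denominators <- function(config, studies) {
  n_up <- config$n_total_up
  n_down <- config$n_total_down
  if (is.null(n_up)) n_up <- nrow(studies)
  if (is.null(n_down)) n_down <- sum(!studies$induced_only)
  if (n_down > n_up)
    stop("n_total_down (", n_down, ") exceeds n_total_up (", n_up, ")")
  list(n_up = n_up, n_down = n_down)
}

#' ABS/SUM/RAT/VIRT record for one gene
#'
#' @param calls Integer vector of per-study calls in `{-1, 0, 1}`.
#' @param studies A [study_meta()] `data.frame` parallel to `calls`.
#' @param config A [virt_config()].
#' @param gene_id Gene identifier attached to the record.
#' @return A one-row `data.frame` with columns `gene_id`, `abs_occ`,
#'   `sum_reg`, `rat`, `virt`, `passes`, `direction`.  A gene never called
#'   regulated (ABS = 0) yields `passes = FALSE`, `virt = 0`,
#'   `direction = "none"` and `rat = NA`.
#' @export
#' @examples
#' studies <- study_meta(paste0("s", 1:14))
#' compute_virt(rep(1L, 14), studies)         # unanimously up: VIRT = 1
compute_virt <- function(calls, studies, config = virt_config(),
                         gene_id = NA_character_) {
  calls <- as.integer(calls)
  if (!all(calls %in% c(-1L, 0L, 1L)))
    stop("calls must be -1, 0 or 1")
  if (length(calls) != nrow(studies))
    stop("calls and study manifest lengths differ")
  if (any(calls == -1L & studies$induced_only))
    stop("induced-only study carries a down-call")
  den <- resolve_denominators(config, studies)
  abs_occ <- sum(calls != 0L)
  sum_reg <- sum(calls)
  if (abs_occ == 0L) {
    rat <- NA_real_
    virt <- 0
  } else {
    rat <- abs(sum_reg) / abs_occ
    n <- if (sum_reg > 0) den$n_up else if (sum_reg < 0) den$n_down else NA
    virt <- if (sum_reg == 0L) 0 else (sum_reg / n) * rat
  }
  passes <- abs_occ > 0L && abs(sum_reg) >= config$sum_min &&
    !is.na(rat) && rat >= config$rat_min && abs(virt) >= config$virt_min
  direction <- if (!passes) "none" else if (sum_reg > 0) "up" else "down"
  data.frame(gene_id = gene_id, abs_occ = abs_occ, sum_reg = sum_reg,
             rat = rat, virt = virt, passes = passes, direction = direction,
             stringsAsFactors = FALSE)
}

#' Score and rank every gene of a study matrix
#'
#' Computes the ABS/SUM/RAT/VIRT record for every gene and retains the genes
#' passing all thresholds, ranked most-consistent first within each
#' direction (up genes by VIRT descending, down genes by VIRT ascending,
#' i.e. both by |VIRT| descending).  Ties are broken by ABS descending, then
#' gene id, so the ranking is deterministic.
#'
#' @param matrix A [study_matrix()].
#' @param config A [virt_config()].
#' @return List with `records` (one row per gene, matrix order) and `ranked`
#'   (passing genes only, up block first).
#' @export
build_virtual_dataset <- function(matrix, config = virt_config()) {
  stopifnot(inherits(matrix, "study_matrix"))
  recs <- lapply(seq_along(matrix$genes), function(i)
    compute_virt(matrix$values[i, ], matrix$studies, config,
                 gene_id = matrix$genes[i]))
  records <- do.call(rbind, recs)
  passing <- records[records$passes, , drop = FALSE]
  up <- passing[passing$direction == "up", , drop = FALSE]
  down <- passing[passing$direction == "down", , drop = FALSE]
  ord <- function(d) d[order(-abs(d$virt), -d$abs_occ, d$gene_id), ,
                       drop = FALSE]
  ranked <- rbind(ord(up), ord(down))
  rownames(ranked) <- NULL
  list(records = records, ranked = ranked)
}

#' Summary statistics of a virtual dataset
#'
#' @param records The `records` `data.frame` from [build_virtual_dataset()]
#'   (or the full list, from which `records` is taken).
#' @param reference Optional character vector of reference genes; the summary
#'   then reports which fraction of them passed.
#' @return List with `n_pass`, `n_up`, `n_down`, `mean_abs_virt` (mean |VIRT|
#'   over passing genes; `NA` if none pass) and, when `reference` is given,
#'   `coverage` (fraction of reference genes among the passing set).
#' @export
summarize_dataset <- function(records, reference = NULL) {
  if (is.list(records) && !is.data.frame(records)) records <- records$records
  passing <- records[records$passes, , drop = FALSE]
  out <- list(
    n_pass = nrow(passing),
    n_up = sum(passing$direction == "up"),
    n_down = sum(passing$direction == "down"),
    mean_abs_virt = if (nrow(passing)) mean(abs(passing$virt)) else NA_real_
  )
  if (!is.null(reference)) {
    reference <- normalize_agi(reference)
    out$coverage <- if (length(reference))
      mean(reference %in% passing$gene_id) else NA_real_
  }
  out
}

#' Top-ranked iron-deficiency marker candidates
#'
#' @param records Records from [build_virtual_dataset()] (list or `records`
#'   `data.frame`).
#' @param direction `"up"` or `"down"`.
#' @param k Number of candidates (positive); if fewer genes pass, the whole
#'   passing set for that direction is returned.
#' @return `data.frame` of the top-k passing records, ordered by |VIRT|
#'   descending, ABS descending, gene id ascending.
#' @export
rank_markers <- function(records, direction = c("up", "down"), k = 5) {
  direction <- match.arg(direction)
  if (!is.numeric(k) || length(k) != 1 || k <= 0)
    stop("k must be a positive number")
  if (is.list(records) && !is.data.frame(records)) records <- records$records
  pool <- records[records$passes & records$direction == direction, ,
                  drop = FALSE]
  pool <- pool[order(-abs(pool$virt), -pool$abs_occ, pool$gene_id), ,
               drop = FALSE]
  out <- utils::head(pool, k)
  rownames(out) <- NULL
  out
}

#' Round as printed in marker tables
#'
#' Half-away-from-zero rounding to 2 decimals, matching how VIRT values are
#' conventionally reported; internal computation always keeps full precision.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_virt <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
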