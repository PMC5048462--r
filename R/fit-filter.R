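#' Four-step sign-pattern cascades for FIT dependence
#'
#' A gene is classified as FIT-dependent by a conjunction of call requirements
#' over specific comparisons (canonical numbering, see
#' [canonical_comparisons()]):
#'
#' \describe{
#'   \item{robust induced}{up in 6 (WT -Fe vs +Fe), down in 2 (fit -Fe vs
#'     WT -Fe), up in 5 (HA-FIT -Fe vs +Fe), not up in 1 (fit +Fe vs WT +Fe)
#'     -- required in roots AND seedlings.}
#'   \item{robust repressed}{the mirror image: down in 6, up in 2, down in 5,
#'     not down in 1 -- in both tissues.}
#'   \item{tissue induced}{up in 6 and down in 2, then up in 5 and not up in
#'     7 (fit -Fe vs fit +Fe) -- in a single tissue; genes already in the
#'     robust set are subtracted.}
#'   \item{tissue repressed}{mirror of tissue induced.}
#' }
#'
#' "Not up" means call != +1, i.e. down-regulated or below threshold; the
#' robust cascade conditions on comparison 1 in its last step while the
#' tissue cascade conditions on comparison 7, and the two are deliberately
#' kept distinct.
#'
#' @name fit_cascades
NULL

cascade_steps <- function(mode) {
  # (comparison number, required call) per step; sign = +1 induced, -1 repressed
  switch(mode,
    robust_induced = list(
      list(number = 6, req = "up",       label = "up in WT -Fe vs +Fe"),
      list(number = 2, req = "down",     label = "down in fit -Fe vs WT -Fe"),
      list(number = 5, req = "up",       label = "up in HA-FIT -Fe vs +Fe"),
      list(number = 1, req = "not_up",   label = "not up in fit +Fe vs WT +Fe")),
    robust_repressed = list(
      list(number = 6, req = "down",     label = "down in WT -Fe vs +Fe"),
      list(number = 2, req = "up",       label = "up in fit -Fe vs WT -Fe"),
      list(number = 5, req = "down",     label = "down in HA-FIT -Fe vs +Fe"),
      list(number = 1, req = "not_down", label = "not down in fit +Fe vs WT +Fe")),
    tissue_induced = list(
      list(number = 6, req = "up",       label = "up in WT -Fe vs +Fe"),
      list(number = 2, req = "down",     label = "down in fit -Fe vs WT -Fe"),
      list(number = 5, req = "up",       label = "up in HA-FIT -Fe vs +Fe"),
      list(number = 7, req = "not_up",   label = "not up in fit -Fe vs fit +Fe")),
    tissue_repressed = list(
      list(number = 6, req = "down",     label = "down in WT -Fe vs +Fe"),
      list(number = 2, req = "up",       label = "up in fit -Fe vs WT -Fe"),
      list(number = 5, req = "down",     label = "down in HA-FIT -Fe vs +Fe"),
      list(number = 7, req = "not_down", label = "not down in fit -Fe vs fit +Fe")),
    stop("unknown cascade mode: ", mode))
}

req_satisfied <- function(calls, req) {
  switch(req,
    up       = calls == 1L,
    down     = calls == -1L,
    not_up   = calls != 1L,
    not_down = calls != -1L,
    stop("unknown call requirement: ", req))
}

new_cascade_result <- function(mode, tissues, universe, steps, survivors,
                               subtracted = character(0)) {
  final <- setdiff(survivors[[length(survivors)]], subtracted)
  structure(list(mode = mode, tissues = tissues,
                 steps = vapply(steps, `[[`, "", "label"),
                 input_universe = universe,
                 per_step_survivors = survivors,
                 subtracted = subtracted,
                 final_set = final),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("cascade_result '%s' (%s)\n", x$mode,
              paste(x$tissues, collapse = " + ")))
  cat(sprintf("  input universe: %d genes\n", length(x$input_universe)))
  for (i in seq_along(x$steps))
    cat(sprintf("  step %d: %-38s %5d survive\n", i, x$steps[i],
                length(x$per_step_survivors[[i]])))
  if (length(x$subtracted))
    cat(sprintf("  subtracted (already robust): %d\n", length(x$subtracted)))
  cat(sprintf("  final set: %d genes\n", length(x$final_set)))
  invisible(x)
}

run_cascade_two_tissue <- function(roots, seedlings, universe, mode) {
  stopifnot(inherits(roots, "regulation_matrix"),
            inherits(seedlings, "regulation_matrix"))
  if (!setequal(roots$comparisons$number, seedlings$comparisons$number))
    stop("roots and seedlings matrices have mismatched comparison manifests")
  if (is.null(universe))
    universe <- intersect(regulated_set(roots), regulated_set(seedlings))
  universe <- intersect(universe, intersect(roots$genes, seedlings$genes))
  steps <- cascade_steps(mode)
  survivors <- vector("list", length(steps))
  current <- universe
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    cr <- matrix_calls(roots, st$number)
    cs <- matrix_calls(seedlings, st$number)
    ok <- req_satisfied(cr[current], st$req) &
          req_satisfied(cs[current], st$req)
    current <- current[ok]
    survivors[[i]] <- current
  }
  new_cascade_result(mode, c("roots", "seedlings"), universe, steps, survivors)
}

run_cascade_one_tissue <- function(matrix, universe, robust_set, mode) {
  stopifnot(inherits(matrix, "regulation_matrix"))
  if (is.null(universe))
    universe <- regulated_set(matrix)
  universe <- intersect(universe, matrix$genes)
  extra <- setdiff(robust_set, matrix$genes)
  if (length(extra))
    warning("robust_set contains ", length(extra),
            " gene(s) absent from the matrix; proceeding")
  steps <- cascade_steps(mode)
  survivors <- vector("list", length(steps))
  current <- universe
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    calls <- matrix_calls(matrix, st$number)
    current <- current[req_satisfied(calls[current], st$req)]
    survivors[[i]] <- current
  }
  subtracted <- intersect(survivors[[length(survivors)]], robust_set)
  new_cascade_result(mode, unique(matrix$comparisons$tissue), universe,
                     steps, survivors, subtracted)
}

#' Robustly FIT-induced genes (both tissues)
#'
#' Applies the four-step induced cascade requiring each condition in roots
#' and seedlings simultaneously: call(6) = +1, call(2) = -1, call(5) = +1
#' and call(1) != +1 in both tissues.
#'
#' @param roots,seedlings `regulation_matrix` objects for the two tissues
#'   with the canonical 7-comparison manifests.
#' @param universe Input gene universe; defaults to the genes regulated in at
#'   least one comparison in roots AND in at least one comparison in
#'   seedlings.
#' @return A `cascade_result` with nested per-step survivor sets.
#' @export
filter_robust_induced <- function(roots, seedlings, universe = NULL) {
  run_cascade_two_tissue(roots, seedlings, universe, "robust_induced")
}

#' Robustly FIT-repressed genes (both tissues)
#'
#' Mirror image of [filter_robust_induced()]: call(6) = -1, call(2) = +1,
#' call(5) = -1 and call(1) != -1 in both tissues.
#'
#' @inheritParams filter_robust_induced
#' @return A `cascade_result`.
#' @export
filter_robust_repressed <- function(roots, seedlings, universe = NULL) {
  run_cascade_two_tissue(roots, seedlings, universe, "robust_repressed")
}

#' Tissue-specific FIT-induced genes
#'
#' Single-tissue cascade: call(6) = +1 and call(2) = -1, then call(5) = +1
#' and call(7) != +1.  Genes already in the robust set are subtracted so the
#' final set is exclusively tissue-specific.
#'
#' @param matrix `regulation_matrix` for one tissue.
#' @param universe Input gene universe; defaults to genes regulated in at
#'   least one comparison in this tissue.
#' @param robust_set Character vector of robustly FIT-regulated genes to
#'   subtract (the final set of the corresponding robust cascade).
#' @return A `cascade_result`; `subtracted` holds the removed robust genes.
#' @export
filter_tissue_induced <- function(matrix, universe = NULL,
                                  robust_set = character(0)) {
  run_cascade_one_tissue(matrix, universe, robust_set, "tissue_induced")
}

#' Tissue-specific FIT-repressed genes
#'
#' Mirror of [filter_tissue_induced()] with all call requirements negated.
#'
#' @inheritParams filter_tissue_induced
#' @return A `cascade_result`.
#' @export
filter_tissue_repressed <- function(matrix, universe = NULL,
                                    robust_set = character(0)) {
  run_cascade_one_tissue(matrix, universe, robust_set, "tissue_repressed")
}

#' Tabular summary of a cascade run
#'
#' @param result A `cascade_result`.
#' @return List with `summary` (a `data.frame` of per-step survivor counts and
#'   attrition) and `genes` (a `data.frame` with the final call per gene:
#'   the step at which each gene dropped out, `"subtracted"` for robust genes
#'   removed from a tissue cascade, or `"final"`).
#' @export
cascade_report <- function(result) {
  stopifnot(inherits(result, "cascade_result"))
  counts <- c(length(result$input_universe),
              lengths(result$per_step_survivors))
  summary <- data.frame(
    step = c("input", paste0("step", seq_along(result$steps))),
    description = c("input universe", result$steps),
    survivors = counts,
    attrition = c(NA_integer_, -diff(counts)),
    stringsAsFactors = FALSE
  )
  status <- rep("final", length(result$input_universe))
  names(status) <- result$input_universe
  previous <- result$input_universe
  for (i in seq_along(result$per_step_survivors)) {
    dropped <- setdiff(previous, result$per_step_survivors[[i]])
    status[dropped] <- paste0("dropped_step", i)
    previous <- result$per_step_survivors[[i]]
  }
  status[result$subtracted] <- "subtracted"
  genes <- data.frame(gene_id = names(status), status = unname(status),
                      stringsAsFactors = FALSE)
  list(summary = summary, genes = genes)
}
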