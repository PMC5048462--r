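#' Planted gene classes for simulated comparisons
#'
#' Each class is defined by the ternary sign pattern it realizes (before
#' noise) in the canonical comparisons of each tissue, mirroring the filter
#' cascade definitions:
#'
#' \describe{
#'   \item{robust_fit_induced}{(c6,c2,c5,c1,c7) = (+1,-1,+1,0,0) in both
#'     tissues -- passes the robust induced cascade and both tissue induced
#'     cascades (from which it is subtracted as robust).}
#'   \item{robust_fit_repressed}{the negated pattern in both tissues.}
#'   \item{seedling_only_induced / root_only_induced}{the induced pattern in
#'     one tissue; in the other tissue only c6 = +1, so the gene stays in
#'     the regulated universe there but fails the cascades.}
#'   \item{seedling_only_repressed / root_only_repressed}{mirror classes.}
#'   \item{fe_regulated_fit_independent}{(+1,-1,+1,+1,+1) in both tissues:
#'     iron-regulated but already elevated without FIT at +Fe and still
#'     induced in the fit mutant, so it survives cascade steps 1-3 and is
#'     cut only by the final "not up" filter -- the designated step-4
#'     distractor.}
#'   \item{unregulated}{all calls 0 everywhere.}
#' }
#'
#' @name synthetic_classes
NULL

synthetic_class_names <- function() {
  c("robust_fit_induced", "robust_fit_repressed",
    "seedling_only_induced", "root_only_induced",
    "seedling_only_repressed", "root_only_repressed",
    "fe_regulated_fit_independent", "unregulated")
}

# c1..c7 sign patterns per class and tissue
class_pattern <- function(class, tissue) {
  zero <- rep(0L, 7)
  induced <- zero;  induced[c(6, 5)] <- 1L;  induced[2] <- -1L
  repressed <- -induced
  weak_up <- zero;  weak_up[6] <- 1L
  distractor <- induced; distractor[c(1, 7)] <- 1L
  switch(class,
    robust_fit_induced = induced,
    robust_fit_repressed = repressed,
    seedling_only_induced = if (tissue == "seedlings") induced else weak_up,
    root_only_induced = if (tissue == "roots") induced else weak_up,
    seedling_only_repressed =
      if (tissue == "seedlings") repressed else -weak_up,
    root_only_repressed = if (tissue == "roots") repressed else -weak_up,
    fe_regulated_fit_independent = distractor,
    unregulated = zero,
    stop("unknown class: ", class))
}

#' Configuration for simulated differential-expression tables
#'
#' Defaults emulate a stringent-threshold two-color microarray screen: a
#' planted effect of 2.0 on the log2 scale (a 4-fold change, comfortably
#' above the 1.5-fold call threshold), log2FC noise of 0.25, and a gene
#' population dominated by unregulated genes with a few percent in each
#' FIT-dependent class.
#'
#' @param n_genes Number of genes.
#' @param class_proportions Named numeric vector over the classes of
#'   [synthetic_classes]; must be nonnegative and sum to 1 (tolerance 1e-9).
#' @param effect_log2fc Magnitude of planted log2 fold changes; must exceed
#'   log2(1.5) so planted calls are recoverable at zero noise.
#' @param noise_sd Standard deviation of Gaussian log2FC noise added to all
#'   cells.
#' @param p_threshold Significance cutoff separating the p-value generators:
#'   planted-signal cells draw p uniformly from (0, p_threshold\], null
#'   cells from (p_threshold, 1\].
#' @param seed Integer seed.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_genes = 1000,
                             class_proportions = c(
                               robust_fit_induced = 0.05,
                               robust_fit_repressed = 0.02,
                               seedling_only_induced = 0.05,
                               root_only_induced = 0.05,
                               seedling_only_repressed = 0.03,
                               root_only_repressed = 0.03,
                               fe_regulated_fit_independent = 0.07,
                               unregulated = 0.70),
                             effect_log2fc = 2.0,
                             noise_sd = 0.25,
                             p_threshold = 0.05,
                             seed = 1L) {
  stopifnot(n_genes >= 1, effect_log2fc > log2(1.5), noise_sd >= 0,
            p_threshold > 0, p_threshold < 1)
  missing <- setdiff(synthetic_class_names(), names(class_proportions))
  if (length(missing))
    stop("class_proportions missing class(es): ",
         paste(missing, collapse = ", "))
  class_proportions <- class_proportions[synthetic_class_names()]
  if (any(class_proportions < 0))
    stop("class proportions must be nonnegative")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class proportions must sum to 1 (got ", sum(class_proportions), ")")
  structure(list(n_genes = as.integer(n_genes),
                 class_proportions = class_proportions,
                 effect_log2fc = effect_log2fc, noise_sd = noise_sd,
                 p_threshold = p_threshold, seed = as.integer(seed)),
            class = "synthetic_config")
}

synthetic_gene_ids <- function(n) sprintf("ATSG%05d", seq_len(n))

#' Simulate the 7 canonical comparison tables per tissue
#'
#' Genes are assigned to classes deterministically by proportion (largest
#' remainder), then each class realizes its defining sign pattern as a
#' log2FC of +/- `effect_log2fc` plus Gaussian noise.  P-values are drawn
#' below the significance cutoff for planted-signal cells and above it for
#' null cells, so downstream threshold logic sees exactly the planted calls
#' at zero noise.  Gene identifiers use the synthetic `ATSG#####` scheme to
#' avoid collision with real Arabidopsis loci.
#'
#' @param config A [synthetic_config()].
#' @return List with `roots` and `seedlings` (each a list of 7
#'   [comparison_table()] objects) and `truth` (named character vector:
#'   class per gene).
#' @export
generate_comparisons <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- synthetic_gene_ids(n)
  counts <- floor(config$class_proportions * n)
  remainder <- n - sum(counts)
  if (remainder > 0) {
    frac <- config$class_proportions * n - counts
    top <- order(-frac)[seq_len(remainder)]
    counts[top] <- counts[top] + 1
  }
  truth <- rep(names(counts), counts)
  names(truth) <- genes

  make_tissue <- function(tissue) {
    spec <- canonical_comparisons(tissue)
    patterns <- vapply(truth, class_pattern, integer(7), tissue = tissue)
    lapply(seq_len(7), function(j) {
      planted <- patterns[j, ]
      lfc <- planted * config$effect_log2fc +
        stats::rnorm(n, sd = config$noise_sd)
      p <- ifelse(planted != 0L,
                  stats::runif(n, 0, config$p_threshold),
                  config$p_threshold +
                    stats::runif(n, 0, 1 - config$p_threshold))
      comparison_table(genes, lfc, p, comparison = spec[j, , drop = FALSE])
    })
  }
  list(roots = make_tissue("roots"), seedlings = make_tissue("seedlings"),
       truth = truth)
}

#' Configuration for simulated multi-study ternary matrices
#'
#' Defaults emulate a compendium of 14 wild-type iron-deficiency analyses of
#' which 2 report only induced genes, with truly regulated genes reported in
#' their true direction by 80% of eligible studies and a 2% spurious call
#' rate -- roughly the reporting variability seen across published
#' iron-deficiency transcriptome screens.
#'
#' @param n_genes Number of genes.
#' @param n_studies Number of studies (columns).
#' @param n_induced_only Number of studies reporting only up-regulated genes.
#' @param consistency Probability that an eligible study reports a truly
#'   regulated gene in its true direction.
#' @param background_rate Probability that a cell that would otherwise be 0
#'   carries a spurious call (+1, or -1 only in studies that can report
#'   down-regulation).
#' @param prop_up,prop_down Proportions of genes truly up-/down-regulated;
#'   the rest are unregulated.
#' @param seed Integer seed.
#' @return A `study_sim_config` object.
#' @export
study_sim_config <- function(n_genes = 500, n_studies = 14,
                             n_induced_only = 2, consistency = 0.8,
                             background_rate = 0.02,
                             prop_up = 0.10, prop_down = 0.05,
                             seed = 1L) {
  stopifnot(n_genes >= 1, n_studies >= 1,
            n_induced_only >= 0, n_induced_only <= n_studies,
            consistency >= 0, consistency <= 1,
            background_rate >= 0, background_rate <= 1,
            prop_up >= 0, prop_down >= 0, prop_up + prop_down <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 n_studies = as.integer(n_studies),
                 n_induced_only = as.integer(n_induced_only),
                 consistency = consistency,
                 background_rate = background_rate,
                 prop_up = prop_up, prop_down = prop_down,
                 seed = as.integer(seed)),
            class = "study_sim_config")
}

#' Simulate a gene-by-study ternary regulation matrix
#'
#' True-up genes emit +1 with probability `consistency` in every study;
#' true-down genes emit -1 with probability `consistency` in studies that
#' can report down-regulation and are forced to 0 in induced-only studies.
#' Remaining zero cells flip to a spurious call with probability
#' `background_rate`.
#'
#' @param config A [study_sim_config()].
#' @return List with `matrix` (a [study_matrix()]) and `truth` (named
#'   character vector in `{"up", "down", "none"}`).
#' @export
generate_study_matrix <- function(config = study_sim_config()) {
  stopifnot(inherits(config, "study_sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  k <- config$n_studies
  genes <- synthetic_gene_ids(n)
  studies <- study_meta(
    study_id = sprintf("study%02d", seq_len(k)),
    induced_only = seq_len(k) <= config$n_induced_only)
  n_up <- round(config$prop_up * n)
  n_down <- round(config$prop_down * n)
  truth <- rep(c("up", "down", "none"), c(n_up, n_down, n - n_up - n_down))
  names(truth) <- genes

  values <- matrix(0L, n, k, dimnames = list(genes, studies$study_id))
  eligible_down <- !studies$induced_only
  for (j in seq_len(k)) {
    up_hit <- truth == "up" & stats::runif(n) < config$consistency
    values[up_hit, j] <- 1L
    if (eligible_down[j]) {
      down_hit <- truth == "down" & stats::runif(n) < config$consistency
      values[down_hit, j] <- -1L
    }
    zero <- values[, j] == 0L
    spurious <- zero & stats::runif(n) < config$background_rate
    if (eligible_down[j]) {
      values[spurious, j] <- sample(c(-1L, 1L), sum(spurious), replace = TRUE)
    } else {
      values[spurious, j] <- 1L
    }
  }
  list(matrix = study_matrix(values, studies), truth = truth)
}
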