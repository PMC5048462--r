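#' Default FIT-regulated marker genes
#'
#' The confirmed FIT-regulated markers IRT1 and FRO2 plus four further
#' FIT-associated iron-deficiency markers used to anchor cluster extraction.
#'
#' @return Named character vector of AGI codes.
#' @export
default_markers <- function() {
  c(IRT1  = "AT4G19690", FRO2 = "AT1G01580", AT3G13610 = "AT3G13610",
    AT3G07720 = "AT3G07720", MTPA2 = "AT3G58810", COPT2 = "AT3G46900")
}

#' Clustering configuration for fold-change profiles
#'
#' @param distance `"pearson_correlation"` (1 - r; the default, capturing
#'   co-regulation of profiles regardless of amplitude) or `"euclidean"`.
#' @param linkage `"average"` (default), `"complete"` or `"ward"` (ward.D2).
#' @param k Fixed number of clusters, or `NULL` to cut by height.
#' @param height_frac When `k` is `NULL`: cut the dendrogram at this fraction
#'   of the maximum merge height (default 0.5).
#' @return A `cluster_config` object.
#' @export
cluster_config <- function(distance = c("pearson_correlation", "euclidean"),
                           linkage = c("average", "complete", "ward"),
                           k = NULL, height_frac = 0.5) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (!is.null(k)) stopifnot(is.numeric(k), length(k) == 1, k >= 1)
  stopifnot(height_frac > 0, height_frac <= 1)
  structure(list(distance = distance, linkage = linkage, k = k,
                 height_frac = height_frac),
            class = "cluster_config")
}

#' Hierarchical clustering of log2 fold-change profiles
#'
#' Clusters genes by their fold-change profiles across the canonical
#' comparisons.  Genes are put in canonical (sorted) order before linkage so
#' the partition does not depend on input order; missing values (gene not
#' measured in a comparison) are imputed as 0, consistent with the ternary
#' treatment of unmeasured cells.  Correlation distance for a constant
#' profile is undefined and set to the maximal distance 2, so such genes
#' end up isolated rather than erroring.
#'
#' @param values Numeric gene-by-comparison matrix of log2 fold changes with
#'   gene rownames; `NA` allowed.
#' @param config A [cluster_config()].
#' @return Named integer vector: cluster id per gene.  Cluster ids are
#'   assigned deterministically by `stats::cutree`.
#' @export
cluster_profiles <- function(values, config = cluster_config()) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("values must have gene rownames")
  if (ncol(values) < 2)
    stop("at least 2 comparisons required")
  rownames(values) <- normalize_agi(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene rows")
  if (nrow(values) < 2)
    stop("at least 2 genes required")
  values <- values[order(rownames(values)), , drop = FALSE]
  values[is.na(values)] <- 0
  if (config$distance == "pearson_correlation") {
    sds <- apply(values, 1, stats::sd)
    r <- suppressWarnings(stats::cor(t(values)))
    d <- 1 - r
    d[is.na(d)] <- 2            # constant profile: maximal distance
    d[sds == 0, ] <- 2
    d[, sds == 0] <- 2
    diag(d) <- 0
    dd <- stats::as.dist(d)
  } else {
    dd <- stats::dist(values, method = "euclidean")
  }
  method <- switch(config$linkage, average = "average",
                   complete = "complete", ward = "ward.D2")
  hc <- stats::hclust(dd, method = method)
  if (!is.null(config$k)) {
    k <- min(config$k, nrow(values))
    assignment <- stats::cutree(hc, k = k)
  } else {
    h <- config$height_frac * max(hc$height)
    assignment <- stats::cutree(hc, h = h)
  }
  assignment
}

#' Clusters containing at least one marker gene
#'
#' @param assignment Named integer vector from [cluster_profiles()].
#' @param markers Character vector of marker AGI codes (default
#'   [default_markers()]).  Markers absent from the assignment are reported
#'   via the `missing_markers` attribute, not an error.
#' @return Named list of gene-id vectors, one element per cluster containing
#'   a marker (names are the cluster ids); empty list with a warning when no
#'   marker is present.
#' @export
marker_anchored_clusters <- function(assignment, markers = default_markers()) {
  markers <- normalize_agi(markers)
  present <- intersect(markers, names(assignment))
  absent <- setdiff(markers, names(assignment))
  if (length(present) == 0) {
    warning("no marker gene present in the clustering")
    out <- list()
  } else {
    ids <- sort(unique(assignment[present]))
    out <- lapply(ids, function(i) names(assignment)[assignment == i])
    names(out) <- as.character(ids)
  }
  attr(out, "missing_markers") <- absent
  out
}

#' Cross-dataset membership tally
#'
#' Given marker-anchored gene sets from several datasets (e.g. roots,
#' seedlings and the combined analysis), counts for every gene in how many
#' datasets it co-clusters with a marker.
#'
#' @param collections Named list (length >= 2) whose elements are either a
#'   character vector of genes or a list of cluster gene sets (flattened).
#' @return `data.frame` with columns `gene_id` and `n_datasets`, sorted by
#'   count descending then gene id.
#' @export
cross_membership_tally <- function(collections) {
  if (!is.list(collections) || length(collections) < 2)
    stop("need at least 2 named collections")
  if (is.null(names(collections)) || any(names(collections) == ""))
    stop("collections must be named")
  flat <- lapply(collections, function(x) unique(unlist(x, use.names = FALSE)))
  universe <- sort(unique(unlist(flat)))
  counts <- rowSums(vapply(flat, function(s) universe %in% s,
                           logical(length(universe))))
  out <- data.frame(gene_id = universe, n_datasets = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_datasets, out$gene_id), ]
  rownames(out) <- NULL
  out
}
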