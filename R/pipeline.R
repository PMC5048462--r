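#' End-to-end pipeline configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed forwarded to both generators.
#' @param synthetic A [synthetic_config()] for the comparison simulator.
#' @param study_sim A [study_sim_config()] for the study-matrix simulator.
#' @param calls A [call_config()].
#' @param virt A [virt_config()].
#' @param clustering A [cluster_config()].
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            synthetic = synthetic_config(seed = seed),
                            study_sim = study_sim_config(seed = seed),
                            calls = call_config(),
                            virt = virt_config(),
                            clustering = cluster_config(k = 10)) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 synthetic = synthetic, study_sim = study_sim,
                 calls = calls, virt = virt, clustering = clustering),
            class = "pipeline_config")
}

#' Run the full simulate -> call -> filter -> virtual -> cluster pipeline
#'
#' Simulates the 7 canonical comparisons per tissue and a multi-study
#' matrix, converts the tables to ternary regulation matrices, runs the four
#' FIT cascades, scores the study matrix into the virtual dataset, clusters
#' the simulated fold-change profiles around the planted robust genes, and
#' writes every artifact plus a machine-readable run manifest (parameters,
#' seed, package version, per-file MD5 digests) to `out_dir`.  Re-running
#' with the same configuration reproduces every file byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)

  sim <- generate_comparisons(config$synthetic)
  for (tissue in c("roots", "seedlings")) {
    spec <- canonical_comparisons(tissue)
    write_comparison_manifest(spec, out(paste0(tissue, "_manifest.tsv")))
    for (j in seq_len(7))
      write_comparison_table(sim[[tissue]][[j]],
                             out(sprintf("%s_%s.tsv", tissue,
                                         spec$comparison_id[j])))
  }
  utils::write.table(
    data.frame(gene_id = names(sim$truth), class = unname(sim$truth)),
    out("truth_classes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  roots <- assemble_matrix(sim$roots, config$calls)
  seedlings <- assemble_matrix(sim$seedlings, config$calls)
  write_regulation_matrix(roots, out("roots_calls.tsv"),
                          out("roots_measured.tsv"))
  write_regulation_matrix(seedlings, out("seedlings_calls.tsv"),
                          out("seedlings_measured.tsv"))

  robust_ind <- filter_robust_induced(roots, seedlings)
  robust_rep <- filter_robust_repressed(roots, seedlings)
  cascades <- list(
    robust_induced = robust_ind,
    robust_repressed = robust_rep,
    roots_induced = filter_tissue_induced(roots,
                                          robust_set = robust_ind$final_set),
    seedlings_induced = filter_tissue_induced(
      seedlings, robust_set = robust_ind$final_set),
    roots_repressed = filter_tissue_repressed(
      roots, robust_set = robust_rep$final_set),
    seedlings_repressed = filter_tissue_repressed(
      seedlings, robust_set = robust_rep$final_set))
  for (nm in names(cascades)) {
    rep <- cascade_report(cascades[[nm]])
    utils::write.table(rep$genes, out(sprintf("cascade_%s_genes.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cascade_counts <- lapply(cascades, function(r)
    list(input = length(r$input_universe),
         survivors = lengths(r$per_step_survivors),
         final = length(r$final_set)))

  ssim <- generate_study_matrix(config$study_sim)
  write_study_matrix(ssim$matrix, out("study_matrix.tsv"),
                     out("study_manifest.tsv"))
  vd <- build_virtual_dataset(ssim$matrix, config$virt)
  ranked <- vd$ranked
  ranked$virt <- round_virt(ranked$virt)
  ranked$rat <- round(ranked$rat, 3)
  utils::write.table(ranked, out("virtual_ranked.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  vsummary <- summarize_dataset(vd)

  # profile clustering: fold changes of the regulated root genes, anchored
  # on the planted robust-induced genes
  regulated <- regulated_set(roots)
  profiles <- vapply(sim$roots, function(t) {
    v <- t$log2fc
    names(v) <- t$gene_id
    v[regulated]
  }, numeric(length(regulated)))
  colnames(profiles) <- canonical_comparisons("roots")$comparison_id
  clusters <- if (length(regulated) >= 2) {
    cluster_profiles(profiles, config$clustering)
  } else {
    stats::setNames(integer(0), character(0))
  }
  utils::write.table(
    data.frame(gene_id = names(clusters), cluster = unname(clusters)),
    out("cluster_assignment.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  anchors <- names(sim$truth)[sim$truth == "robust_fit_induced"]
  marker_clusters <- if (length(clusters)) {
    suppressWarnings(marker_anchored_clusters(clusters, anchors))
  } else list()

  files <- list.files(config$out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ironvirt")),
    seed = config$seed,
    parameters = list(
      calls = unclass(config$calls), virt = unclass(config$virt),
      synthetic = unclass(config$synthetic),
      study_sim = unclass(config$study_sim),
      clustering = unclass(config$clustering)),
    cascade_counts = cascade_counts,
    virtual_summary = vsummary,
    files = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, out("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(cascades = cascades, virtual = vd, clusters = clusters,
                 marker_clusters = marker_clusters, manifest = manifest))
}
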