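# Builders shared across test files.

# Regulation matrix from a genes x 7 matrix of desired calls, built through
# the real table -> call -> assemble path: planted calls become log2fc of
# +/-1 (above the 1.5-fold cutoff) at p = 0.01; zero calls get log2fc 0.
matrix_from_calls <- function(calls, tissue = "roots",
                              genes = sprintf("G%04d", seq_len(nrow(calls)))) {
  spec <- canonical_comparisons(tissue)
  tables <- lapply(seq_len(7), function(j) {
    comparison_table(genes, log2fc = calls[, j], p_value = rep(0.01, nrow(calls)),
                     comparison = spec[j, , drop = FALSE])
  })
  assemble_matrix(tables, gene_universe = genes)
}

# Random ternary call matrix
random_calls <- function(n, k = 7) {
  matrix(sample(c(-1, 0, 1), n * k, replace = TRUE,
                prob = c(0.2, 0.6, 0.2)), n, k)
}

# Random comparison table
random_table <- function(n, spec_row = NULL, sd = 1.5) {
  comparison_table(sprintf("G%04d", seq_len(n)),
                   log2fc = stats::rnorm(n, sd = sd),
                   p_value = stats::runif(n),
                   comparison = spec_row)
}

# Study manifest with the first n_io studies induced-only
sim_studies <- function(k, n_io = 0) {
  study_meta(sprintf("s%02d", seq_len(k)), induced_only = seq_len(k) <= n_io)
}

# Random study matrix honouring the induced-only constraint
random_study_matrix <- function(n, k = 14, n_io = 2) {
  studies <- sim_studies(k, n_io)
  values <- matrix(sample(c(-1L, 0L, 1L), n * k, replace = TRUE,
                          prob = c(0.2, 0.5, 0.3)), n, k,
                   dimnames = list(sprintf("G%04d", seq_len(n)),
                                   studies$study_id))
  values[, seq_len(n_io)][values[, seq_len(n_io)] == -1L] <- 0L
  study_matrix(values, studies)
}
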