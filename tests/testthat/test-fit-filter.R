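# Build two-tissue matrices where every gene realizes a chosen pattern on
# comparisons (6, 2, 5, x) and zero elsewhere.
two_tissue_from_patterns <- function(root_pat, seed_pat, numbers) {
  n <- nrow(root_pat)
  to_calls <- function(pat) {
    calls <- matrix(0, n, 7)
    calls[, numbers] <- pat
    calls
  }
  genes <- sprintf("G%04d", seq_len(n))
  list(roots = matrix_from_calls(to_calls(root_pat), "roots", genes),
       seedlings = matrix_from_calls(to_calls(seed_pat), "seedlings", genes),
       genes = genes)
}

test_that("robust induced cascade includes/excludes the defining patterns", {
  # rows: (c6, c2, c5, c1)
  root_pat <- rbind(c(1, -1, 1, 0),   # textbook robust-induced
                    c(1, -1, 1, 1),   # fails step 4 in roots
                    c(1, -1, 1, -1))  # "not up" includes down
  seed_pat <- rbind(c(1, -1, 1, 0),
                    c(1, -1, 1, 0),   # fine in seedlings, root c1=+1 kills it
                    c(1, -1, 1, 0))
  mm <- two_tissue_from_patterns(root_pat, seed_pat, c(6, 2, 5, 1))
  res <- filter_robust_induced(mm$roots, mm$seedlings, universe = mm$genes)
  expect_setequal(res$final_set, mm$genes[c(1, 3)])
  expect_identical(lengths(res$per_step_survivors), c(3L, 3L, 3L, 2L))
})

test_that("exhaustive enumeration: 4 of 6561 joint patterns pass each robust cascade", {
  pats <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), 8)))
  root_pat <- pats[, 1:4]
  seed_pat <- pats[, 5:8]
  mm <- two_tissue_from_patterns(root_pat, seed_pat, c(6, 2, 5, 1))

  ind <- filter_robust_induced(mm$roots, mm$seedlings, universe = mm$genes)
  # independent oracle: direct logical evaluation of the four conditions
  ok <- function(p) p[1] == 1 & p[2] == -1 & p[3] == 1 & p[4] != 1
  oracle_ind <- mm$genes[apply(root_pat, 1, ok) & apply(seed_pat, 1, ok)]
  expect_setequal(ind$final_set, oracle_ind)
  expect_length(ind$final_set, 4L)

  rep <- filter_robust_repressed(mm$roots, mm$seedlings, universe = mm$genes)
  okr <- function(p) p[1] == -1 & p[2] == 1 & p[3] == -1 & p[4] != -1
  oracle_rep <- mm$genes[apply(root_pat, 1, okr) & apply(seed_pat, 1, okr)]
  expect_setequal(rep$final_set, oracle_rep)
  expect_length(rep$final_set, 4L)
})

test_that("exhaustive enumeration: 2 of 81 per-tissue patterns pass each tissue cascade", {
  pats <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), 4)))  # (c6,c2,c5,c7)
  n <- nrow(pats)
  calls <- matrix(0, n, 7)
  calls[, c(6, 2, 5, 7)] <- pats
  genes <- sprintf("G%04d", seq_len(n))
  m <- matrix_from_calls(calls, "seedlings", genes)

  ind <- filter_tissue_induced(m, universe = genes)
  ok <- pats[, 1] == 1 & pats[, 2] == -1 & pats[, 3] == 1 & pats[, 4] != 1
  expect_setequal(ind$final_set, genes[ok])
  expect_length(ind$final_set, 2L)

  rep <- filter_tissue_repressed(m, universe = genes)
  okr <- pats[, 1] == -1 & pats[, 2] == 1 & pats[, 3] == -1 & pats[, 4] != -1
  expect_setequal(rep$final_set, genes[okr])
  expect_length(rep$final_set, 2L)
})

test_that("induced/repressed duality under global sign flip", {
  set.seed(13)
  for (i in 1:5) {
    cr <- random_calls(60)
    cs <- random_calls(60)
    genes <- sprintf("G%04d", 1:60)
    roots <- matrix_from_calls(cr, "roots", genes)
    seedlings <- matrix_from_calls(cs, "seedlings", genes)
    neg_roots <- matrix_from_calls(-cr, "roots", genes)
    neg_seedlings <- matrix_from_calls(-cs, "seedlings", genes)
    expect_setequal(
      filter_robust_induced(roots, seedlings, genes)$final_set,
      filter_robust_repressed(neg_roots, neg_seedlings, genes)$final_set)
    expect_setequal(
      filter_tissue_induced(roots, universe = genes)$final_set,
      filter_tissue_repressed(neg_roots, universe = genes)$final_set)
  }
})

test_that("per-step survivors are nested and match the order-free conjunction", {
  set.seed(29)
  cr <- random_calls(100)
  cs <- random_calls(100)
  genes <- sprintf("G%04d", 1:100)
  roots <- matrix_from_calls(cr, "roots", genes)
  seedlings <- matrix_from_calls(cs, "seedlings", genes)
  res <- filter_robust_induced(roots, seedlings, genes)
  surv <- c(list(res$input_universe), res$per_step_survivors)
  for (i in 2:length(surv))
    expect_true(all(surv[[i]] %in% surv[[i - 1]]))
  # order-free conjunction of the four conditions over both tissues
  cond <- function(m) {
    c6 <- matrix_calls(m, 6); c2 <- matrix_calls(m, 2)
    c5 <- matrix_calls(m, 5); c1 <- matrix_calls(m, 1)
    names(which(c6 == 1 & c2 == -1 & c5 == 1 & c1 != 1))
  }
  expect_setequal(res$final_set,
                  intersect(genes, intersect(cond(roots), cond(seedlings))))
})

test_that("default universe is the cross-tissue regulated intersection", {
  # gene A regulated in both tissues, B only in roots, C nowhere
  cr <- rbind(c(0, 0, 0, 0, 0, 1, 0),
              c(0, 0, 0, 0, 0, 1, 0),
              rep(0, 7))
  cs <- rbind(c(0, 0, 0, 0, 0, 1, 0),
              rep(0, 7),
              rep(0, 7))
  genes <- c("GA", "GB", "GC")
  res <- filter_robust_induced(matrix_from_calls(cr, "roots", genes),
                               matrix_from_calls(cs, "seedlings", genes))
  expect_identical(res$input_universe, "GA")
})

test_that("tissue cascades subtract the robust set and warn on strays", {
  pats <- rbind(c(1, -1, 1, 0),  # passes, robust -> subtracted
                c(1, -1, 1, 0),  # passes, not robust -> final
                c(1, -1, 1, 1))  # cut at step 4
  calls <- matrix(0, 3, 7)
  calls[, c(6, 2, 5, 7)] <- pats
  genes <- c("GR", "GT", "GX")
  m <- matrix_from_calls(calls, "roots", genes)
  res <- filter_tissue_induced(m, universe = genes, robust_set = "GR")
  expect_identical(res$subtracted, "GR")
  expect_identical(res$final_set, "GT")
  expect_length(intersect(res$final_set, "GR"), 0L)
  expect_warning(
    filter_tissue_induced(m, universe = genes, robust_set = "NOPE"),
    "absent from the matrix")
})

test_that("mismatched manifests are rejected", {
  genes <- sprintf("G%04d", 1:3)
  roots <- matrix_from_calls(random_calls(3), "roots", genes)
  seedlings <- matrix_from_calls(random_calls(3), "seedlings", genes)
  seedlings$comparisons$number <- c(1:6, 9L)
  expect_error(filter_robust_induced(roots, seedlings, genes),
               "mismatched comparison manifests")
})

test_that("cascade_report recounts survivors and locates drop-outs", {
  set.seed(31)
  cr <- random_calls(80)
  cs <- random_calls(80)
  genes <- sprintf("G%04d", 1:80)
  res <- filter_robust_induced(matrix_from_calls(cr, "roots", genes),
                               matrix_from_calls(cs, "seedlings", genes),
                               genes)
  rep <- cascade_report(res)
  expect_identical(rep$summary$survivors,
                   c(length(res$input_universe),
                     lengths(res$per_step_survivors)))
  expect_identical(rep$summary$attrition[-1],
                   -diff(rep$summary$survivors))
  final <- rep$genes$gene_id[rep$genes$status == "final"]
  expect_setequal(final, res$final_set)
  # a gene dropped at step k must be in survivors k-1 but not k
  for (k in 1:4) {
    dropped <- rep$genes$gene_id[rep$genes$status == paste0("dropped_step", k)]
    prev <- if (k == 1) res$input_universe else res$per_step_survivors[[k - 1]]
    expect_true(all(dropped %in% prev))
    expect_length(intersect(dropped, res$per_step_survivors[[k]]), 0L)
  }
  # empty universe -> all-zero report
  empty <- filter_robust_induced(matrix_from_calls(cr, "roots", genes),
                                 matrix_from_calls(cs, "seedlings", genes),
                                 character(0))
  expect_true(all(cascade_report(empty)$summary$survivors == 0L))
})
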