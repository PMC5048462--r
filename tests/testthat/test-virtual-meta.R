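test_that("compute_virt reproduces the defining arithmetic", {
  st14 <- sim_studies(14, n_io = 2)
  cfg <- virt_config(n_total_up = 14, n_total_down = 12)

  r <- compute_virt(rep(1L, 14), st14, cfg, "GU")
  expect_identical(c(r$abs_occ, r$sum_reg), c(14L, 14L))
  expect_identical(r$rat, 1)
  expect_identical(r$virt, 1)        # unanimity: VIRT exactly 1
  expect_true(r$passes && r$direction == "up")

  r <- compute_virt(c(rep(1L, 13), 0L), st14, cfg)
  expect_equal(r$virt, 13 / 14)      # 0.93 after rounding
  expect_identical(round_virt(r$virt), 0.93)

  # ten down-calls, two zeros among the 12 down-eligible studies
  calls <- rep(0L, 14)
  calls[c(3:8, 10:13)] <- -1L
  r <- compute_virt(calls, st14, cfg)
  expect_identical(c(r$abs_occ, r$sum_reg), c(10L, -10L))
  expect_equal(r$virt, -10 / 12)
  expect_identical(round_virt(r$virt), -0.83)
  expect_identical(r$direction, "down")

  # 7 up, 3 down, 4 zero -> RAT 0.4 below threshold
  calls <- c(rep(1L, 7), rep(0L, 4), rep(-1L, 3))
  r <- compute_virt(calls, sim_studies(14), cfg)
  expect_identical(c(r$abs_occ, r$sum_reg), c(10L, 4L))
  expect_equal(r$rat, 0.4)
  expect_false(r$passes)
  expect_identical(r$direction, "none")
})

test_that("ABS = 0 yields a non-passing record, not an error", {
  r <- compute_virt(rep(0L, 5), sim_studies(5), gene_id = "G0")
  expect_false(r$passes)
  expect_identical(r$virt, 0)
  expect_true(is.na(r$rat))
  expect_identical(r$direction, "none")
})

test_that("compute_virt validates its inputs", {
  st <- sim_studies(3, n_io = 1)
  expect_error(compute_virt(c(2L, 0L, 0L), st), "-1, 0 or 1")
  expect_error(compute_virt(c(-1L, 0L, 0L), st), "induced-only")
  expect_error(compute_virt(c(0L, 0L), st), "lengths differ")
})

test_that("a single study can never produce a passing gene", {
  m <- study_matrix(matrix(c(1L, -1L, 0L), 3, 1,
                           dimnames = list(c("G1", "G2", "G3"), "s01")),
                    sim_studies(1))
  vd <- build_virtual_dataset(m)
  expect_identical(nrow(vd$ranked), 0L)
})

test_that("build_virtual_dataset matches an independent per-gene oracle", {
  set.seed(17)
  m <- random_study_matrix(200)
  cfg <- virt_config()
  vd <- build_virtual_dataset(m, cfg)
  n_up <- 14; n_down <- 12
  for (i in seq_along(m$genes)) {
    calls <- m$values[i, ]
    a <- sum(calls != 0); s <- sum(calls)
    rec <- vd$records[vd$records$gene_id == m$genes[i], ]
    expect_identical(rec$abs_occ, as.integer(a))
    expect_identical(rec$sum_reg, as.integer(s))
    if (a > 0) {
      rat <- abs(s) / a
      virt <- if (s == 0) 0 else (s / if (s > 0) n_up else n_down) * rat
      expect_equal(rec$virt, virt)
      expect_identical(rec$passes,
                       abs(s) >= 2 && rat >= 0.5 && abs(virt) >= 0.25)
    } else {
      expect_false(rec$passes)
    }
  }
  expect_setequal(vd$ranked$gene_id,
                  vd$records$gene_id[vd$records$passes])
})

test_that("VIRT invariants hold on random matrices", {
  set.seed(19)
  m <- random_study_matrix(150)
  recs <- build_virtual_dataset(m)$records
  expect_true(all(abs(recs$virt) <= 1 + 1e-12))
  expect_true(all(sign(recs$virt) == sign(recs$sum_reg)))
  expect_true(all(recs$abs_occ <= nrow(m$studies)))
  expect_true(all(abs(recs$sum_reg) <= recs$abs_occ))
  ok <- !is.na(recs$rat)
  expect_true(all(recs$rat[ok] >= 0 & recs$rat[ok] <= 1))
})

test_that("contradiction penalty: |VIRT| strictly decreases with minority calls", {
  st <- sim_studies(14)
  abs_occ <- 10
  virts <- sapply(0:4, function(minority) {
    calls <- c(rep(1L, abs_occ - minority), rep(-1L, minority),
               rep(0L, 14 - abs_occ))
    abs(compute_virt(calls, st)$virt)
  })
  expect_true(all(diff(virts) < 0))
})

test_that("agreement monotonicity: converting a 0 to the majority direction", {
  set.seed(23)
  st <- sim_studies(14)
  cfg <- virt_config(n_total_up = 14, n_total_down = 14)
  for (i in 1:50) {
    calls <- sample(c(-1L, 0L, 1L), 14, replace = TRUE)
    s <- sum(calls)
    if (s == 0 || !any(calls == 0L)) next
    before <- abs(compute_virt(calls, st, cfg)$virt)
    calls[which(calls == 0L)[1]] <- sign(s)
    after <- abs(compute_virt(calls, st, cfg)$virt)
    expect_gte(after, before)
  }
})

test_that("induced-only flags change VIRT only for down-direction genes", {
  k <- 10
  up_calls <- c(rep(1L, 7), rep(0L, 3))
  down_calls <- c(rep(0L, 3), rep(-1L, 7))
  plain <- sim_studies(k)
  flagged <- sim_studies(k, n_io = 2)   # studies s01, s02 induced-only
  expect_identical(compute_virt(up_calls, plain)$virt,
                   compute_virt(up_calls, flagged)$virt)
  expect_lt(compute_virt(down_calls, flagged)$virt,
            compute_virt(down_calls, plain)$virt)  # smaller denominator
})

test_that("rank_markers orders by the documented deterministic key", {
  set.seed(27)
  m <- random_study_matrix(100)
  vd <- build_virtual_dataset(m)
  for (dir in c("up", "down")) {
    got <- rank_markers(vd, dir, k = 1000)
    pool <- vd$records[vd$records$passes & vd$records$direction == dir, ]
    want <- pool[order(-abs(pool$virt), -pool$abs_occ, pool$gene_id), ]
    expect_identical(got$gene_id, want$gene_id)
    expect_identical(rank_markers(vd, dir, k = 3)$gene_id,
                     utils::head(want$gene_id, 3))
  }
  expect_error(rank_markers(vd, "up", k = 0), "positive")
})

test_that("summarize_dataset reports counts, mean |VIRT| and coverage", {
  recs <- data.frame(gene_id = c("G1", "G2", "G3"),
                     abs_occ = c(5L, 5L, 1L), sum_reg = c(5L, -4L, 1L),
                     rat = c(1, 0.8, 1), virt = c(0.5, -0.3, 0.1),
                     passes = c(TRUE, TRUE, FALSE),
                     direction = c("up", "down", "none"))
  s <- summarize_dataset(recs, reference = c("G1", "G3"))
  expect_identical(c(s$n_pass, s$n_up, s$n_down), c(2L, 1L, 1L))
  expect_equal(s$mean_abs_virt, 0.4)
  expect_equal(s$coverage, 0.5)
  none <- summarize_dataset(recs[recs$gene_id == "G3", ])
  expect_identical(none$n_pass, 0L)
  expect_true(is.na(none$mean_abs_virt))
  # derived: mean equals brute-force average over a random passing set
  set.seed(33)
  vd <- build_virtual_dataset(random_study_matrix(50))
  s <- summarize_dataset(vd)
  passing <- vd$records[vd$records$passes, ]
  if (nrow(passing))
    expect_equal(s$mean_abs_virt, sum(abs(passing$virt)) / nrow(passing))
})

test_that("round_virt rounds half away from zero", {
  expect_identical(round_virt(c(0.125, -0.125, 0.855, -0.835)),
                   c(0.13, -0.13, 0.86, -0.84))
})

test_that("study_matrix enforces the induced-only and ternary invariants", {
  st <- sim_studies(2, n_io = 1)
  vals <- matrix(c(-1L, 0L, 0L, 1L), 2, 2,
                 dimnames = list(c("G1", "G2"), st$study_id))
  expect_error(study_matrix(vals, st), "induced-only study 's01'.*G1")
  vals2 <- matrix(c(2L, 0L, 0L, 1L), 2, 2,
                  dimnames = list(c("G1", "G2"), st$study_id))
  expect_error(study_matrix(vals2, st), "-1, 0 or 1")
})
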