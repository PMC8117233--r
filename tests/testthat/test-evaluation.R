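mk_map <- function(values, counts = NULL, grid = field_grid(3, 3)) {
  v <- matrix(values, grid$ny, grid$nx)
  if (is.null(counts)) counts <- matrix(10, grid$ny, grid$nx)
  gazeperim:::.new_field_map(counts, v * counts, 0, grid)
}

test_that("2D Spearman accuracy behaves on canonical cases", {
  g <- field_grid(3, 3)
  set.seed(41)
  v <- runif(g$nx * g$ny)
  a <- mk_map(v, grid = g)
  expect_equal(spearman2d(a, a), 1)
  b <- mk_map(1 - v, grid = g)
  expect_equal(spearman2d(a, b), -1)

  # hand-computed 3-cell case: {0, .5, 1} vs {0, 1, .5} -> rho = 0.5
  counts <- matrix(0, g$ny, g$nx)
  counts[1, 1:3] <- 2
  ma <- gazeperim:::.new_field_map(counts, counts * 0 +
                                     cbind(c(0, 0, 0, 0, 0, 0),
                                           0, 0, 0, 0, 0)[, 1] * 0, 0, g)
  va <- matrix(0, g$ny, g$nx); va[1, 1:3] <- c(0, 0.5, 1)
  vb <- matrix(0, g$ny, g$nx); vb[1, 1:3] <- c(0, 1, 0.5)
  ma <- gazeperim:::.new_field_map(counts, va * counts, 0, g)
  mb <- gazeperim:::.new_field_map(counts, vb * counts, 0, g)
  expect_equal(spearman2d(ma, mb), 0.5)

  # monotone-transform invariance and symmetry
  c1 <- mk_map(v, grid = g)
  c2 <- mk_map(v^3, grid = g)
  expect_equal(spearman2d(c1, c2), 1)
  d <- mk_map(runif(g$nx * g$ny), grid = g)
  expect_equal(spearman2d(c1, d), spearman2d(d, c1))

  # constant-reference fallback: 1 - mean absolute difference; a constant
  # reconstruction against a non-constant reference carries no information
  z <- mk_map(rep(0, g$nx * g$ny), grid = g)
  e <- mk_map(rep(0, g$nx * g$ny), grid = g)
  expect_equal(spearman2d(z, e), 1)
  f <- mk_map(c(rep(0.5, 18), rep(0, 18)), grid = g)
  expect_equal(spearman2d(f, z), 1 - mean(abs(f$values)))
  expect_equal(spearman2d(z, f), 0)

  tiny <- gazeperim:::.new_field_map(matrix(0, g$ny, g$nx),
                                     matrix(0, g$ny, g$nx), 0, g)
  expect_error(spearman2d(tiny, tiny), "insufficient overlap")
})

test_that("fold plans are contiguous partitions matching the canonical 50/5", {
  plan <- make_fold_plan(1:50, 5)
  expect_equal(plan[[1]]$test, 41:50)
  expect_equal(plan[[2]]$test, 31:40)
  expect_equal(plan[[5]]$test, 1:10)
  expect_equal(plan[[1]]$train, 1:40)
  for (k in c(2, 5)) {
    p <- make_fold_plan(sprintf("s%02d", 1:10), k)
    tests <- unlist(lapply(p, `[[`, "test"))
    expect_setequal(tests, sprintf("s%02d", 1:10))
    expect_equal(anyDuplicated(tests), 0)
    for (f in p) expect_length(intersect(f$train, f$test), 0)
  }
  expect_equal(lengths(lapply(make_fold_plan(1:10, 5), `[[`, "test")),
               rep(2L, 5))
  expect_error(make_fold_plan(1:10, 1), "k must be")
})

test_that("error maps count false positives and negatives per cell", {
  g <- field_grid(1, 1)  # 4 cells
  truth <- mk_map(c(1, 1, 0, 0), grid = g)
  recon <- mk_map(c(1, 0, 0, 1), grid = g)
  em <- error_maps(recon, truth)
  expect_equal(em$fpr, 0.5)
  expect_equal(em$fnr, 0.5)
  perfect <- error_maps(truth, truth)
  expect_equal(perfect$fpr, 0)
  expect_equal(perfect$fnr, 0)
  comp <- error_maps(mk_map(c(0, 0, 1, 1), grid = g), truth)
  expect_equal(comp$fpr, 1)
  expect_equal(comp$fnr, 1)
  none <- error_maps(mk_map(c(0, 0, 0, 0), grid = g),
                     mk_map(c(0, 0, 0, 0), grid = g))
  expect_true(is.na(none$fnr))
  # totals equal the mean of the per-cell indicator maps
  set.seed(42)
  t2 <- mk_map(rbinom(4, 1, 0.5), grid = g)
  r2 <- mk_map(runif(4), grid = g)
  em2 <- error_maps(r2, t2)
  common <- r2$sampled_mask & t2$sampled_mask
  expect_equal(em2$fpr * sum(t2$values[common] <= 0.5),
               sum(em2$fp_map[common]))
})

test_that("summaries report IQRs and a rank test between methods", {
  acc <- data.frame(
    method = rep(c("tfce", "rnn"), each = 8),
    condition = rep(rep(c("central", "none"), each = 4), 2),
    accuracy = c(0.2, 0.3, 0.4, 0.5, 0.9, 0.92, 0.94, 0.96,
                 0.2, 0.3, 0.4, 0.5, 0.9, 0.92, 0.94, 0.96))
  rep1 <- summarize_accuracy(acc)
  expect_equal(nrow(rep1$table), 4)
  iqr_c <- rep1$table$iqr[rep1$table$condition == "central"]
  expect_equal(iqr_c[1], iqr_c[2])
  expect_equal(iqr_c[1],
               unname(diff(quantile(c(0.2, 0.3, 0.4, 0.5), c(0.25, 0.75)))))

  # clearly shifted distributions: agreement with an independent
  # permutation test on the rank-sum statistic
  set.seed(43)
  x <- runif(30, 0.1, 0.4)
  y <- runif(30, 0.6, 0.9)
  acc2 <- data.frame(method = rep(c("a", "b"), each = 30),
                     condition = "central", accuracy = c(x, y))
  p_kw <- summarize_accuracy(acc2)$tests[["central"]]
  perm_stat <- function(lab, val) sum(rank(val)[lab == "a"])
  obs <- perm_stat(acc2$method, acc2$accuracy)
  perm <- replicate(999, perm_stat(sample(acc2$method), acc2$accuracy))
  p_perm <- mean(abs(perm - mean(perm)) >= abs(obs - mean(perm)))
  expect_lt(p_kw, 0.01)
  expect_lt(p_perm, 0.01)
})

test_that("lambda optimization breaks ties toward the lower percentile and
           validates its inputs", {
  grand <- c(rep(0.2, 50), 0.9, 0.9, rep(0.1, 48))
  expect_equal((1:100)[which.max(grand)], 51)
  co <- simulate_cohort(2, conditions = c("none", "central"),
                        protocol = protocol_config(repetitions = 1),
                        base_cfg = trial_config(duration = 2), seed = 9)
  expect_error(optimize_lambda(co), "all four defect conditions")
})
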