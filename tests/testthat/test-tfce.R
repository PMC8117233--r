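test_that("deviation series is the per-sample Euclidean distance", {
  n <- 100
  rec <- new_record(s_x = rep(0, n), s_y = rep(0, n),
                    p_x = rep(0, n), p_y = rep(0, n))
  expect_equal(deviation_series(rec)$values, rep(0, n))

  px <- rep(0, n); py <- rep(0, n)
  px[10] <- 3; py[10] <- 4
  rec2 <- new_record(rep(0, n), rep(0, n), px, py)
  expect_equal(deviation_series(rec2)$values[10], 5)

  set.seed(3)
  rec3 <- new_record(rnorm(n), rnorm(n), rnorm(n), rnorm(n))
  manual <- sqrt((rec3$p_x - rec3$s_x)^2 + (rec3$p_y - rec3$s_y)^2)
  expect_equal(deviation_series(rec3)$values, manual)
})

test_that("TFCE of a constant series is identically zero", {
  for (v in c(0, 1.7)) {
    D <- list(values = rep(v, 50), dt = 1 / 240, provenance = NULL)
    out <- tfce_transform(D, tfce_params())
    expect_equal(out$values, rep(0, 50))
  }
  expect_error(tfce_transform(list(values = numeric(0), dt = 1 / 240)),
               "empty")
})

test_that("rectangular pulse matches the closed-form integral within 1%", {
  # baseline-0 series with one pulse of height h_p lasting d seconds:
  # in-pulse TFCE -> d^2 * (2/3) * h_p^(3/2) as the height step vanishes
  rate <- 240
  d_sec <- 0.5
  h_p <- 4
  v <- rep(0, 1000)
  v[301:(300 + d_sec * rate)] <- h_p
  out <- tfce_transform(list(values = v, dt = 1 / rate),
                        tfce_params(n_steps = 2500))
  expected <- d_sec^2 * (2 / 3) * h_p^1.5
  inside <- out$values[301:(300 + d_sec * rate)]
  expect_true(all(abs(inside - expected) / expected < 0.01))
  expect_equal(out$values[v == 0], rep(0, sum(v == 0)))
})

test_that("production transform equals the brute-force oracle", {
  set.seed(12)
  for (i in 1:20) {
    v <- abs(rnorm(200, sd = runif(1, 0.5, 3)))
    D <- list(values = v, dt = 1 / 240, provenance = NULL)
    p <- tfce_params(n_steps = 50, extent_unit = "samples")
    out <- tfce_transform(D, p)
    expect_equal(out$values, tfce_oracle(v, E = 2, H = 0.5, n_steps = 50,
                                         unit = 1),
                 tolerance = 1e-9)
    # seconds vs samples is a pure global rescaling by dt^E
    out_s <- tfce_transform(D, tfce_params(n_steps = 50))
    expect_equal(out_s$values, out$values * (1 / 240)^2, tolerance = 1e-12)
  }
})

test_that("TFCE is pointwise monotone in D and reversal invariant", {
  set.seed(21)
  for (i in 1:10) {
    v <- abs(rnorm(150))
    p <- tfce_params(n_steps = 60)
    base <- tfce_transform(list(values = v, dt = 1 / 240), p)$values
    # bump interior samples, keeping the series min and max (hence the
    # height levels) fixed: monotonicity then holds exactly, not only in
    # the continuum limit
    v2 <- v
    idx <- sample(setdiff(seq_along(v), c(which.max(v), which.min(v))), 10)
    v2[idx] <- pmin(v2[idx] + runif(10, 0, 1), max(v))
    bumped <- tfce_transform(list(values = v2, dt = 1 / 240), p)$values
    expect_true(all(bumped >= base - 1e-12))
    revd <- tfce_transform(list(values = rev(v), dt = 1 / 240), p)$values
    expect_equal(revd, rev(base), tolerance = 1e-12)
  }
})

test_that("scaling D by c > 0 scales TFCE by c^(H+1) when the minimum is 0", {
  set.seed(5)
  v <- c(0, abs(rnorm(99)))
  p <- tfce_params(n_steps = 80, extent_unit = "samples")
  base <- tfce_transform(list(values = v, dt = 1), p)$values
  for (cc in c(0.5, 2, 7)) {
    scaled <- tfce_transform(list(values = cc * v, dt = 1), p)$values
    expect_equal(scaled, cc^1.5 * base, tolerance = 1e-9)
  }
})

test_that("normative distribution pools trials and rejects contamination", {
  a <- mk_tfce_series(1:10, pid = "pa")
  b <- mk_tfce_series(11:20, pid = "pb")
  norms <- build_normative_distribution(list(a, b))
  expect_length(norms$values, 20)
  expect_setequal(norms$source_ids, c("pa", "pb"))
  one <- build_normative_distribution(list(a))
  expect_equal(one$values, sort(a$values))
  bad <- mk_tfce_series(1:5, kind = "central")
  expect_error(build_normative_distribution(list(a, bad)), "contamination")
  expect_error(build_normative_distribution(list()), "no trials")
  # pooled percentile equals direct sorting of the mixture
  set.seed(8)
  mix <- list(mk_tfce_series(rexp(40)), mk_tfce_series(rexp(60, 0.2)))
  norms2 <- build_normative_distribution(mix)
  expect_equal(normative_threshold(norms2, 73),
               unname(quantile(sort(c(mix[[1]]$values, mix[[2]]$values)),
                               0.73, type = 7)))
})

test_that("binarize applies the strict-exceedance percentile rule", {
  F <- build_normative_distribution(list(mk_tfce_series(1:100)))
  s <- mk_tfce_series(c(50, 95))
  b <- binarize(s, F, 90)
  expect_identical(b$flags, c(0L, 1L))
  expect_equal(b$threshold_value,
               unname(quantile(1:100, 0.9, type = 7)))
  # values equal to the threshold stay healthy (<= rule)
  s_eq <- mk_tfce_series(rep(b$threshold_value, 5))
  expect_identical(binarize(s_eq, F, 90)$flags, rep(0L, 5))
  # lambda = 100: nothing drawn from F itself exceeds the maximum
  s_from_F <- mk_tfce_series(sample(1:100, 30, replace = TRUE))
  expect_identical(binarize(s_from_F, F, 100)$flags, rep(0L, 30))
  expect_error(binarize(s, F, 0.5), "lambda_n")
})

test_that("flagged fraction is nonincreasing in lambda", {
  set.seed(14)
  F <- build_normative_distribution(list(mk_tfce_series(rexp(500))))
  s <- mk_tfce_series(rexp(300, 0.5))
  fr <- vapply(1:100, function(l) mean(binarize(s, F, l)$flags), numeric(1))
  expect_true(all(diff(fr) <= 0))
})
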