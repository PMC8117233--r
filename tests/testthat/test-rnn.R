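tiny_cfg <- function(...) {
  rnn_config(hidden_units = 4, categorical_dense_units = 3, batch_size = 4,
             subsequence_len_in = 40, downsample = 4, iterations = 5, ...)
}

rand_batch <- function(B, Tn, seed = 1) {
  set.seed(seed)
  structure(list(x = array(rnorm(B * 4 * Tn), c(B, 4, Tn)),
                 categorical = matrix(sample(0:1, B * 2, TRUE), B, 2),
                 pointwise = matrix(sample(0:1, B * Tn, TRUE), B, Tn),
                 shape = sample(0:3, B, TRUE)),
            class = "training_batch")
}

test_that("configuration invariants are enforced", {
  expect_error(rnn_config(alpha = 0.5, beta = 0.4), "alpha \\+ beta")
  expect_error(rnn_config(subsequence_len_in = 999), "multiple")
  expect_error(rnn_config(gru_layers = 2), "exactly 3")
  cfg <- rnn_config()
  expect_equal(cfg$subsequence_len_train, 250L)
  expect_equal(cfg$alpha, 0.75)
  expect_equal(cfg$beta, 0.25)
})

test_that("batch sampling windows, decimates and labels correctly", {
  set.seed(6)
  recs <- list(quick_record(scotoma_spec("central"), seed = 1, duration = 5,
                            pursuit = "saccadic"))
  cfg <- rnn_config(batch_size = 3, rng_seed = 8)
  set.seed(8)
  b <- sample_batch(recs, cfg)
  expect_equal(dim(b$x), c(3, 4, 250))
  expect_equal(dim(b$pointwise), c(3, 250))
  expect_equal(b$shape, rep(1L, 3))            # central = class 1 (0-based)
  expect_equal(b$categorical[, 1], rep(1, 3))  # high contrast
  expect_equal(b$categorical[, 2], rep(1, 3))  # saccadic
  set.seed(8)
  b2 <- sample_batch(recs, cfg)
  expect_identical(b$x, b2$x)
  # labels are the decimated occlusion flags of the same window
  expect_true(all(b$pointwise %in% 0:1))
  short <- list(new_record(rnorm(100), rnorm(100), rnorm(100), rnorm(100)))
  expect_error(suppressWarnings(sample_batch(short, cfg)), "no usable")
})

test_that("both heads emit proper distributions; zero weights give uniforms", {
  cfg <- tiny_cfg(rng_seed = 3)
  model <- rnn_init(cfg)
  b <- rand_batch(4, 10)
  out <- rnn_forward(model, b)
  expect_equal(apply(out$pointwise_probs, c(1, 3), sum),
               matrix(1, 4, 10), tolerance = 1e-9)
  expect_equal(rowSums(out$shape_probs), rep(1, 4), tolerance = 1e-9)
  expect_true(all(out$shape_probs >= 0))

  zero <- model
  zero$params <- lapply(zero$params, function(p) p * 0)
  out0 <- rnn_forward(zero, b)
  expect_equal(out0$shape_probs, matrix(0.25, 4, 4), tolerance = 1e-12)
  expect_equal(as.numeric(out0$pointwise_probs),
               rep(0.5, 4 * 2 * 10), tolerance = 1e-12)
})

test_that("permuting the batch permutes predictions identically", {
  model <- rnn_init(tiny_cfg(rng_seed = 5))
  b <- rand_batch(4, 10, seed = 2)
  out <- rnn_forward(model, b)
  perm <- c(3, 1, 4, 2)
  bp <- b
  bp$x <- b$x[perm, , , drop = FALSE]
  bp$categorical <- b$categorical[perm, , drop = FALSE]
  bp$pointwise <- b$pointwise[perm, , drop = FALSE]
  bp$shape <- b$shape[perm]
  outp <- rnn_forward(model, bp)
  expect_equal(outp$shape_probs, out$shape_probs[perm, ], tolerance = 1e-12)
  expect_equal(outp$pointwise_probs, out$pointwise_probs[perm, , ],
               tolerance = 1e-12)
})

test_that("loss matches closed forms and weighting contract", {
  model <- rnn_init(tiny_cfg(rng_seed = 7))
  zero <- model
  zero$params <- lapply(zero$params, function(p) p * 0)
  b <- rand_batch(4, 10, seed = 3)
  res <- rnn_loss(zero, b)
  expect_equal(res$loss, 0.75 * log(2) + 0.25 * log(4), tolerance = 1e-12)
  expect_equal(res$loss_pointwise, log(2), tolerance = 1e-12)
  expect_equal(res$loss_shape, log(4), tolerance = 1e-12)
  # J is the alpha/beta weighted combination
  expect_equal(res$loss, 0.75 * res$loss_pointwise + 0.25 * res$loss_shape)

  # beta = 0 leaves the shape head without gradient
  cfg0 <- rnn_config(hidden_units = 4, categorical_dense_units = 3,
                     batch_size = 4, subsequence_len_in = 40,
                     alpha = 1, beta = 0, rng_seed = 7)
  m0 <- rnn_init(cfg0)
  g <- rnn_loss(m0, b, want_grad = TRUE)$grads
  expect_equal(g$Wd, matrix(0, nrow(m0$params$Wd), 4))
  expect_gt(max(abs(g$Wp)), 0)  # the point-wise head still learns
})

test_that("analytic gradients match central finite differences", {
  set.seed(9)
  model <- rnn_init(tiny_cfg(rng_seed = 11))
  b <- rand_batch(2, 5, seed = 4)
  res <- rnn_loss(model, b, want_grad = TRUE)
  h <- 1e-5
  for (nm in names(model$params)) {
    idx <- sample(length(model$params[[nm]]),
                  min(4, length(model$params[[nm]])))
    for (i in idx) {
      m2 <- model
      m2$params[[nm]][i] <- m2$params[[nm]][i] + h
      up <- rnn_loss(m2, b)$loss
      m2$params[[nm]][i] <- m2$params[[nm]][i] - 2 * h
      dn <- rnn_loss(m2, b)$loss
      num <- (up - dn) / (2 * h)
      expect_equal(res$grads[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("ensemble shape prediction averages distributions with low-index
           tie-break", {
  # direct check of the averaging rule on synthetic per-trial distributions
  avg <- colMeans(rbind(c(0.6, 0.4, 0, 0), c(0.2, 0.8, 0, 0)))
  expect_equal(avg, c(0.4, 0.6, 0, 0))
  expect_equal(scotoma_kinds()[which.max(avg)], "central")
  tie <- colMeans(rbind(c(0.5, 0.5, 0, 0), c(0.5, 0.5, 0, 0)))
  expect_equal(scotoma_kinds()[which.max(tie)], "none")

  # through the model: K equals the number of trials, order-invariant
  model <- rnn_init(rnn_config(hidden_units = 4, categorical_dense_units = 3,
                               rng_seed = 2))
  recs <- lapply(1:3, function(s) quick_record(seed = s, duration = 5))
  pred <- predict_shape(model, recs)
  expect_equal(pred$K, 3)
  expect_equal(sum(pred$probs), 1, tolerance = 1e-9)
  pred_rev <- predict_shape(model, rev(recs))
  expect_equal(pred$probs, pred_rev$probs, tolerance = 1e-12)
  expect_error(predict_shape(model, list()), "K = 0")
})

test_that("point-wise map reconstruction follows the predicted flags", {
  cfg <- rnn_config(hidden_units = 4, categorical_dense_units = 3,
                    rng_seed = 2)
  model <- rnn_init(cfg)
  rec <- quick_record(scotoma_spec("central"), seed = 13, duration = 10)
  # force the point-wise head to always answer "unobstructed"
  never <- model
  never$params <- lapply(never$params, function(p) p * 0)
  never$params$bp <- matrix(c(50, -50), 1, 2)
  m <- predict_pointwise_map(never, rec)
  expect_true(all(m$values[m$sampled_mask] == 0))
  # ... and always "obstructed": map value 1 wherever sampled
  always <- never
  always$params$bp <- matrix(c(-50, 50), 1, 2)
  m1 <- predict_pointwise_map(always, rec)
  expect_true(all(m1$values[m1$sampled_mask] == 1))
  # windows tile without overlap: 10 s at 240 Hz -> 2 windows of 250 steps
  # (samples whose retinotopic coordinate falls outside the grid are
  # dropped and tallied)
  expect_equal(sum(m$counts) + m$dropped, 2 * 250)
})

test_that("a short training run reduces the loss", {
  set.seed(15)
  recs <- c(lapply(1:2, function(s) quick_record(scotoma_spec("none"),
                                                 seed = s, duration = 5)),
            lapply(1:2, function(s) quick_record(scotoma_spec("peripheral"),
                                                 seed = 10 + s, duration = 5,
                                                 pursuit = "saccadic")))
  cfg <- rnn_config(hidden_units = 6, categorical_dense_units = 4,
                    batch_size = 6, subsequence_len_in = 240,
                    iterations = 60, rng_seed = 21)
  model <- rnn_train(recs, cfg, log_every = 10)
  expect_lt(model$loss_log$loss[nrow(model$loss_log)],
            model$loss_log$loss[1])
  expect_true(all(is.finite(model$loss_log$loss)))
})

test_that("miscalibration harness applies offsets and reports per magnitude", {
  co <- simulate_cohort(1, conditions = c("none", "central"),
                        protocol = protocol_config(repetitions = 1),
                        base_cfg = trial_config(duration = 5), seed = 31)
  model <- rnn_init(rnn_config(hidden_units = 4, categorical_dense_units = 3,
                               rng_seed = 2))
  set.seed(5)
  tab <- miscalibration_robustness(model, co, "p01", magnitudes = c(0, 2))
  expect_equal(tab$magnitude, c(0, 2))
  expect_equal(tab$n_cases, c(2, 2))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
})
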