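#' Recurrent network configuration
#'
#' Architecture and training settings of the two-stream network: three
#' stacked bidirectional GRU layers over the `(p_x, p_y, s_x, s_y)`
#' sequence, a dense tanh transform of the two categorical flags, a
#' per-step point-wise softmax head (obstructed vs. unobstructed) and a
#' mean-pooled 4-class defect-shape head.  The loss is
#' `alpha * pointwise cross-entropy + beta * shape cross-entropy` with
#' `alpha = 0.75`, `beta = 0.25`, optimized with RMSprop mini-batch
#' gradient descent.  Training subsequences are 1000 samples at 240 Hz
#' (4.17 s) decimated by 4 to 250 steps at 60 Hz.
#'
#' @param gru_layers Number of bidirectional GRU layers (fixed architecture
#'   default 3).
#' @param hidden_units Hidden units per direction (default 32).
#' @param categorical_dense_units Units of the categorical stream
#'   (default 16).
#' @param alpha,beta Loss weights (defaults 0.75 and 0.25; must sum to 1).
#' @param batch_size Mini-batch size (paper-scale 128).
#' @param iterations Optimization steps (desk-scale default 2000;
#'   paper-scale 15000).
#' @param subsequence_len_in Input window length in samples at the
#'   acquisition rate (default 1000).
#' @param downsample Decimation factor (default 4, i.e. 240 Hz to 60 Hz).
#' @param learning_rate RMSprop learning rate (default 1e-3).
#' @param rmsprop_decay RMSprop smoothing constant (default 0.9).
#' @param input_scale Multiplier applied to position inputs before the
#'   network (default 0.05, mapping the +-24 degree field roughly into
#'   +-1.2).
#' @param rng_seed Optional integer seed for init and batch sampling.
#' @return An object of class `rnn_config`.
#' @export
rnn_config <- function(gru_layers = 3, hidden_units = 32,
                       categorical_dense_units = 16,
                       alpha = 0.75, beta = 0.25,
                       batch_size = 128, iterations = 2000,
                       subsequence_len_in = 1000, downsample = 4,
                       learning_rate = 1e-3, rmsprop_decay = 0.9,
                       input_scale = 0.05, rng_seed = NULL) {
  if (gru_layers != 3) {
    stop("the architecture uses exactly 3 bidirectional GRU layers",
         call. = FALSE)
  }
  if (abs(alpha + beta - 1) > 1e-12) {
    stop("alpha + beta must equal 1", call. = FALSE)
  }
  if (subsequence_len_in %% downsample != 0) {
    stop("subsequence length must be a multiple of the decimation factor",
         call. = FALSE)
  }
  structure(list(gru_layers = 3L, hidden_units = as.integer(hidden_units),
                 categorical_dense_units = as.integer(categorical_dense_units),
                 alpha = alpha, beta = beta,
                 batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 subsequence_len_in = as.integer(subsequence_len_in),
                 downsample = as.integer(downsample),
                 subsequence_len_train =
                   as.integer(subsequence_len_in / downsample),
                 learning_rate = learning_rate,
                 rmsprop_decay = rmsprop_decay,
                 input_scale = input_scale, rng_seed = rng_seed),
            class = "rnn_config")
}

#' Initialize network parameters
#'
#' Uniform initialization in `[-1/sqrt(fan_in), 1/sqrt(fan_in)]` per weight
#' matrix; biases start at zero.  GRU gate blocks are ordered `[z | r | n]`.
#'
#' @param cfg An [rnn_config()].
#' @param input_dim Sequential input dimensionality (default 4).
#' @return An object of class `rnn_model`: named list of parameter matrices
#'   plus the config as attribute.
#' @export
rnn_init <- function(cfg = rnn_config(), input_dim = 4) {
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  H <- cfg$hidden_units
  Cc <- cfg$categorical_dense_units
  u <- function(nr, nc) {
    a <- 1 / sqrt(nr)
    matrix(runif(nr * nc, -a, a), nr, nc)
  }
  params <- list()
  din <- input_dim
  for (l in 1:3) {
    for (d in c("f", "b")) {
      params[[paste0("W", l, d)]] <- u(din, 3 * H)
      params[[paste0("U", l, d)]] <- u(H, 3 * H)
      params[[paste0("b", l, d)]] <- matrix(0, 1, 3 * H)
    }
    din <- 2 * H
  }
  params$Wc <- u(2, Cc)
  params$bc <- matrix(0, 1, Cc)
  params$Wp <- u(2 * H + Cc, 2)
  params$bp <- matrix(0, 1, 2)
  params$Wd <- u(2 * H + Cc, 4)
  params$bd <- matrix(0, 1, 4)
  structure(list(params = params, config = cfg, input_dim = input_dim,
                 loss_log = NULL),
            class = "rnn_model")
}

.record_window <- function(record, start, cfg) {
  idx <- seq(start, start + cfg$subsequence_len_in - 1L)
  keep <- idx[seq(1, length(idx), by = cfg$downsample)]
  list(
    x = rbind(record$p_x[keep], record$p_y[keep],
              record$s_x[keep], record$s_y[keep]) * cfg$input_scale,
    y = record$occluded[keep],
    cat = c(if (record$config$contrast == "high") 1 else 0,
            if (record$config$pursuit == "saccadic") 1 else 0),
    shape = .scotoma_kind_code(record$scotoma$kind),
    sample_idx = keep)
}

#' Sample a training batch
#'
#' Draws `batch_size` trials with replacement from the training records;
#' from each, a uniformly placed window of `subsequence_len_in` samples is
#' taken and decimated to the training rate.  Occlusion labels are decimated
#' identically and the contrast/pursuit flags attached.  Trials shorter than
#' the window are skipped (with a warning).
#'
#' @param records List of `tracking_record`s.
#' @param cfg An [rnn_config()].
#' @return A `training_batch`: list with array `x` (batch x 4 x steps),
#'   matrix `categorical` (batch x 2), matrix `pointwise` (batch x steps),
#'   vector `shape` (0-based class codes).
#' @export
sample_batch <- function(records, cfg = rnn_config()) {
  usable <- vapply(records, function(r) length(r$s_x) >= cfg$subsequence_len_in,
                   logical(1))
  if (!all(usable)) {
    warning(sum(!usable), " trial(s) shorter than the window were skipped")
    records <- records[usable]
  }
  if (length(records) == 0) stop("no usable trials", call. = FALSE)
  B <- cfg$batch_size
  Tn <- cfg$subsequence_len_train
  x <- array(0, c(B, 4, Tn))
  ys <- matrix(0L, B, Tn)
  cats <- matrix(0, B, 2)
  shapes <- integer(B)
  pick <- sample.int(length(records), B, replace = TRUE)
  for (b in seq_len(B)) {
    rec <- records[[pick[b]]]
    start <- sample.int(length(rec$s_x) - cfg$subsequence_len_in + 1L, 1)
    w <- .record_window(rec, start, cfg)
    x[b, , ] <- w$x
    ys[b, ] <- w$y
    cats[b, ] <- w$cat
    shapes[b] <- w$shape
  }
  structure(list(x = x, categorical = cats, pointwise = ys, shape = shapes),
            class = "training_batch")
}

#' Forward pass
#'
#' @param model An `rnn_model`.
#' @param batch A `training_batch` (labels may be dummy zeros for pure
#'   prediction).
#' @return List with `pointwise_probs` (batch x 2 x steps array) and
#'   `shape_probs` (batch x 4 matrix); both heads are proper probability
#'   distributions.
#' @export
rnn_forward <- function(model, batch) {
  res <- rnn_pass_cpp(model$params, batch$x, batch$categorical,
                      matrix(as.numeric(batch$pointwise),
                             nrow(batch$categorical)),
                      as.numeric(batch$shape),
                      model$config$alpha, model$config$beta, FALSE)
  list(pointwise_probs = res$pointwise_probs, shape_probs = res$shape_probs)
}

#' Loss and gradients on one batch
#'
#' Weighted cross-entropy `J = alpha * CE(pointwise, averaged over steps and
#' batch) + beta * CE(shape, averaged over batch)`; log-probabilities are
#' clamped at 1e-12.
#'
#' @param model An `rnn_model`.
#' @param batch A `training_batch` with labels.
#' @param want_grad Also compute parameter gradients.
#' @return List with `loss`, `loss_pointwise`, `loss_shape`, predictions
#'   and (optionally) `grads`.
#' @export
rnn_loss <- function(model, batch, want_grad = FALSE) {
  rnn_pass_cpp(model$params, batch$x, batch$categorical,
               matrix(as.numeric(batch$pointwise), nrow(batch$categorical)),
               as.numeric(batch$shape),
               model$config$alpha, model$config$beta, want_grad)
}

#' Train the network
#'
#' Mini-batch RMSprop on the weighted cross-entropy for `cfg$iterations`
#' steps.  Deterministic given `cfg$rng_seed` (all randomness flows through
#' R's RNG).  Aborts if the loss becomes non-finite.
#'
#' @param records Training `tracking_record`s (all four defect conditions).
#' @param cfg An [rnn_config()].
#' @param log_every Record the loss every this many iterations (default 50).
#' @param verbose Print progress.
#' @return A trained `rnn_model` with a `loss_log` data.frame.
#' @export
rnn_train <- function(records, cfg = rnn_config(), log_every = 50,
                      verbose = FALSE) {
  model <- rnn_init(cfg)
  params <- model$params
  caches <- lapply(params, function(p) p * 0)
  rho <- cfg$rmsprop_decay
  lr <- cfg$learning_rate
  eps <- 1e-8
  log_it <- integer(0); log_loss <- numeric(0)
  for (it in seq_len(cfg$iterations)) {
    batch <- sample_batch(records, cfg)
    res <- rnn_pass_cpp(params, batch$x, batch$categorical,
                        matrix(as.numeric(batch$pointwise), cfg$batch_size),
                        as.numeric(batch$shape), cfg$alpha, cfg$beta, TRUE)
    if (!is.finite(res$loss)) {
      stop("training diverged at iteration ", it, " (non-finite loss)",
           call. = FALSE)
    }
    g <- res$grads
    for (nm in names(params)) {
      caches[[nm]] <- rho * caches[[nm]] + (1 - rho) * g[[nm]]^2
      params[[nm]] <- params[[nm]] - lr * g[[nm]] / (sqrt(caches[[nm]]) + eps)
    }
    if (it == 1L || it %% log_every == 0L) {
      log_it <- c(log_it, it); log_loss <- c(log_loss, res$loss)
      if (verbose) message(sprintf("iter %5d  loss %.4f", it, res$loss))
    }
  }
  model$params <- params
  model$loss_log <- data.frame(iteration = log_it, loss = log_loss)
  model
}

.batch_from_windows <- function(windows) {
  B <- length(windows)
  Tn <- ncol(windows[[1]]$x)
  x <- array(0, c(B, 4, Tn))
  ys <- matrix(0L, B, Tn)
  cats <- matrix(0, B, 2)
  shapes <- integer(B)
  for (b in seq_len(B)) {
    x[b, , ] <- windows[[b]]$x
    ys[b, ] <- windows[[b]]$y
    cats[b, ] <- windows[[b]]$cat
    shapes[b] <- windows[[b]]$shape
  }
  structure(list(x = x, categorical = cats, pointwise = ys, shape = shapes),
            class = "training_batch")
}

#' Ensemble defect-shape prediction for one participant
#'
#' Takes one downsampled subsequence per trial (the first window of each),
#' averages the K predicted shape distributions and returns the argmax
#' class (ties broken toward the lowest class index, i.e. the order of
#' [scotoma_kinds()]).
#'
#' @param model A trained `rnn_model`.
#' @param records The participant's trials (standard protocol: K = 24).
#' @return List with `class` (character), `probs` (length-4 averaged
#'   distribution) and `K`.
#' @export
predict_shape <- function(model, records) {
  if (inherits(records, "tracking_record")) records <- list(records)
  if (length(records) == 0) stop("K = 0: no records", call. = FALSE)
  cfg <- model$config
  windows <- lapply(records, .record_window, start = 1L, cfg = cfg)
  batch <- .batch_from_windows(windows)
  probs <- rnn_forward(model, batch)$shape_probs
  avg <- colMeans(probs)
  cls <- scotoma_kinds()[which.max(avg)]
  list(class = cls, probs = setNames(avg, scotoma_kinds()),
       K = length(records))
}

#' Point-wise map reconstruction from the network
#'
#' Tiles each trial into consecutive non-overlapping windows, decimates,
#' predicts the per-step obstruction class (argmax of the point-wise head)
#' and back-projects the predicted flags at the retained samples'
#' retinotopic coordinates.  Any tail shorter than one window is dropped.
#'
#' @param model A trained `rnn_model`.
#' @param records Trials to reconstruct (pooled into one map).
#' @param grid A [field_grid()].
#' @return A `field_map`.
#' @export
predict_pointwise_map <- function(model, records, grid = field_grid()) {
  if (inherits(records, "tracking_record")) records <- list(records)
  cfg <- model$config
  rx <- numeric(0); ry <- numeric(0); fl <- integer(0)
  for (rec in records) {
    nwin <- length(rec$s_x) %/% cfg$subsequence_len_in
    if (nwin == 0) next
    windows <- lapply(seq_len(nwin), function(w) {
      .record_window(rec, (w - 1L) * cfg$subsequence_len_in + 1L, cfg)
    })
    batch <- .batch_from_windows(windows)
    probs <- rnn_forward(model, batch)$pointwise_probs  # B x 2 x T
    pred <- (probs[, 2, , drop = FALSE] > probs[, 1, , drop = FALSE]) * 1L
    sgn <- if (grid$flip_sign) -1 else 1
    for (w in seq_len(nwin)) {
      keep <- windows[[w]]$sample_idx
      rx <- c(rx, sgn * (rec$s_x[keep] - rec$p_x[keep]))
      ry <- c(ry, sgn * (rec$s_y[keep] - rec$p_y[keep]))
      fl <- c(fl, as.integer(pred[w, 1, ]))
    }
  }
  backproject_samples(rx, ry, fl, grid)
}

#' Shape-classification robustness to miscalibration
#'
#' Applies constant gaze offsets of the given magnitudes (direction drawn
#' uniformly at random per record) to the test records, then reports the
#' ensemble shape-classification accuracy per magnitude.  Chance level for
#' the four classes is 25%.
#'
#' @param model A trained `rnn_model`.
#' @param cohort A [simulate_cohort()] result providing the test records.
#' @param participants Participant ids to evaluate.
#' @param magnitudes Offset magnitudes in degrees (default `0:5`).
#' @param directions_per_case Number of random offset directions averaged
#'   per participant-condition case (default 1).
#' @return data.frame with columns `magnitude`, `accuracy`, `n_cases`.
#' @export
miscalibration_robustness <- function(model, cohort, participants,
                                      magnitudes = 0:5,
                                      directions_per_case = 1) {
  man <- cohort$manifest
  out <- lapply(magnitudes, function(m) {
    correct <- 0L; total <- 0L
    for (p in participants) {
      for (cond in unique(man$condition[man$participant_id == p])) {
        for (d in seq_len(directions_per_case)) {
          recs <- cohort_records(cohort, p, cond)
          theta <- runif(1, 0, 2 * pi)
          off <- m * c(cos(theta), sin(theta))
          recs <- lapply(recs, function(r) {
            r$p_x <- r$p_x + off[1]
            r$p_y <- r$p_y + off[2]
            r
          })
          pred <- predict_shape(model, recs)$class
          correct <- correct + as.integer(pred == cond)
          total <- total + 1L
        }
      }
    }
    data.frame(magnitude = m, accuracy = correct / total, n_cases = total)
  })
  do.call(rbind, out)
}

#' @export
print.rnn_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(
    "<rnn_model> 3 BiGRU layers x %d units, %d categorical units, %d parameters\n",
    x$config$hidden_units, x$config$categorical_dense_units, np))
  if (!is.null(x$loss_log) && nrow(x$loss_log)) {
    cat(sprintf("  trained %d iterations, final loss %.4f\n",
                max(x$loss_log$iteration),
                x$loss_log$loss[nrow(x$loss_log)]))
  }
  invisible(x)
}
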