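#' 2D Spearman accuracy between a reconstruction and a reference map
#'
#' Spearman rank correlation over the cells sampled in both maps (average
#' ranks for ties).  A constant map makes rank correlation undefined; the
#' fallbacks are asymmetric by design: when the *reference* map is constant
#' (notably the all-zero no-loss ground truth) the accuracy is
#' `1 - mean(|a - b|)` over the common cells (1 for a perfect empty
#' reconstruction), but when only the *reconstruction* is constant it
#' carries no rank information and the accuracy is 0.  A symmetric fallback
#' would reward degenerate empty reconstructions of small defects (an empty
#' central-loss map is close to truth in L1 while detecting nothing) and
#' lets the percentile optimization collapse onto thresholds that flag
#' nothing.
#'
#' @param map_a The reconstructed `field_map`.
#' @param map_b The reference (ground-truth) `field_map`, same grid.
#' @return A scalar accuracy.
#' @export
spearman2d <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "field_map"), inherits(map_b, "field_map"))
  if (!identical(dim(map_a$values), dim(map_b$values))) {
    stop("maps are on different grids", call. = FALSE)
  }
  common <- map_a$sampled_mask & map_b$sampled_mask
  if (sum(common) < 3) stop("insufficient overlap: < 3 common cells",
                            call. = FALSE)
  a <- map_a$values[common]
  b <- map_b$values[common]
  .spearman_or_fallback(a, b)
}

.spearman_or_fallback <- function(a, b) {
  if (length(unique(b)) < 2) return(1 - mean(abs(a - b)))
  if (length(unique(a)) < 2) return(0)
  cor(a, b, method = "spearman")
}

#' Participant-aware fold plan
#'
#' Partitions participant ids into `k` contiguous near-equal blocks; fold 1
#' tests the last block, fold `k` the first (so 50 ids with `k = 5` give the
#' canonical plan where fold 1 tests ids 41-50 and fold 5 tests ids 1-10).
#' Train and test sets are disjoint within each fold and the test sets
#' partition the ids across folds.
#'
#' @param participant_ids Character or integer vector of ids.
#' @param k Number of folds (default 5).
#' @return An object of class `fold_plan`: list of `k` elements, each with
#'   `train` and `test` id vectors.
#' @export
make_fold_plan <- function(participant_ids, k = 5) {
  n <- length(participant_ids)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop("need at least k participants", call. = FALSE)
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1
  block <- rep(seq_len(k), sizes)
  folds <- lapply(seq_len(k), function(j) {
    test <- participant_ids[block == k + 1 - j]
    list(train = setdiff(participant_ids, test), test = test)
  })
  structure(folds, class = "fold_plan")
}

# Per participant-per-condition cache of back-projected TFCE samples:
# cell index, per-cell sorted TFCE values, per-cell ground-truth counts.
# Lets the lambda sweep re-threshold in O(cells * n_lambda) per map.
.map_cache_entry <- function(records, grid, params) {
  tf <- numeric(0); rx <- numeric(0); ry <- numeric(0); truth <- integer(0)
  all_values <- numeric(0)
  for (r in records) {
    v <- tfce_transform(deviation_series(r), params)$values
    all_values <- c(all_values, v)
    sgn <- if (grid$flip_sign) -1 else 1
    tf <- c(tf, v)
    rx <- c(rx, sgn * (r$s_x - r$p_x))
    ry <- c(ry, sgn * (r$s_y - r$p_y))
    truth <- c(truth, r$occluded)
  }
  ix <- floor(rx) + grid$ex + 1
  iy <- floor(ry) + grid$ey + 1
  ok <- ix >= 1 & ix <= grid$nx & iy >= 1 & iy <= grid$ny
  idx <- (ix[ok] - 1L) * grid$ny + iy[ok]
  tf <- tf[ok]; truth <- truth[ok]
  o <- order(idx, tf)
  idx <- idx[o]; tf <- tf[o]; truth <- truth[o]
  rl <- rle(idx)
  ends <- cumsum(rl$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  truth_cell <- vapply(seq_along(starts),
                       function(j) sum(truth[starts[j]:ends[j]]), numeric(1))
  list(cells = rl$values, starts = starts, ends = ends,
       lens = rl$lengths, tf = tf, truth_cell = truth_cell,
       all_values = all_values)
}

# Accuracy of the thresholded map vs. ground truth for each threshold.
.cache_accuracies <- function(entry, thrs, min_count) {
  keep <- entry$lens >= min_count
  st <- entry$starts[keep]; en <- entry$ends[keep]; ln <- entry$lens[keep]
  truth_v <- entry$truth_cell[keep] / ln
  nl <- length(thrs)
  acc <- numeric(nl)
  above <- matrix(0, length(st), nl)
  for (j in seq_along(st)) {
    above[j, ] <- ln[j] - findInterval(thrs, entry$tf[st[j]:en[j]])
  }
  for (i in seq_len(nl)) {
    acc[i] <- .spearman_or_fallback(above[, i] / ln, truth_v)
  }
  acc
}

# Reconstructed field map from a cache entry at a single threshold.
.cache_map <- function(entry, thr, grid) {
  counts <- matrix(0, grid$ny, grid$nx)
  flagged <- matrix(0, grid$ny, grid$nx)
  counts[entry$cells] <- entry$lens
  above <- vapply(seq_along(entry$starts), function(j) {
    entry$lens[j] - findInterval(thr, entry$tf[entry$starts[j]:entry$ends[j]])
  }, numeric(1))
  flagged[entry$cells] <- above
  .new_field_map(counts, flagged, 0, grid)
}

.cache_truth_map <- function(entry, grid) {
  counts <- matrix(0, grid$ny, grid$nx)
  flagged <- matrix(0, grid$ny, grid$nx)
  counts[entry$cells] <- entry$lens
  flagged[entry$cells] <- entry$truth_cell
  .new_field_map(counts, flagged, 0, grid)
}

.build_map_cache <- function(cohort, grid, params, participants = NULL) {
  man <- cohort$manifest
  if (is.null(participants)) participants <- unique(man$participant_id)
  cache <- list()
  for (p in participants) {
    cache[[p]] <- list()
    for (cond in unique(man$condition[man$participant_id == p])) {
      recs <- cohort_records(cohort, p, cond)
      cache[[p]][[cond]] <- .map_cache_entry(recs, grid, params)
    }
  }
  cache
}

#' Reconstruct a TFCE visual field map
#'
#' Full first-route pipeline for a set of pooled trials: deviation series,
#' TFCE transform, binarization against the normative percentile threshold,
#' and retinotopic back-projection.
#'
#' @param records List of `tracking_record`s (pooled into one map).
#' @param norms A [build_normative_distribution()] result.
#' @param lambda_n Percentile threshold in `[1, 100]`.
#' @param grid A [field_grid()].
#' @param params A [tfce_params()].
#' @return A `field_map`.
#' @export
reconstruct_tfce_map <- function(records, norms, lambda_n,
                                 grid = field_grid(),
                                 params = tfce_params()) {
  if (inherits(records, "tracking_record")) records <- list(records)
  flags <- lapply(records, function(r) {
    binarize(tfce_transform(deviation_series(r), params), norms, lambda_n)
  })
  backproject(flags, records, grid)
}

#' Optimize the normative percentile threshold
#'
#' For each candidate percentile, reconstructs every training participant's
#' map in every defect condition, scores it against the ground-truth map
#' (2D Spearman with constant-map fallback), averages over participants per
#' condition and grand-averages over conditions.  Returns the percentile at
#' the peak of the grand average (ties broken toward the lowest percentile).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param participants Training participant ids (default: all).
#' @param norms Optional normative distribution; by default built from the
#'   training participants' no-loss trials.
#' @param lambdas Candidate percentiles (default `1:100`).
#' @param grid,params Grid and TFCE settings.
#' @param cache Internal precomputed cache (used by cross-validation).
#' @return List with `lambda_opt`, `grand_curve` (named by lambda),
#'   `condition_curves` (conditions x lambdas matrix) and `norms`.
#' @export
optimize_lambda <- function(cohort, participants = NULL, norms = NULL,
                            lambdas = 1:100, grid = field_grid(),
                            params = tfce_params(), cache = NULL) {
  man <- cohort$manifest
  if (is.null(participants)) participants <- unique(man$participant_id)
  conds <- unique(man$condition[man$participant_id %in% participants])
  if (!all(scotoma_kinds() %in% conds)) {
    stop("training set must contain all four defect conditions",
         call. = FALSE)
  }
  if (is.null(cache)) {
    cache <- .build_map_cache(cohort, grid, params, participants)
  }
  if (is.null(norms)) {
    vals <- unlist(lapply(participants,
                          function(p) cache[[p]][["none"]]$all_values))
    norms <- structure(list(values = sort(vals), source_ids = participants),
                       class = "normative_distribution")
  }
  thrs <- quantile(norms$values, lambdas / 100, type = 7, names = FALSE)
  cond_curves <- matrix(NA_real_, length(scotoma_kinds()), length(lambdas),
                        dimnames = list(scotoma_kinds(), lambdas))
  for (cond in scotoma_kinds()) {
    accs <- vapply(participants, function(p) {
      .cache_accuracies(cache[[p]][[cond]], thrs, grid$min_count)
    }, numeric(length(lambdas)))
    cond_curves[cond, ] <- rowMeans(matrix(accs, nrow = length(lambdas)))
  }
  grand <- colMeans(cond_curves)
  lambda_opt <- lambdas[which.max(grand)]
  list(lambda_opt = lambda_opt, grand_curve = setNames(grand, lambdas),
       condition_curves = cond_curves, norms = norms)
}

#' Fivefold cross-validated TFCE evaluation
#'
#' Participant-aware cross-validation of the TFCE route: per fold, the
#' normative distribution and the optimal percentile are estimated on the
#' training participants only, then the held-out participants' maps are
#' reconstructed at that percentile and scored against their ground-truth
#' maps.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param k Number of folds (default 5).
#' @param lambdas Candidate percentiles.
#' @param grid,params Grid and TFCE settings.
#' @return An object of class `cv_report`: per-fold optimal lambda, a
#'   data.frame `accuracies` (fold, participant, condition, accuracy), the
#'   deployment lambda (mean of per-fold optima), the fold plan and the
#'   held-out reconstructed/ground-truth map pairs (`maps`).
#' @export
crossvalidate_tfce <- function(cohort, k = 5, lambdas = 1:100,
                               grid = field_grid(), params = tfce_params()) {
  ids <- unique(cohort$manifest$participant_id)
  plan <- make_fold_plan(ids, k)
  cache <- .build_map_cache(cohort, grid, params, ids)
  lambda_opt <- numeric(length(plan))
  rows <- list()
  maps <- list()
  for (f in seq_along(plan)) {
    opt <- optimize_lambda(cohort, plan[[f]]$train, lambdas = lambdas,
                           grid = grid, params = params, cache = cache)
    lambda_opt[f] <- opt$lambda_opt
    thr <- normative_threshold(opt$norms, opt$lambda_opt)
    for (p in plan[[f]]$test) {
      for (cond in scotoma_kinds()) {
        entry <- cache[[p]][[cond]]
        recon <- .cache_map(entry, thr, grid)
        truth <- .cache_truth_map(entry, grid)
        rows[[length(rows) + 1L]] <- data.frame(
          fold = f, participant_id = p, condition = cond,
          accuracy = spearman2d(recon, truth), stringsAsFactors = FALSE)
        maps[[length(maps) + 1L]] <- list(fold = f, participant_id = p,
                                          condition = cond, recon = recon,
                                          truth = truth)
      }
    }
  }
  structure(list(lambda_per_fold = lambda_opt,
                 deployment_lambda = mean(lambda_opt),
                 accuracies = do.call(rbind, rows), plan = plan,
                 maps = maps),
            class = "cv_report")
}

#' False-positive / false-negative error maps
#'
#' Classifies each common cell of both maps as loss (value > `threshold`)
#' or healthy, and reports per-cell false-positive and false-negative
#' indicator maps plus total rates (normalized by truth-negative and
#' truth-positive cell counts).  With no truth-positive cells the FNR is
#' undefined and reported as `NA`.
#'
#' @param reconstructed,truth `field_map`s on the same grid.
#' @param threshold Cell classification cut (default 0.5).
#' @return List with `fp_map`, `fn_map` (NA outside common cells), `fpr`,
#'   `fnr`.
#' @export
error_maps <- function(reconstructed, truth, threshold = 0.5) {
  stopifnot(inherits(reconstructed, "field_map"),
            inherits(truth, "field_map"))
  if (!identical(dim(reconstructed$values), dim(truth$values))) {
    stop("maps are on different grids", call. = FALSE)
  }
  common <- reconstructed$sampled_mask & truth$sampled_mask
  rcls <- reconstructed$values > threshold
  tcls <- truth$values > threshold
  fp <- matrix(NA_real_, nrow(rcls), ncol(rcls))
  fn <- matrix(NA_real_, nrow(rcls), ncol(rcls))
  fp[common] <- as.numeric(rcls[common] & !tcls[common])
  fn[common] <- as.numeric(!rcls[common] & tcls[common])
  npos <- sum(tcls[common])
  nneg <- sum(!tcls[common])
  list(fp_map = fp, fn_map = fn,
       fpr = if (nneg > 0) sum(fp[common]) / nneg else NA_real_,
       fnr = if (npos > 0) sum(fn[common]) / npos else NA_real_)
}

#' Summarize accuracy distributions and compare methods
#'
#' Per-condition median, mean and interquartile range of map accuracies for
#' each method, plus a Kruskal-Wallis rank test between methods per
#' condition.
#'
#' @param accuracies data.frame with columns `method`, `condition`,
#'   `accuracy`.
#' @return An object of class `evaluation_report` with elements `table`
#'   (per method x condition summary) and `tests` (per-condition
#'   Kruskal-Wallis p-values; `NA` when only one method present).
#' @export
summarize_accuracy <- function(accuracies) {
  stopifnot(all(c("method", "condition", "accuracy") %in% names(accuracies)))
  tab <- do.call(rbind, lapply(split(accuracies,
                                     accuracies[c("method", "condition")],
                                     drop = TRUE), function(d) {
    data.frame(method = d$method[1], condition = d$condition[1],
               n = nrow(d), median = median(d$accuracy),
               mean = mean(d$accuracy),
               iqr = unname(diff(quantile(d$accuracy, c(0.25, 0.75),
                                          type = 7))),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  tests <- vapply(split(accuracies, accuracies$condition), function(d) {
    if (length(unique(d$method)) < 2 ||
        length(unique(d$accuracy)) < 2) return(NA_real_)
    kruskal.test(d$accuracy, factor(d$method))$p.value
  }, numeric(1))
  structure(list(table = tab, tests = tests), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  print(x$table)
  cat("Kruskal-Wallis p-values by condition:\n")
  print(x$tests)
  invisible(x)
}
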