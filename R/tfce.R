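#' TFCE parameters
#'
#' Exponents and discretization of the threshold-free cluster enhancement
#' transform.  `E` weights the temporal extent of a supra-threshold cluster
#' and `H` its height; the recommended defaults are E = 2, H = 0.5.  The
#' integral over heights is discretized into `n_steps` levels spanning
#' `[min(D), max(D)]` of each series (default 2500).  Extents are measured
#' in seconds by default so results are sample-rate invariant.
#'
#' @param E Extent exponent (default 2).
#' @param H Height exponent (default 0.5).
#' @param n_steps Number of height levels (default 2500).
#' @param extent_unit `"seconds"` or `"samples"`.
#' @return An object of class `tfce_params`.
#' @export
tfce_params <- function(E = 2, H = 0.5, n_steps = 2500,
                        extent_unit = c("seconds", "samples")) {
  extent_unit <- match.arg(extent_unit)
  if (E < 0 || H < 0) stop("E and H must be nonnegative", call. = FALSE)
  if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  structure(list(E = E, H = H, n_steps = as.integer(n_steps),
                 extent_unit = extent_unit),
            class = "tfce_params")
}

#' Positional deviation series
#'
#' The Euclidean eye-to-stimulus distance at each sample,
#' `D(t) = sqrt((p_x - s_x)^2 + (p_y - s_y)^2)`.
#'
#' @param record A `tracking_record`.
#' @return An object of class `deviation_series` with fields `values`
#'   (degrees), `dt` (seconds) and `provenance`.
#' @export
deviation_series <- function(record) {
  stopifnot(inherits(record, "tracking_record"))
  ns <- lengths(record[c("s_x", "s_y", "p_x", "p_y")])
  if (length(unique(ns)) != 1) {
    stop("malformed record: traces differ in length", call. = FALSE)
  }
  v <- sqrt((record$p_x - record$s_x)^2 + (record$p_y - record$s_y)^2)
  structure(list(values = v, dt = 1 / record$config$sample_rate,
                 provenance = list(participant_id = record$participant_id,
                                   trial_id = record$trial_id,
                                   scotoma_kind = record$scotoma$kind)),
            class = "deviation_series")
}

#' TFCE transform of a deviation series
#'
#' Spatio-temporal integration of the deviation series: each sample's value
#' is the discrete integral, over height levels up to its own deviation, of
#' extent^E * height^H, where the extent is the duration of the maximal
#' contiguous run of samples at or above that height containing the sample.
#' A constant series yields all zeros (zero-width integration range).
#'
#' @param D A [deviation_series()] (or any object with numeric `values` and
#'   `dt`).
#' @param params A [tfce_params()].
#' @return An object of class `tfce_series` with `values`, `params`, `h0`,
#'   `h_max`, `dt` and `provenance`.
#' @export
tfce_transform <- function(D, params = tfce_params()) {
  stopifnot(inherits(params, "tfce_params"))
  v <- D$values
  if (length(v) == 0) stop("empty series", call. = FALSE)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("deviation series must be finite and nonnegative", call. = FALSE)
  }
  unit <- if (params$extent_unit == "seconds") D$dt else 1
  out <- tfce_cpp(v, params$E, params$H, params$n_steps, unit)
  structure(list(values = out, params = params,
                 h0 = min(v), h_max = max(v), dt = D$dt,
                 provenance = D$provenance),
            class = "tfce_series")
}

#' Pooled normative TFCE distribution
#'
#' Pools the TFCE values of all defect-free trials of the training
#' participants into one empirical distribution, from which percentile
#' thresholds are taken.  Any contributing trial labelled with a scotoma is
#' an error (contamination).
#'
#' @param no_loss_trials List of `tfce_series` from the no-loss condition.
#' @return An object of class `normative_distribution` with sorted `values`
#'   and `source_ids`.
#' @export
build_normative_distribution <- function(no_loss_trials) {
  if (length(no_loss_trials) == 0) {
    stop("no trials supplied", call. = FALSE)
  }
  for (tr in no_loss_trials) {
    stopifnot(inherits(tr, "tfce_series"))
    kind <- tr$provenance$scotoma_kind
    if (!is.null(kind) && kind != "none") {
      stop("contamination: trial with scotoma label '", kind,
           "' in normative set", call. = FALSE)
    }
  }
  vals <- sort(unlist(lapply(no_loss_trials, `[[`, "values")))
  ids <- unique(vapply(no_loss_trials,
                       function(tr) tr$provenance$participant_id %||% NA_character_,
                       character(1)))
  structure(list(values = vals, source_ids = ids[!is.na(ids)]),
            class = "normative_distribution")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percentile threshold of the normative distribution
#'
#' Linear interpolation on the sorted empirical distribution (quantile
#' type 7); no histogram binning is involved, so bin width never influences
#' thresholds.
#'
#' @param F A [build_normative_distribution()] result.
#' @param lambda_n Percentile in `[1, 100]`.
#' @return The threshold value `F(lambda_n)`.
#' @export
normative_threshold <- function(F, lambda_n) {
  stopifnot(inherits(F, "normative_distribution"))
  if (length(F$values) == 0) stop("empty normative distribution",
                                  call. = FALSE)
  if (lambda_n < 1 || lambda_n > 100) {
    stop("`lambda_n` must be in [1, 100]", call. = FALSE)
  }
  unname(quantile(F$values, lambda_n / 100, type = 7, names = FALSE))
}

#' Binarize a TFCE series against a normative threshold
#'
#' Flags a sample as "visual loss" (1) when its TFCE value strictly exceeds
#' the `lambda_n`-th percentile of the normative distribution; values at or
#' below the threshold are "healthy" (0).
#'
#' @param series A [tfce_transform()] result.
#' @param F A [build_normative_distribution()] result.
#' @param lambda_n Percentile in `[1, 100]`.
#' @return An object of class `binary_series` with `flags`, `lambda_n` and
#'   `threshold_value`.
#' @export
binarize <- function(series, F, lambda_n) {
  stopifnot(inherits(series, "tfce_series"))
  thr <- normative_threshold(F, lambda_n)
  structure(list(flags = as.integer(series$values > thr),
                 lambda_n = lambda_n, threshold_value = thr,
                 provenance = series$provenance),
            class = "binary_series")
}

#' Construct a binary series directly from flags
#'
#' Convenience constructor used for ground-truth flags and network output.
#'
#' @param flags 0/1 vector.
#' @param lambda_n,threshold_value Optional metadata.
#' @return A `binary_series`.
#' @export
binary_series <- function(flags, lambda_n = NA_real_,
                          threshold_value = NA_real_) {
  stopifnot(all(flags %in% c(0L, 1L)))
  structure(list(flags = as.integer(flags), lambda_n = lambda_n,
                 threshold_value = threshold_value, provenance = NULL),
            class = "binary_series")
}
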