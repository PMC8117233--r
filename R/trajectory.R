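#' Trial configuration
#'
#' Describes one 20-s tracking trial: sampling rate, stimulus contrast,
#' pursuit mode and the extent of the stimulus field.  Positions are in
#' degrees of visual angle with the origin at screen centre; time is the
#' sample index times `1/sample_rate`.
#'
#' @param duration Trial duration in seconds (default 20).
#' @param sample_rate Sampling rate in Hz (default 240, the display refresh
#'   rate the protocol is built around).
#' @param contrast `"low"` (5% from background) or `"high"` (50%).
#' @param pursuit `"smooth"` (pure random walk) or `"saccadic"` (random walk
#'   interleaved with displacement jumps).
#' @param field_halfwidth_x,field_halfwidth_y Half-extent of the stimulus
#'   field in degrees (defaults 24 and 13.5).
#' @param rng_seed Optional integer seed; when non-`NULL`, path generation is
#'   reproducible.
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(duration = 20, sample_rate = 240,
                         contrast = c("high", "low"),
                         pursuit = c("smooth", "saccadic"),
                         field_halfwidth_x = 24, field_halfwidth_y = 13.5,
                         rng_seed = NULL) {
  contrast <- match.arg(contrast)
  pursuit <- match.arg(pursuit)
  if (!is.numeric(duration) || length(duration) != 1 || !is.finite(duration) ||
      duration <= 0) {
    stop("invalid configuration: `duration` must be a positive number",
         call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    stop("invalid configuration: `sample_rate` must be a positive number",
         call. = FALSE)
  }
  if (field_halfwidth_x <= 0 || field_halfwidth_y <= 0) {
    stop("invalid configuration: field halfwidths must be positive",
         call. = FALSE)
  }
  structure(list(duration = duration, sample_rate = sample_rate,
                 contrast = contrast, pursuit = pursuit,
                 field_halfwidth_x = field_halfwidth_x,
                 field_halfwidth_y = field_halfwidth_y,
                 rng_seed = rng_seed),
            class = "trial_config")
}

#' Number of samples in a trial
#' @param cfg A [trial_config()].
#' @return Integer sample count, `round(duration * sample_rate)`.
#' @export
n_samples <- function(cfg) {
  stopifnot(inherits(cfg, "trial_config"))
  as.integer(round(cfg$duration * cfg$sample_rate))
}

#' Random-walk parameters
#'
#' Parameters of the velocity-random-walk stimulus path.  The smooth
#' component is a first-order autocorrelated velocity process: heading
#' performs rotation diffusion with intensity `dir_sigma` while speed relaxes
#' toward `mean_speed` at rate `speed_relax` under Gaussian perturbations of
#' intensity `speed_sigma`.  In the saccadic condition, displacement jumps
#' occur at inter-jump intervals drawn uniformly from
#' `[jump_interval_min, jump_interval_max]` seconds with a target uniform in
#' the field rectangle.
#'
#' @param mean_speed Mean stimulus speed, degrees/s (default 10).
#' @param dir_sigma Heading diffusion, rad/sqrt(s) (default 1.5).
#' @param speed_relax Speed relaxation rate, 1/s (default 4).
#' @param speed_sigma Speed perturbation, deg/s/sqrt(s) (default 3).
#' @param jump_interval_min,jump_interval_max Inter-jump interval bounds in
#'   seconds (defaults 1 and 3).
#' @return An object of class `walk_params`.
#' @export
walk_params <- function(mean_speed = 10, dir_sigma = 1.5, speed_relax = 4,
                        speed_sigma = 3, jump_interval_min = 1,
                        jump_interval_max = 3) {
  if (mean_speed <= 0) stop("`mean_speed` must be positive", call. = FALSE)
  if (jump_interval_min <= 0 || jump_interval_max < jump_interval_min) {
    stop("invalid jump interval bounds", call. = FALSE)
  }
  structure(list(mean_speed = mean_speed, dir_sigma = dir_sigma,
                 speed_relax = speed_relax, speed_sigma = speed_sigma,
                 jump_interval_min = jump_interval_min,
                 jump_interval_max = jump_interval_max),
            class = "walk_params")
}

#' Generate a stimulus trajectory
#'
#' Produces a pseudo-random-walk path confined to the field rectangle by
#' reflection at the edges.  Under `pursuit = "saccadic"`, displacement jumps
#' are interleaved at random intervals; under `"smooth"` the jump list is
#' empty.
#'
#' @param cfg A [trial_config()].
#' @param walk A [walk_params()].
#' @return An object of class `stimulus_trajectory` with fields `s_x`, `s_y`
#'   (degrees), `jump_times` (1-based sample indices) and `config`.
#' @export
generate_trajectory <- function(cfg, walk = walk_params()) {
  stopifnot(inherits(cfg, "trial_config"), inherits(walk, "walk_params"))
  n <- n_samples(cfg)
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  res <- walk_path_cpp(n, 1 / cfg$sample_rate,
                       cfg$field_halfwidth_x, cfg$field_halfwidth_y,
                       walk$mean_speed, walk$dir_sigma, walk$speed_relax,
                       walk$speed_sigma, cfg$pursuit == "saccadic",
                       walk$jump_interval_min, walk$jump_interval_max)
  structure(list(s_x = res$s_x, s_y = res$s_y,
                 jump_times = as.integer(res$jump_times), config = cfg),
            class = "stimulus_trajectory")
}

#' @export
print.stimulus_trajectory <- function(x, ...) {
  cat(sprintf("<stimulus_trajectory> %d samples at %g Hz, %s pursuit, %d jumps\n",
              length(x$s_x), x$config$sample_rate, x$config$pursuit,
              length(x$jump_times)))
  invisible(x)
}
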