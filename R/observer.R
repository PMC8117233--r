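#' Observer model parameters
#'
#' Parameters of the simulated tracker.  The observer pursues the stimulus
#' with a proportional gain on a latency-delayed copy of the stimulus
#' velocity plus white positional noise, and fires a corrective saccade
#' (instantaneous jump to the delayed target position plus landing noise)
#' once the positional error has exceeded `saccade_trigger_error`
#' continuously for `saccade_latency` seconds.  While the stimulus is
#' occluded there is no visual feedback: gaze either extrapolates its last
#' velocity or freezes, until the stimulus re-enters the seeing field.
#' Reaction latency and noise depend on stimulus contrast (low contrast is
#' slower and noisier).
#'
#' @param pursuit_gain Dimensionless pursuit gain in (0, 1.5] (default 0.95).
#' @param reaction_latency_high,reaction_latency_low Visuomotor latency in
#'   seconds at high/low contrast (defaults 0.12 and 0.18).
#' @param position_noise_sd Positional diffusion, deg/sqrt(s) (default 0.3).
#' @param noise_scale_low Multiplier on `position_noise_sd` at low contrast
#'   (default 1.5).
#' @param saccade_trigger_error Error threshold triggering a corrective
#'   saccade, degrees (default 2).
#' @param saccade_latency Time the error must persist before the saccade
#'   fires, seconds (default 0.2).
#' @param saccade_landing_noise_sd Landing scatter, degrees (default 0.5).
#' @param occluded_behavior `"extrapolate"` (continue last velocity, the
#'   default, consistent with pursuit extrapolation) or `"freeze"`.
#' @param extrapolation_decay Exponential decay rate of the extrapolated
#'   velocity while the stimulus is occluded, 1/s (default 0.7, so
#'   predictive pursuit persists over roughly a second, consistent with
#'   smooth-pursuit target-occlusion studies); gaze is also clamped to the
#'   screen rectangle.
#' @param search_latency Seconds without visual feedback before the
#'   observer makes a memory-guided exploratory saccade toward the
#'   extrapolated last-seen stimulus position (default 0.5); set to 0 to
#'   disable visual search.
#' @param search_scatter SD of the isotropic Gaussian scatter around the
#'   memory-guided search target, degrees (default 3).
#' @param rng_seed Optional integer seed.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(pursuit_gain = 0.95,
                            reaction_latency_high = 0.12,
                            reaction_latency_low = 0.18,
                            position_noise_sd = 0.3,
                            noise_scale_low = 1.5,
                            saccade_trigger_error = 2,
                            saccade_latency = 0.2,
                            saccade_landing_noise_sd = 0.5,
                            occluded_behavior = c("extrapolate", "freeze"),
                            extrapolation_decay = 0.7,
                            search_latency = 0.5,
                            search_scatter = 3,
                            rng_seed = NULL) {
  occluded_behavior <- match.arg(occluded_behavior)
  if (pursuit_gain <= 0 || pursuit_gain > 1.5) {
    stop("`pursuit_gain` must be in (0, 1.5]", call. = FALSE)
  }
  if (reaction_latency_high < 0 || reaction_latency_low < 0 ||
      saccade_latency < 0) {
    stop("latencies must be nonnegative", call. = FALSE)
  }
  if (position_noise_sd < 0 || saccade_landing_noise_sd < 0) {
    stop("noise SDs must be nonnegative", call. = FALSE)
  }
  structure(list(pursuit_gain = pursuit_gain,
                 reaction_latency_high = reaction_latency_high,
                 reaction_latency_low = reaction_latency_low,
                 position_noise_sd = position_noise_sd,
                 noise_scale_low = noise_scale_low,
                 saccade_trigger_error = saccade_trigger_error,
                 saccade_latency = saccade_latency,
                 saccade_landing_noise_sd = saccade_landing_noise_sd,
                 occluded_behavior = occluded_behavior,
                 extrapolation_decay = extrapolation_decay,
                 search_latency = search_latency,
                 search_scatter = search_scatter,
                 rng_seed = rng_seed),
            class = "observer_params")
}

#' Acquisition protocol
#'
#' @param repetitions Trials per contrast-by-pursuit cell (default 6).
#' @param contrasts Contrast levels tested (default both).
#' @param pursuits Pursuit modes tested (default both).
#' @return An object of class `protocol_config`.  The default yields
#'   6 x 2 x 2 = 24 trials (480 s) per defect condition.
#' @export
protocol_config <- function(repetitions = 6,
                            contrasts = c("low", "high"),
                            pursuits = c("smooth", "saccadic")) {
  stopifnot(repetitions >= 1, all(contrasts %in% c("low", "high")),
            all(pursuits %in% c("smooth", "saccadic")))
  structure(list(repetitions = repetitions, contrasts = contrasts,
                 pursuits = pursuits),
            class = "protocol_config")
}

#' Simulate one tracked trial
#'
#' Runs the discrete-time oculomotor control loop of the simulated observer
#' over a stimulus trajectory under a gaze-contingent scotoma, and returns
#' the full tracking record (stimulus, gaze, ground-truth occlusion flags).
#'
#' @param traj A [generate_trajectory()] result.
#' @param spec A [scotoma_spec()].
#' @param obs An [observer_params()].
#' @param participant_id,trial_id Identifiers stored with the record.
#' @return An object of class `tracking_record`.
#' @export
simulate_gaze <- function(traj, spec = scotoma_spec("none"),
                          obs = observer_params(),
                          participant_id = "p01", trial_id = "t01") {
  stopifnot(inherits(traj, "stimulus_trajectory"),
            inherits(spec, "scotoma_spec"),
            inherits(obs, "observer_params"))
  cfg <- traj$config
  if (!is.null(obs$rng_seed)) set.seed(obs$rng_seed)
  lat <- if (cfg$contrast == "high") obs$reaction_latency_high else
    obs$reaction_latency_low
  nsd <- obs$position_noise_sd *
    if (cfg$contrast == "low") obs$noise_scale_low else 1
  res <- simulate_gaze_cpp(traj$s_x, traj$s_y, 1 / cfg$sample_rate,
                           .scotoma_kind_code(spec$kind), spec$size_deg / 2,
                           obs$pursuit_gain,
                           as.integer(round(lat * cfg$sample_rate)), nsd,
                           obs$saccade_trigger_error, obs$saccade_latency,
                           obs$saccade_landing_noise_sd,
                           if (obs$occluded_behavior == "extrapolate") 0L else 1L,
                           obs$extrapolation_decay, obs$search_latency,
                           obs$search_scatter,
                           cfg$field_halfwidth_x, cfg$field_halfwidth_y)
  rec <- structure(list(config = cfg, scotoma = spec,
                        s_x = traj$s_x, s_y = traj$s_y,
                        p_x = res$p_x, p_y = res$p_y,
                        occluded = integer(length(traj$s_x)),
                        participant_id = participant_id, trial_id = trial_id),
                   class = "tracking_record")
  rec$occluded <- ground_truth_labels(rec)
  rec
}

#' @export
print.tracking_record <- function(x, ...) {
  cat(sprintf(
    "<tracking_record> %s/%s: %d samples, %s/%s, scotoma=%s, %.1f%% occluded\n",
    x$participant_id, x$trial_id, length(x$s_x), x$config$contrast,
    x$config$pursuit, x$scotoma$kind, 100 * mean(x$occluded)))
  invisible(x)
}

.draw_participant_params <- function(base, sd_frac) {
  trunc_norm <- function(mu, sd, lo, hi) {
    min(max(rnorm(1, mu, sd), lo), hi)
  }
  observer_params(
    pursuit_gain = trunc_norm(base$pursuit_gain,
                              sd_frac * base$pursuit_gain, 0.5, 1.2),
    reaction_latency_high = trunc_norm(base$reaction_latency_high,
                                       sd_frac * base$reaction_latency_high,
                                       0.05, 0.4),
    reaction_latency_low = trunc_norm(base$reaction_latency_low,
                                      sd_frac * base$reaction_latency_low,
                                      0.05, 0.5),
    position_noise_sd = trunc_norm(base$position_noise_sd,
                                   sd_frac * base$position_noise_sd, 0.05, 1),
    noise_scale_low = base$noise_scale_low,
    saccade_trigger_error = trunc_norm(base$saccade_trigger_error,
                                       sd_frac * base$saccade_trigger_error,
                                       1, 4),
    saccade_latency = trunc_norm(base$saccade_latency,
                                 sd_frac * base$saccade_latency, 0.1, 0.4),
    saccade_landing_noise_sd = trunc_norm(base$saccade_landing_noise_sd,
                                          sd_frac *
                                            base$saccade_landing_noise_sd,
                                          0.1, 1.5),
    occluded_behavior = base$occluded_behavior,
    extrapolation_decay = base$extrapolation_decay,
    search_latency = base$search_latency,
    search_scatter = base$search_scatter
  )
}

#' Simulate the full protocol for one participant and one defect
#'
#' Runs `repetitions x contrasts x pursuits` trials (default 24, i.e. 480 s
#' of tracking) for a single participant under one scotoma condition.
#'
#' @param participant_id Identifier.
#' @param spec A [scotoma_spec()].
#' @param protocol A [protocol_config()].
#' @param obs Observer parameters for this participant.
#' @param walk A [walk_params()].
#' @param base_cfg Template [trial_config()] supplying duration, rate and
#'   field extent.
#' @return A list of `tracking_record`s.
#' @export
simulate_participant <- function(participant_id, spec,
                                 protocol = protocol_config(),
                                 obs = observer_params(),
                                 walk = walk_params(),
                                 base_cfg = trial_config()) {
  records <- list()
  i <- 0L
  for (contrast in protocol$contrasts) {
    for (pursuit in protocol$pursuits) {
      for (rep in seq_len(protocol$repetitions)) {
        i <- i + 1L
        cfg <- trial_config(duration = base_cfg$duration,
                            sample_rate = base_cfg$sample_rate,
                            contrast = contrast, pursuit = pursuit,
                            field_halfwidth_x = base_cfg$field_halfwidth_x,
                            field_halfwidth_y = base_cfg$field_halfwidth_y)
        traj <- generate_trajectory(cfg, walk)
        records[[i]] <- simulate_gaze(traj, spec, obs, participant_id,
                                      sprintf("%s_%s_%s_r%02d", spec$kind,
                                              contrast, pursuit, rep))
      }
    }
  }
  records
}

#' Simulate a cohort across defect conditions
#'
#' Generates a fully labelled synthetic cohort: each participant receives
#' individual observer parameters drawn once from truncated normal
#' population distributions, then performs the full protocol under each
#' requested defect condition (the default 24 trials per condition).
#'
#' @param n_participants Number of participants.
#' @param conditions Character vector of scotoma kinds (default all four).
#' @param protocol A [protocol_config()].
#' @param base_obs Population-mean observer parameters.
#' @param sd_frac Population SD of each observer parameter as a fraction of
#'   its mean (default 0.1).
#' @param walk,base_cfg Stimulus settings shared by all trials.
#' @param seed Integer seed making the whole cohort reproducible.
#' @return An object of class `cohort`: list with `records` (flat list of
#'   `tracking_record`s), `manifest` (data.frame) and `seed`.
#' @export
simulate_cohort <- function(n_participants,
                            conditions = scotoma_kinds(),
                            protocol = protocol_config(),
                            base_obs = observer_params(), sd_frac = 0.1,
                            walk = walk_params(), base_cfg = trial_config(),
                            seed = 1L) {
  stopifnot(n_participants >= 1, all(conditions %in% scotoma_kinds()))
  set.seed(seed)
  records <- list()
  rows <- list()
  for (p in seq_len(n_participants)) {
    pid <- sprintf("p%02d", p)
    obs <- .draw_participant_params(base_obs, sd_frac)
    for (cond in conditions) {
      recs <- simulate_participant(pid, scotoma_spec(cond), protocol, obs,
                                   walk, base_cfg)
      for (r in recs) {
        records[[length(records) + 1L]] <- r
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, condition = cond, trial_id = r$trial_id,
          contrast = r$config$contrast, pursuit = r$config$pursuit,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$index <- seq_len(nrow(manifest))
  structure(list(records = records, manifest = manifest, seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants, %d records (%s)\n",
              length(unique(x$manifest$participant_id)), length(x$records),
              paste(unique(x$manifest$condition), collapse = ", ")))
  invisible(x)
}

#' Select records from a cohort
#'
#' @param cohort A [simulate_cohort()] result.
#' @param participants,conditions Optional filters.
#' @return List of `tracking_record`s.
#' @export
cohort_records <- function(cohort, participants = NULL, conditions = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  keep <- rep(TRUE, nrow(cohort$manifest))
  if (!is.null(participants)) {
    keep <- keep & cohort$manifest$participant_id %in% participants
  }
  if (!is.null(conditions)) {
    keep <- keep & cohort$manifest$condition %in% conditions
  }
  cohort$records[cohort$manifest$index[keep]]
}
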