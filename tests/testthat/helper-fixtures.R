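# Build a tracking record directly from traces (bypasses the simulator).
new_record <- function(s_x, s_y, p_x, p_y, spec = scotoma_spec("none"),
                       sample_rate = 240, participant_id = "px",
                       trial_id = "tx", contrast = "high",
                       pursuit = "smooth") {
  cfg <- trial_config(duration = length(s_x) / sample_rate,
                      sample_rate = sample_rate, contrast = contrast,
                      pursuit = pursuit)
  rec <- structure(list(config = cfg, scotoma = spec,
                        s_x = s_x, s_y = s_y, p_x = p_x, p_y = p_y,
                        occluded = integer(length(s_x)),
                        participant_id = participant_id,
                        trial_id = trial_id),
                   class = "tracking_record")
  rec$occluded <- ground_truth_labels(rec)
  rec
}

# Wrap a plain numeric vector as a TFCE series (for binarize / norms tests).
mk_tfce_series <- function(values, dt = 1 / 240, kind = "none", pid = "px") {
  structure(list(values = values, params = tfce_params(),
                 h0 = min(values), h_max = max(values), dt = dt,
                 provenance = list(participant_id = pid, trial_id = "t",
                                   scotoma_kind = kind)),
            class = "tfce_series")
}

# Independent brute-force TFCE oracle: per height level, label contiguous
# supra-threshold runs with rle() and accumulate per-sample terms.
tfce_oracle <- function(d, E = 2, H = 0.5, n_steps = 50, unit = 1) {
  h0 <- min(d)
  hm <- max(d)
  out <- numeric(length(d))
  if (hm <= h0) return(out)
  dh <- (hm - h0) / n_steps
  for (k in seq_len(n_steps)) {
    h <- h0 + k * dh
    r <- rle(d >= h)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      e <- r$lengths[j] * unit
      out[starts[j]:ends[j]] <- out[starts[j]:ends[j]] + e^E * h^H * dh
    }
  }
  out
}

# A quick low-cost simulated record.
quick_record <- function(spec = scotoma_spec("none"), seed = 1,
                         pursuit = "smooth", duration = 20,
                         obs = observer_params(), contrast = "high") {
  set.seed(seed)
  cfg <- trial_config(duration = duration, pursuit = pursuit,
                      contrast = contrast)
  simulate_gaze(generate_trajectory(cfg), spec, obs)
}
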