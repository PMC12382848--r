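# Shared fixture builders: everything is generated in code at test time.

# A small zero-noise calcein simulation with known events.
small_calcein_sim <- function(seed = 3, n_mito = 5, n_event = 4,
                              drop = 0.6, noise_sd = 0, field_px = 160) {
  cfg <- sim_config(seed = seed, noise_sd = noise_sd, field_px = field_px)
  ev <- rep(NA_integer_, n_mito)
  dr <- rep(NA_real_, n_mito)
  if (n_event > 0) {
    ev[seq_len(n_event)] <- 4L + (seq_len(n_event) %% 7L)
    dr[seq_len(n_event)] <- drop
  }
  sim <- gen_calcein_timelapse(cfg, n_mito,
                               data.frame(event_frame = ev, drop_fraction = dr),
                               diameter_um = 1.5)
  sim$cfg <- cfg
  sim
}

# Detect particles on the first frame and build a blank window.
detect_with_blank <- function(bundle, rel_threshold = 0.3) {
  f1 <- bundle$frames[[1]]
  rois <- detect_particles(f1, bundle$pixel_size_um,
                           threshold = rel_threshold * max(f1))
  occupied <- unlist(lapply(rois, function(r) {
    roi_window(r$centroid["x"], r$centroid["y"], 10L, r$dim,
               bundle$pixel_size_um)$pixels
  }))
  blank <- mitoquant:::find_blank_window(dim(f1), occupied, 6L,
                                         bundle$pixel_size_um)
  list(rois = rois, blank = blank)
}

# Independent brute-force MPT oracle: literal scan over every consecutive
# frame pair, written without reference to the caller's internals.
brute_force_mpt <- function(values, threshold = 0.20) {
  flagged <- FALSE
  first <- NULL
  for (i in seq_len(length(values) - 1)) {
    if (values[i] - values[i + 1] > threshold * values[1]) {
      if (!flagged) first <- c(i, i + 1)
      flagged <- TRUE
    }
  }
  list(flagged = flagged, first = first)
}

# Random plausible calcein-like traces: positive start, drifting, with
# occasional abrupt drops.
random_trace <- function(n = 11) {
  v <- numeric(n)
  v[1] <- stats::runif(1, 50, 200)
  for (i in 2:n) {
    step <- stats::rnorm(1, 0, 0.05 * v[1])
    if (stats::runif(1) < 0.15) step <- step - stats::runif(1, 0.1, 0.6) * v[1]
    v[i] <- max(v[i - 1] + step, 1)
  }
  v
}
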