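# Shared fixture builders. Everything is generated in code; no binary
# fixtures.

# A minimal valid recording: deterministic smooth trajectories for an
# arbitrary marker set.
toy_recording <- function(n_frames = 100, markers = c("m1", "m2"),
                          rate = 120, seed = 1) {
  nm <- length(markers)
  pos <- array(0, c(n_frames, nm, 3))
  t <- (seq_len(n_frames) - 1) / rate
  withr::with_seed(seed, {
    for (m in seq_len(nm)) for (a in 1:3) {
      f <- runif(1, 0.5, 3)
      pos[, m, a] <- 100 * m + 50 * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
    }
  })
  marker_recording(pos, markers, rate)
}

# A full 23-marker recording compatible with the default joint map,
# via the synthetic generator (no target coupling unless asked).
toy_marker_recording <- function(duration = 2, rate = 60, seed = 5,
                                 spec_args = list()) {
  spec <- do.call(synthetic_cohort_spec,
                  utils::modifyList(list(n_dancers = 1, n_stimuli = 1,
                                         duration = duration,
                                         sampling_rate = rate, seed = seed),
                                    spec_args))
  synthesize_recording(sample_cohort_labels(spec)[1, ], spec, 1)
}

# Local-frame joint recording built directly (bypasses marker stage) for
# filter-level tests. `signals` is frames x joints x 3.
toy_joint_recording <- function(signals, rate = 120,
                                labels = paste0("j", seq_len(dim(signals)[2]))) {
  joint_recording(signals, labels, rate, "position", "local")
}

# Small synthetic cohort spec used by recovery-style tests: short, fast,
# still at a 60 Hz rate compatible with the default Butterworth cutoff.
small_cohort_spec <- function(...) {
  do.call(synthetic_cohort_spec,
          utils::modifyList(list(n_dancers = 24, n_stimuli = 2, duration = 10,
                                 sampling_rate = 60, seed = 1), list(...)))
}
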