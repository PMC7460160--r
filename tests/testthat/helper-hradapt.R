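# shared builders for the test suite

# window pre-filled with the given raw bpm values (default scaling)
filled_window <- function(bpms, cfg = scale_config()) {
  Reduce(function(w, b) push_sample(w, b, cfg), bpms, init = scaled_window())
}

# a small deterministic participant
quiet_participant <- function(seed = 1L, ...) {
  sim_participant(age = 6, resting_hr = 80, noise_sd = 0, seed = seed, ...)
}

# short protocol so session-level tests stay fast
short_protocol <- function(play = 90) {
  protocol_config(play_duration_s = play, rest_duration_s = 60)
}

expect_within <- function(actual, reference, tol) {
  expect_true(abs(actual - reference) <= tol,
              label = sprintf("|%.4f - %.4f| <= %.3f", actual, reference,
                              tol))
}
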