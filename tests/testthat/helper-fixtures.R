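# Shared in-code fixtures: everything is generated, nothing read from disk.

# identity correspondence: each activity its own state
identity_corr <- function(n = 3L) {
  labs <- paste0("A", seq_len(n))
  sts <- paste0("M", seq_len(n))
  correspondence(activity_set(labs), motion_state_set(sts), cbind(labs, sts))
}

# one singleton group + one multi-activity group
mixed_corr <- function() {
  A <- activity_set(c("solo", "x", "y"))
  M <- motion_state_set(c("alone", "shared"))
  correspondence(A, M, cbind(c("solo", "x", "y"), c("alone", "shared", "shared")))
}

# regular sample grid stream with deterministic channel values
grid_stream <- function(duration = 15, fs = 90, value = NULL) {
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  ch <- if (is.null(value)) matrix(seq_len(n * 6) / 100, n, 6)
        else matrix(value, n, 6)
  sensor_stream(tt, ch, fs = fs)
}

# tiny quick training configuration for structural tests
quick_cfg <- function(...) {
  train_config("ci", epochs_motion = 5L, epochs_image = 10L,
               hidden_motion = 8L, hidden_seq = 8L, fc_seq = 8L,
               n_steps = 10L, ...)
}
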