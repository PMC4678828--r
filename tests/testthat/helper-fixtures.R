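# Shared fixtures: small schemes and helpers used across test files.

fig8 <- function() scheme_preset("fig8_12mer")

# slow scheme whose dwells comfortably exceed the frame time, for
# classifier oracles
slow_scheme <- function() {
  kinetic_scheme(kon1 = 0.02, koff1 = 0.25, kon2 = 0.015,
                 koff_pair = 0.12, kon4 = 0.004, koff4 = 0.15)
}

quiet_phys <- function(...) {
  photophysics(noise_sigma = 0, donor_bleach = 0, acceptor_bleach = 0, ...)
}

# snap a state path's transition times to the frame grid so that every
# frame is occupied by exactly one state; isolates threshold logic from
# frame-averaging in exact-equality oracles
snap_path <- function(path, frame_time) {
  # every dwell becomes a whole (>= 1) number of frames, preserving the
  # state sequence exactly
  n_frames <- pmax(1, round((path$t_end - path$t_start) / frame_time))
  t1 <- cumsum(n_frames) * frame_time
  t0 <- c(0, head(t1, -1))
  out <- tibble::tibble(state = path$state, t_start = t0, t_end = t1)
  structure(out, class = c("state_path", class(out)),
            concentration = attr(path, "concentration"),
            duration = max(out$t_end), seed = attr(path, "seed"))
}

# hand-built state path from (state, dwell) pairs
path_from_dwells <- function(states, dwells, concentration = 10) {
  t1 <- cumsum(dwells)
  t0 <- c(0, head(t1, -1))
  structure(tibble::tibble(state = states, t_start = t0, t_end = t1),
            class = c("state_path", "tbl_df", "tbl", "data.frame"),
            concentration = concentration, duration = max(t1), seed = NULL)
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
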