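# shared fixtures: small, fast synthetic sessions

# noise-free simulation parameters (deterministic apart from ITI draws and
# amplitude jitter, which individual tests switch off via amplitude_jitter_sd)
quiet_params <- function(...) {
  args <- list(noise_sd = 0, motion_rate = 0, spont_rate = 0,
               amplitude_jitter_sd = 0)
  user <- list(...)
  args[names(user)] <- user
  do.call(sim_params, args)
}

# two-ear track in cm from per-frame ear coordinates
tiny_ears <- function(lx, ly, rx, ry) {
  coords <- data.frame(ear_left_x = lx, ear_left_y = ly, ear_left_likelihood = 0.99,
                       ear_right_x = rx, ear_right_y = ry, ear_right_likelihood = 0.99)
  structure(list(coords = coords, fps = 10, bodyparts = c("ear_left", "ear_right"),
                 landmarks = character(0), landmark_spacing = NA,
                 view = "above", units = "cm"),
            class = "pose_track")
}

small_events <- function(n = 5, seed = 42) {
  make_event_schedule(n, duration = 5, iti_min = 10, iti_max = 15, seed = seed)
}

# a hand-built pose track: one body part plus two landmarks 100 px apart
tiny_track <- function(x, y = rep(0, length(x)), likelihood = rep(0.99, length(x)),
                       fps = 10) {
  n <- length(x)
  coords <- data.frame(
    nose_x = x, nose_y = y, nose_likelihood = likelihood,
    chamber_leg_1_x = rep(0, n), chamber_leg_1_y = rep(0, n),
    chamber_leg_1_likelihood = rep(0.999, n),
    chamber_leg_2_x = rep(100, n), chamber_leg_2_y = rep(0, n),
    chamber_leg_2_likelihood = rep(0.999, n))
  structure(list(coords = coords, fps = fps, bodyparts = "nose",
                 landmarks = c("chamber_leg_1", "chamber_leg_2"),
                 landmark_spacing = 10, view = "below", units = "px"),
            class = "pose_track")
}

# measured amplitude of a filtered unit sinusoid, middle third of the trace
measure_gain <- function(f, fs, dur = 400, ...) {
  t <- seq(0, dur, by = 1 / fs)
  y <- bandpass_filter(sin(2 * pi * f * t), fs, ...)
  mid <- (length(y) %/% 3):(2 * length(y) %/% 3)
  max(abs(y[mid]))
}
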