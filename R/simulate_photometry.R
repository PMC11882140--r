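#' Parameters of the phenomenological photometry signal model
#'
#' Collects the knobs of the two-channel fluorescence simulator.  The model
#' is phenomenological: a slowly photobleaching baseline, infusion-locked
#' dopamine transients with a double-exponential kernel in the 465 nm
#' channel only, motion artifacts shared between channels (the premise of
#' isosbestic correction), and independent Gaussian sensor noise.
#'
#' @param sampling_rate Sampling rate in Hz of the demodulated traces
#'   (default 40).
#' @param baseline_level Baseline fluorescence of the 465 nm channel, in
#'   arbitrary demodulated units (default 100).
#' @param bleach_time_constant Photobleaching time constant in seconds
#'   (default 1500; slow decay over a ~30 min session).
#' @param transient_amplitude Peak amplitude of a full appetitive dopamine
#'   transient, same units as `baseline_level` (default 6, i.e. ~6% dF/F).
#' @param transient_rise,transient_decay Rise and decay time constants of
#'   the double-exponential transient kernel, in seconds (defaults 0.5 and
#'   2, matching slow GRAB/GCaMP kinetics).
#' @param suppression_factor Dimensionless scaling of the transient
#'   amplitude in `[-1, 1]`: 1 = full appetitive response, 0 = no response,
#'   negative values = suppression below baseline (the conditioned-aversion
#'   signature).
#' @param amplitude_jitter_sd SD of the lognormal per-trial amplitude
#'   jitter (on the log scale, default 0.35) so trial distributions overlap.
#' @param spont_rate Rate of spontaneous (non-infusion-locked) dopamine
#'   transients in events per minute, 465 nm channel only (default 6).
#'   These overlap infusion windows at random and are what makes
#'   trial-level statistics overlap between conditions, as in real
#'   recordings.
#' @param spont_amplitude Peak amplitude of spontaneous transients
#'   (default 4).
#' @param motion_rate Rate of motion artifacts in events per minute
#'   (default 2).
#' @param motion_amplitude Typical artifact amplitude (default 3).
#' @param motion_decay Artifact decay time constant in seconds (default 0.3).
#' @param motion_gain_control Gain with which artifacts appear in the 405 nm
#'   channel relative to the 465 nm channel.  Motion perturbs the optical
#'   coupling, so artifacts scale with each channel's collected
#'   fluorescence — the same ratio as the bleaching baseline — which is
#'   what makes them removable by the affine control fit; the default
#'   therefore equals `control_gain` (0.6).
#' @param control_offset,control_gain Affine map relating the 405 nm
#'   channel's bleaching component to the 465 nm one (defaults 20 and 0.6).
#' @param noise_sd SD of the independent white noise in each channel
#'   (default 0.3).
#' @param seed Optional integer seed used by [simulate_photometry_session()].
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(sampling_rate = 40, baseline_level = 100,
                       bleach_time_constant = 1500,
                       transient_amplitude = 6,
                       transient_rise = 0.5, transient_decay = 2,
                       suppression_factor = 1, amplitude_jitter_sd = 0.35,
                       spont_rate = 6, spont_amplitude = 4,
                       motion_rate = 2, motion_amplitude = 3,
                       motion_decay = 0.3, motion_gain_control = 0.6,
                       control_offset = 20, control_gain = 0.6,
                       noise_sd = 0.3, seed = NULL) {
  p <- list(sampling_rate = sampling_rate, baseline_level = baseline_level,
            bleach_time_constant = bleach_time_constant,
            transient_amplitude = transient_amplitude,
            transient_rise = transient_rise, transient_decay = transient_decay,
            suppression_factor = suppression_factor,
            amplitude_jitter_sd = amplitude_jitter_sd,
            spont_rate = spont_rate, spont_amplitude = spont_amplitude,
            motion_rate = motion_rate, motion_amplitude = motion_amplitude,
            motion_decay = motion_decay,
            motion_gain_control = motion_gain_control,
            control_offset = control_offset, control_gain = control_gain,
            noise_sd = noise_sd, seed = seed)
  check_number(p$sampling_rate, "sampling_rate", lower = 0, allow_equal_lower = FALSE)
  check_number(p$bleach_time_constant, "bleach_time_constant", lower = 0,
               allow_equal_lower = FALSE)
  check_number(p$noise_sd, "noise_sd", lower = 0)
  check_number(p$suppression_factor, "suppression_factor", lower = -1, upper = 1)
  check_number(p$motion_rate, "motion_rate", lower = 0)
  check_number(p$spont_rate, "spont_rate", lower = 0)
  check_number(p$transient_rise, "transient_rise", lower = 0, allow_equal_lower = FALSE)
  check_number(p$transient_decay, "transient_decay", lower = 0, allow_equal_lower = FALSE)
  if (p$transient_decay <= p$transient_rise)
    stop_invalid("transient_decay must exceed transient_rise")
  structure(p, class = "sim_params")
}

## double-exponential transient kernel, peak-normalized to 1
transient_kernel <- function(t, rise, decay) {
  k <- exp(-t / decay) - exp(-t / rise)
  k[t < 0] <- 0
  tp <- log(decay / rise) * rise * decay / (decay - rise)
  k / (exp(-tp / decay) - exp(-tp / rise))
}

#' Construct a raw two-channel photometry session
#'
#' Bundles demodulated traces, the event log and session metadata into the
#' container the preprocessing chain consumes.
#'
#' @param time Time vector in seconds, uniformly sampled.
#' @param f465 Signal-dependent (465 nm) fluorescence.
#' @param f405 Control (405 nm, isosbestic) fluorescence.
#' @param sampling_rate Sampling rate in Hz; must match `time`.
#' @param events An `event_log` (see [make_event_schedule()]).
#' @param metadata Named list; conventional entries are `rat`, `group`
#'   (`"Paired"`/`"Unpaired"`), `day` (`"CD"`, `"TD"`, `"C1"`..., `"E1"`...),
#'   `sensor` and `region`.
#' @return A list of class `photometry_session`.
#' @export
photometry_session <- function(time, f465, f405, sampling_rate, events,
                               metadata = list()) {
  if (length(time) != length(f465) || length(time) != length(f405))
    stop_invalid("time, f465 and f405 must have equal length")
  if (length(time) > 1) {
    dt <- diff(time)
    if (max(abs(dt - 1 / sampling_rate)) > 1e-6 / sampling_rate)
      stop_invalid("time vector is not uniform at the stated sampling_rate")
  }
  events <- validate_event_log(events)
  if (any(events$onset < time[1] | events$onset + events$duration > time[length(time)]))
    stop_invalid("event onsets must lie within the recording")
  structure(list(time = time, f465 = f465, f405 = f405,
                 sampling_rate = sampling_rate, events = events,
                 metadata = metadata),
            class = "photometry_session")
}

#' @export
print.photometry_session <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<photometry_session> %.1f s at %g Hz, %d trials%s\n",
              x$time[length(x$time)] - x$time[1], x$sampling_rate,
              nrow(x$events),
              if (length(md)) paste0(" [", paste(unlist(md), collapse = " "), "]") else ""))
  invisible(x)
}

#' Simulate a two-channel photometry session
#'
#' Generates demodulated 465/405 nm traces for one infusion session.  The
#' 465 nm channel is `baseline * exp(-t/tau)` plus infusion-locked
#' double-exponential transients (amplitude `transient_amplitude *
#' suppression_factor` with lognormal per-trial jitter), motion artifacts
#' and white noise.  The 405 nm channel is an affine function of the same
#' bleaching baseline plus the same motion artifacts (scaled by
#' `motion_gain_control`) and independent noise, with no transients — so an
#' affine control fit can remove bleaching and motion but not the signal.
#'
#' @param events An `event_log` from [make_event_schedule()].
#' @param params A [sim_params()] object.
#' @param metadata Session metadata passed to [photometry_session()].
#' @param tail Seconds of recording after the last infusion offset
#'   (default 20, so post-event windows fit).
#' @return A list with elements `session` (a `photometry_session`) and
#'   `truth` (ground truth: per-trial true transient amplitudes, motion
#'   artifact times, and the suppression factor used).
#' @examples
#' ev <- make_event_schedule(5, seed = 1)
#' sim <- simulate_photometry_session(ev, sim_params(noise_sd = 0, motion_rate = 0))
#' @export
simulate_photometry_session <- function(events, params = sim_params(),
                                        metadata = list(), tail = 20) {
  events <- validate_event_log(events)
  if (!inherits(params, "sim_params")) stop_invalid("params must be a sim_params object")
  if (!is.null(params$seed)) set.seed(params$seed)
  fs <- params$sampling_rate
  t_end <- max(events$onset + events$duration) + tail
  time <- seq(0, t_end, by = 1 / fs)
  n <- length(time)

  bleach <- params$baseline_level * exp(-time / params$bleach_time_constant)
  ## transients ride on the surviving fluorophore pool: a fixed fractional
  ## (dF/F) response shrinks in raw units as the sensor bleaches
  bleach_frac <- function(t0) exp(-t0 / params$bleach_time_constant)

  amp <- params$transient_amplitude * params$suppression_factor *
    exp(rnorm(nrow(events), 0, params$amplitude_jitter_sd))
  transients <- numeric(n)
  for (i in seq_len(nrow(events))) {
    rel <- time - events$onset[i]
    idx <- which(rel >= 0 & rel < 6 * params$transient_decay + events$duration[i])
    transients[idx] <- transients[idx] +
      amp[i] * bleach_frac(events$onset[i]) *
      transient_kernel(rel[idx], params$transient_rise, params$transient_decay)
  }

  ## spontaneous transients: same kernel, 465 nm only, not event-locked
  n_spont <- rpois(1, params$spont_rate * t_end / 60)
  spont_times <- sort(runif(n_spont, 0, t_end))
  if (n_spont > 0) {
    spont_amp <- params$spont_amplitude * exp(rnorm(n_spont, 0, params$amplitude_jitter_sd))
    for (i in seq_len(n_spont)) {
      rel <- time - spont_times[i]
      idx <- which(rel >= 0 & rel < 6 * params$transient_decay)
      transients[idx] <- transients[idx] +
        spont_amp[i] * bleach_frac(spont_times[i]) *
        transient_kernel(rel[idx], params$transient_rise,
                         params$transient_decay)
    }
  }

  n_motion <- rpois(1, params$motion_rate * t_end / 60)
  motion_times <- sort(runif(n_motion, 0, t_end))
  motion <- numeric(n)
  if (n_motion > 0) {
    signs <- sample(c(-1, 1), n_motion, replace = TRUE)
    sizes <- params$motion_amplitude * runif(n_motion, 0.5, 1.5)
    for (i in seq_len(n_motion)) {
      rel <- time - motion_times[i]
      idx <- which(rel >= 0 & rel < 6 * params$motion_decay)
      motion[idx] <- motion[idx] + signs[i] * sizes[i] * exp(-rel[idx] / params$motion_decay)
    }
  }

  f465 <- bleach + transients + motion + rnorm(n, 0, params$noise_sd)
  f405 <- params$control_offset + params$control_gain * bleach +
    params$motion_gain_control * motion + rnorm(n, 0, params$noise_sd)

  list(session = photometry_session(time, f465, f405, fs, events, metadata),
       truth = list(amplitudes = amp, motion_times = motion_times,
                    spont_times = spont_times,
                    suppression_factor = params$suppression_factor))
}
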