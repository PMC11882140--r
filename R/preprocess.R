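#' Fit the isosbestic control channel and subtract it
#'
#' Maps the 405 nm control channel onto the 465 nm signal channel by an
#' affine fit over the full session, then forms
#' `dF/F = (f465 - fit(f405)) / fit(f405)`.  Bleaching and motion artifacts
#' appear in both channels, so the fitted control removes them while the
#' sensor-dependent transients survive.
#'
#' @param session A `photometry_session`.
#' @param method `"ols"` (ordinary least squares, default) or `"robust"`
#'   (iterated reweighting via Tukey bisquare; resists large transients).
#' @return A list of class `processed_trace` at the subtracted stage:
#'   elements `time`, `subtracted` (dF/F), `control_fit_coefficients`
#'   (intercept, slope), `sampling_rate`, `events`, `metadata`.
#' @examples
#' ev <- make_event_schedule(3, seed = 1)
#' s <- simulate_photometry_session(ev, sim_params(noise_sd = 0, motion_rate = 0,
#'                                                 suppression_factor = 0))$session
#' ft <- fit_and_subtract_control(s)
#' max(abs(ft$subtracted))   # ~0: channels are exactly affine-related
#' @export
fit_and_subtract_control <- function(session, method = c("ols", "robust")) {
  method <- match.arg(method)
  if (!inherits(session, "photometry_session"))
    stop_invalid("session must be a photometry_session")
  if (session$time[length(session$time)] - session$time[1] <= 10)
    stop_invalid("session must be longer than 10 s")
  if (!all(is.finite(session$f465)) || !all(is.finite(session$f405)))
    stop_invalid("both channels must be finite")
  if (var(session$f405) == 0)
    stop_invalid("control channel has zero variance; affine fit is degenerate")

  if (method == "ols") {
    fit <- lm(session$f465 ~ session$f405)
    cf <- unname(coef(fit))
  } else {
    cf <- tukey_affine_fit(session$f405, session$f465)
  }
  fitted <- cf[1] + cf[2] * session$f405
  if (any(fitted <= 0))
    stop_invalid("fitted control crosses zero; dF/F undefined")
  out <- list(time = session$time,
              subtracted = (session$f465 - fitted) / fitted,
              control_fit_coefficients = c(intercept = cf[1], slope = cf[2]),
              sampling_rate = session$sampling_rate,
              events = session$events, metadata = session$metadata)
  class(out) <- "processed_trace"
  out
}

## iteratively reweighted affine fit with Tukey bisquare weights
tukey_affine_fit <- function(x, y, iter = 20, c_tune = 4.685) {
  w <- rep(1, length(x))
  cf <- c(0, 0)
  for (i in seq_len(iter)) {
    fit <- lm(y ~ x, weights = w)
    new_cf <- unname(coef(fit))
    r <- y - (new_cf[1] + new_cf[2] * x)
    s <- median(abs(r)) / 0.6745
    if (s == 0) { cf <- new_cf; break }
    u <- r / (c_tune * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (max(abs(new_cf - cf)) < 1e-10 * max(1, abs(cf[2]))) { cf <- new_cf; break }
    cf <- new_cf
  }
  cf
}

## ---- Butterworth bandpass as a biquad cascade -------------------------------
##
## The bandpass is designed in zero-pole-gain form (analog Butterworth
## prototype -> lowpass-to-bandpass transform -> bilinear transform) and
## factored into second-order sections.  A direct transfer-function
## realization of a 10-pole bandpass with a 0.05 Hz corner is numerically
## unstable at usual sampling rates; the cascade is not.
butter_bandpass_sos <- function(order, low, high, fs) {
  n <- order
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))   # unit-circle LHP poles
  wl <- 2 * fs * tan(pi * low / fs)                    # prewarped edges
  wh <- 2 * fs * tan(pi * high / fs)
  bw <- wh - wl
  w0 <- sqrt(wl * wh)
  pb <- proto * bw / 2
  disc <- sqrt(pb^2 - w0^2)
  poles <- c(pb + disc, pb - disc)                     # 2n analog poles
  zp <- (2 * fs + poles) / (2 * fs - poles)            # bilinear
  tol <- 1e-9
  cpx <- zp[Im(zp) > tol]
  re <- sort(Re(zp[abs(Im(zp)) <= tol]))
  sos <- matrix(0, n, 6,
                dimnames = list(NULL, c("b0", "b1", "b2", "a0", "a1", "a2")))
  i <- 0
  for (pp in cpx) {                                    # conjugate-pair biquads
    i <- i + 1
    sos[i, ] <- c(1, 0, -1, 1, -2 * Re(pp), Mod(pp)^2)
  }
  if (length(re)) {                                    # real poles pair up
    for (j in seq(1, length(re), by = 2)) {
      i <- i + 1
      sos[i, ] <- c(1, 0, -1, 1, -(re[j] + re[j + 1]), re[j] * re[j + 1])
    }
  }
  ## unity gain at the (warped) center frequency
  f0 <- fs / pi * atan(w0 / (2 * fs))
  zc <- exp(2i * pi * f0 / fs)
  h <- prod((zc^2 - 1) / (zc^2 + sos[, "a1"] * zc + sos[, "a2"]))
  sos[1, 1:3] <- sos[1, 1:3] / Mod(h)
  sos
}

## each biquad is started from its steady state for the first input sample,
## so a constant trace maps exactly to its DC gain (zero for a bandpass)
## instead of exciting a slow start-up transient at the 0.05 Hz corner
apply_sos <- function(sos, x) {
  for (i in seq_len(nrow(sos))) {
    b <- sos[i, 1:3]; a <- sos[i, 4:6]
    g <- sum(b) / sum(a)                 # DC gain of the section
    x <- as.numeric(signal::filter(b, a, x,
                                   init.x = rep(x[1], 2),
                                   init.y = rep(g * x[1], 2)))
  }
  x
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies the study's smoothing filter: a fifth-order Butterworth bandpass
#' with cutoffs 0.05 and 2.25 Hz, run forward and backward so the result is
#' zero-phase (event-aligned timing is preserved; the effective magnitude
#' response is the squared single-pass response).  Edges are padded by odd
#' reflection before filtering.
#'
#' @param trace Numeric time series.
#' @param sampling_rate Sampling rate in Hz.
#' @param order Filter order of the single pass (default 5).
#' @param low,high Cutoff frequencies in Hz (defaults 0.05 and 2.25).
#' @param zero_phase Forward-backward if `TRUE` (default); a single causal
#'   forward pass if `FALSE`.
#' @return Filtered series, same length as the input.
#' @export
bandpass_filter <- function(trace, sampling_rate, order = 5,
                            low = 0.05, high = 2.25, zero_phase = TRUE) {
  check_number(sampling_rate, "sampling_rate", lower = 0, allow_equal_lower = FALSE)
  check_number(order, "order", lower = 1)
  if (!(low > 0 && low < high && high < sampling_rate / 2))
    stop_invalid("cutoffs must satisfy 0 < low < high < Nyquist (%g Hz)",
                 sampling_rate / 2)
  n <- length(trace)
  if (n < 8) stop_invalid("trace too short to filter")
  sos <- butter_bandpass_sos(order, low, high, sampling_rate)
  np <- min(30 * nrow(sos), n - 1)
  padded <- c(2 * trace[1] - trace[(np + 1):2], trace,
              2 * trace[n] - trace[(n - 1):(n - np)])
  y <- apply_sos(sos, padded)
  if (zero_phase) y <- rev(apply_sos(sos, rev(y)))
  y[(np + 1):(np + n)]
}

## analytic two-pass magnitude response of the digital design (used by the
## test-suite oracle and exposed for diagnostics): prewarped analog
## bandpass-Butterworth power response; squared again for the second pass.
#' Analytic magnitude response of the zero-phase bandpass
#'
#' Closed-form gain of [bandpass_filter()] at frequency `f`, from the
#' prewarped analog Butterworth bandpass power response (squared once more
#' for the backward pass).
#' @param f Frequency in Hz (vectorized).
#' @inheritParams bandpass_filter
#' @return Amplitude gain(s) in `[0, 1]`.
#' @export
bandpass_gain <- function(f, sampling_rate, order = 5, low = 0.05, high = 2.25) {
  w <- 2 * sampling_rate * tan(pi * f / sampling_rate)
  wl <- 2 * sampling_rate * tan(pi * low / sampling_rate)
  wh <- 2 * sampling_rate * tan(pi * high / sampling_rate)
  bw <- wh - wl
  w0 <- sqrt(wl * wh)
  1 / (1 + ((w^2 - w0^2) / (w * bw))^(2 * order))
}

#' Session z-score normalization
#'
#' Standardizes a trace by the whole-recording mean and population SD
#' (n denominator), the session-level normalization applied before trial
#' alignment.
#'
#' @param trace Numeric series with at least 2 samples and non-zero variance.
#' @return List with `z` (the standardized trace), `session_mean` and
#'   `session_sd`.
#' @export
zscore_normalize <- function(trace) {
  if (length(trace) < 2) stop_invalid("trace must have at least 2 samples")
  s <- pop_sd(trace)
  if (s == 0) stop_invalid("trace has zero variance; z-score undefined")
  m <- mean(trace)
  list(z = (trace - m) / s, session_mean = m, session_sd = s)
}

#' Run the full preprocessing chain on a session
#'
#' Control fit and subtraction, zero-phase Butterworth bandpass, and
#' session z-scoring, in that order.
#'
#' @inheritParams fit_and_subtract_control
#' @param order,low,high Bandpass settings (see [bandpass_filter()]).
#' @param zero_phase Passed to [bandpass_filter()].
#' @return A `processed_trace` with `subtracted`, `filtered`, `z`,
#'   `session_mean`, `session_sd` and `control_fit_coefficients`.
#' @export
preprocess_session <- function(session, method = c("ols", "robust"),
                               order = 5, low = 0.05, high = 2.25,
                               zero_phase = TRUE) {
  pt <- fit_and_subtract_control(session, method = method)
  pt$filtered <- bandpass_filter(pt$subtracted, pt$sampling_rate,
                                 order = order, low = low, high = high,
                                 zero_phase = zero_phase)
  zs <- zscore_normalize(pt$filtered)
  pt$z <- zs$z
  pt$session_mean <- zs$session_mean
  pt$session_sd <- zs$session_sd
  pt
}

#' @export
print.processed_trace <- function(x, ...) {
  cat(sprintf("<processed_trace> %d samples at %g Hz; stages: %s\n",
              length(x$subtracted), x$sampling_rate,
              paste(intersect(c("subtracted", "filtered", "z"), names(x)),
                    collapse = " -> ")))
  invisible(x)
}

#' Align the normalized trace to infusion onsets
#'
#' Cuts one row per event from the z-scored trace, spanning `pre` seconds
#' before to `post` seconds after onset.  The onset sample is the nearest
#' sample at or before the event time; windows are half-open.  Trials whose
#' window leaves the recording are dropped with a warning.
#'
#' @param x A `processed_trace` (with a `z` stage) or a numeric trace.
#' @param events An `event_log`; taken from `x` if omitted.
#' @param pre,post Window extent in seconds (defaults 5 and 10).
#' @param sampling_rate,t0 Required when `x` is a bare numeric trace.
#' @return A matrix of class `trial_tensor` (trials x timepoints) with
#'   attributes `rel_time` (seconds relative to onset), `window`,
#'   `trials` (retained trial indices) and `labels` (session metadata).
#' @export
align_trials <- function(x, events = NULL, pre = 5, post = 10,
                         sampling_rate = NULL, t0 = 0) {
  if (inherits(x, "processed_trace")) {
    z <- x$z %||% stop_invalid("processed_trace has no z stage; run preprocess_session()")
    events <- events %||% x$events
    sampling_rate <- x$sampling_rate
    t0 <- x$time[1]
    labels <- x$metadata
  } else {
    z <- as.numeric(x)
    if (is.null(events) || is.null(sampling_rate))
      stop_invalid("events and sampling_rate are required for a bare trace")
    labels <- list()
  }
  events <- validate_event_log(events)
  check_number(pre, "pre", lower = 0)
  check_number(post, "post", lower = 0, allow_equal_lower = FALSE)
  n <- length(z)
  npre <- round(pre * sampling_rate)
  npost <- round(post * sampling_rate)
  width <- npre + npost
  rows <- list()
  kept <- integer(0)
  for (i in seq_len(nrow(events))) {
    onset_idx <- floor((events$onset[i] - t0) * sampling_rate + 1e-9) + 1L
    i0 <- onset_idx - npre
    i1 <- onset_idx + npost - 1L
    if (i0 < 1 || i1 > n) {
      warning(sprintf("trial %d excluded: window [%g, %g] s outside recording",
                      events$trial[i], events$onset[i] - pre,
                      events$onset[i] + post), call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- z[i0:i1]
    kept <- c(kept, events$trial[i])
  }
  if (!length(rows)) stop_invalid("all trials excluded; no alignment window fits")
  tensor <- do.call(rbind, rows)
  structure(tensor,
            rel_time = (seq_len(width) - 1 - npre) / sampling_rate,
            window = c(-pre, post), trials = kept,
            sampling_rate = sampling_rate, labels = labels,
            class = c("trial_tensor", "matrix", "array"))
}

#' Per-trial mean z-score in the infusion window
#'
#' The study's trial statistic: the arithmetic mean of the z-scored signal
#' over the 5-s infusion window `[0, 5)` of each aligned trial; the session
#' value is the mean of the per-trial values.
#'
#' @param tensor A `trial_tensor` from [align_trials()].
#' @param window Two-element window in seconds relative to onset, half-open
#'   (default `c(0, 5)`).
#' @return A data frame of class `trial_stats` with columns `trial` and
#'   `mean_z` (plus `rat`, `group`, `day` when session metadata is
#'   present); the session average is attached as attribute
#'   `session_mean_z`.
#' @export
infusion_mean_zscore <- function(tensor, window = c(0, 5)) {
  if (!inherits(tensor, "trial_tensor")) stop_invalid("tensor must be a trial_tensor")
  rel <- attr(tensor, "rel_time")
  sel <- rel >= window[1] & rel < window[2]
  if (!any(sel)) stop_invalid("window [%g, %g) contains no samples", window[1], window[2])
  vals <- rowMeans(tensor[, sel, drop = FALSE])
  labels <- attr(tensor, "labels")
  out <- data.frame(trial = attr(tensor, "trials"), mean_z = vals)
  for (f in c("rat", "group", "day"))
    if (!is.null(labels[[f]])) out[[f]] <- labels[[f]]
  attr(out, "session_mean_z") <- mean(vals)
  class(out) <- c("trial_stats", "data.frame")
  out
}

#' Session average of the trial statistic
#'
#' @param stats A `trial_stats` table.
#' @return Mean of the per-trial infusion-window z-scores.
#' @export
session_mean_z <- function(stats) mean(stats$mean_z)
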