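pose_xy <- function(track, part) {
  cx <- paste0(part, "_x"); cy <- paste0(part, "_y")
  if (!all(c(cx, cy) %in% names(track$coords)))
    stop_invalid("body part '%s' not present in track", part)
  cbind(x = track$coords[[cx]], y = track$coords[[cy]])
}

#' Likelihood-filter and interpolate a pose track
#'
#' Frames whose tracking likelihood falls below `likelihood_threshold` are
#' treated as missing and replaced by linear interpolation between the
#' nearest flanking high-confidence frames; low-confidence runs at the
#' start or end of the recording are filled with the nearest high-confidence
#' value.  A logical mask records every replaced frame.
#'
#' @param track A `pose_track`.
#' @param likelihood_threshold Minimum retained likelihood (default 0.95).
#' @return The track with interpolated coordinates and an
#'   `interpolated` element: a logical frames x parts matrix of
#'   replacements.
#' @export
clean_pose <- function(track, likelihood_threshold = 0.95) {
  if (!inherits(track, "pose_track")) stop_invalid("track must be a pose_track")
  parts <- c(track$bodyparts, track$landmarks)
  n <- nrow(track$coords)
  mask <- matrix(FALSE, n, length(parts), dimnames = list(NULL, parts))
  for (p in parts) {
    lk <- track$coords[[paste0(p, "_likelihood")]]
    good <- lk >= likelihood_threshold
    if (sum(good) < 2)
      stop_invalid("body part '%s' has fewer than 2 frames above the likelihood threshold", p)
    if (all(good)) next
    idx <- seq_len(n)
    for (ax in c("_x", "_y")) {
      col <- paste0(p, ax)
      track$coords[[col]] <- approx(idx[good], track$coords[[col]][good],
                                    xout = idx, method = "linear", rule = 2)$y
    }
    mask[, p] <- !good
  }
  track$interpolated <- mask
  track$likelihood_threshold <- likelihood_threshold
  track
}

#' Pixel-to-metric calibration from stationary landmarks
#'
#' Estimates the pixel scale as the mean over landmark pairs of
#' (pixel distance / physical distance).  With two landmarks, the single
#' pair is used; with more, consecutive landmarks are treated as the sides
#' of a closed polygon of known side length, unless an explicit `pairs`
#' matrix with per-pair distances is supplied.
#'
#' @param landmarks An n x 2 matrix of landmark pixel coordinates.
#' @param known_spacing Physical distance in cm: a scalar side/pair length,
#'   or a vector of length `nrow(pairs)`.
#' @param pairs Optional 2-column integer matrix of landmark index pairs.
#' @return Scale in pixels per cm.
#' @examples
#' calibrate_scale(rbind(c(0, 0), c(100, 0)), 10)   # 10 px/cm
#' @export
calibrate_scale <- function(landmarks, known_spacing, pairs = NULL) {
  landmarks <- as.matrix(landmarks)
  if (nrow(landmarks) < 2) stop_invalid("need at least 2 landmarks")
  if (is.null(pairs)) {
    n <- nrow(landmarks)
    pairs <- if (n == 2) cbind(1L, 2L) else cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  }
  d_px <- sqrt(rowSums((landmarks[pairs[, 1], , drop = FALSE] -
                          landmarks[pairs[, 2], , drop = FALSE])^2))
  if (any(d_px == 0)) stop_invalid("coincident landmarks; cannot calibrate")
  spacing <- rep_len(known_spacing, nrow(pairs))
  if (any(spacing <= 0)) stop_invalid("known_spacing must be positive")
  mean(d_px / spacing)
}

#' Convert a pose track to metric units
#'
#' Divides all coordinates by the pixel scale.  When `px_per_cm` is not
#' given it is computed with [calibrate_scale()] from the track's own
#' stationary landmarks (their median position over frames) and the known
#' landmark spacing stored in the track.
#'
#' @param track A (cleaned) `pose_track` in pixels.
#' @param px_per_cm Optional pixel scale to use directly.
#' @return The track with coordinates in cm and element `px_per_cm` set.
#' @export
calibrate_track <- function(track, px_per_cm = NULL) {
  if (!inherits(track, "pose_track")) stop_invalid("track must be a pose_track")
  if (identical(track$units, "cm")) return(track)
  if (is.null(px_per_cm)) {
    if (!length(track$landmarks)) stop_invalid("track has no landmarks; supply px_per_cm")
    lm <- t(vapply(track$landmarks,
                   function(p) apply(pose_xy(track, p), 2, median),
                   numeric(2)))
    px_per_cm <- calibrate_scale(lm, track$landmark_spacing)
  }
  check_number(px_per_cm, "px_per_cm", lower = 0, allow_equal_lower = FALSE)
  for (p in c(track$bodyparts, track$landmarks)) for (ax in c("_x", "_y")) {
    col <- paste0(p, ax)
    track$coords[[col]] <- track$coords[[col]] / px_per_cm
  }
  track$px_per_cm <- px_per_cm
  track$units <- "cm"
  track
}

#' Head position as the midpoint between the ears
#'
#' @param track A `pose_track` containing `ear_left` and `ear_right`.
#' @return A two-column matrix (x, y) per frame, in the track's units.
#' @export
head_position <- function(track) {
  have <- c("ear_left", "ear_right") %in%
    sub("_x$", "", grep("_x$", names(track$coords), value = TRUE))
  if (!all(have)) stop_invalid("both ear tracks are required for head position")
  (pose_xy(track, "ear_left") + pose_xy(track, "ear_right")) / 2
}

#' Distance moved within a time window
#'
#' Total path length: the sum of inter-frame Euclidean displacements over
#' the frames whose times fall in the half-open window `[t0, t1)`.
#'
#' @param xy A two-column matrix of per-frame positions (cm).
#' @param fps Frame rate.
#' @param window Two-element window `c(t0, t1)` in seconds from recording
#'   start.
#' @return Path length in the coordinate units.
#' @export
movement_in_window <- function(xy, fps, window) {
  xy <- as.matrix(xy)
  times <- (seq_len(nrow(xy)) - 1) / fps
  sel <- which(times >= window[1] & times < window[2])
  if (length(sel) < 2) stop_invalid("window [%g, %g) contains fewer than 2 frames",
                                    window[1], window[2])
  d <- diff(xy[sel, , drop = FALSE])
  sum(sqrt(rowSums(d^2)))
}

#' Behavioral reactivity to intraoral infusions
#'
#' For each trial, movement (path length, cm) is measured in the 5-s
#' pre-infusion baseline window and the 5-s infusion window; reactivity is
#' their difference (infusion minus baseline).  Aversive taste responses —
#' gapes, headshakes, forelimb flails — raise it.  The composite part
#' `"forepaw"` averages the left and right forepaw reactivities; `"head"`
#' is the midpoint of the ears.
#'
#' @param track A cleaned, calibrated `pose_track` (cm units).
#' @param events An `event_log`.
#' @param bodyparts Parts to score.  Defaults to `c("nose", "forepaw")` for
#'   the below view and `"head"` for the above view.
#' @param baseline,infusion Windows in seconds relative to onset, half-open
#'   (defaults `c(-5, 0)` and `c(0, 5)`).
#' @return A data frame of class `reactivity_table` with one row per trial
#'   and part: `trial`, `bodypart`, `baseline_cm`, `infusion_cm`,
#'   `reactivity_cm`.  Out-of-bounds trials are excluded with a warning.
#'   Session means per part are attached as attribute `session_means`.
#' @export
behavioral_reactivity <- function(track, events, bodyparts = NULL,
                                  baseline = c(-5, 0), infusion = c(0, 5)) {
  if (!identical(track$units, "cm"))
    stop_invalid("track must be calibrated to cm first (calibrate_track)")
  events <- validate_event_log(events)
  if (is.null(bodyparts))
    bodyparts <- if ("ear_left" %in% track$bodyparts) "head" else c("nose", "forepaw")

  part_xy <- function(part) {
    switch(part,
           head = head_position(track),
           forepaw = NULL,    # composite handled below
           pose_xy(track, part))
  }
  t_max <- (nrow(track$coords) - 1) / track$fps
  rows <- list()
  for (i in seq_len(nrow(events))) {
    w_base <- events$onset[i] + baseline
    w_inf <- events$onset[i] + infusion
    if (w_base[1] < 0 || w_inf[2] > t_max) {
      warning(sprintf("trial %d excluded: windows outside recording", events$trial[i]),
              call. = FALSE)
      next
    }
    for (part in bodyparts) {
      if (part == "forepaw") {
        sub <- lapply(c("forepaw_left", "forepaw_right"), function(p) {
          xy <- pose_xy(track, p)
          c(base = movement_in_window(xy, track$fps, w_base),
            inf = movement_in_window(xy, track$fps, w_inf))
        })
        b <- mean(vapply(sub, `[[`, numeric(1), "base"))
        m <- mean(vapply(sub, `[[`, numeric(1), "inf"))
      } else {
        xy <- part_xy(part)
        b <- movement_in_window(xy, track$fps, w_base)
        m <- movement_in_window(xy, track$fps, w_inf)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(trial = events$trial[i], bodypart = part,
                   baseline_cm = b, infusion_cm = m, reactivity_cm = m - b)
    }
  }
  if (!length(rows)) stop_invalid("no trial fits inside the recording")
  out <- do.call(rbind, rows)
  sm <- tapply(out$reactivity_cm, out$bodypart, mean)
  attr(out, "session_means") <- sm
  class(out) <- c("reactivity_table", "data.frame")
  out
}

#' Session-average reactivity
#'
#' @param reactivity A `reactivity_table`.
#' @param bodypart Optional part to select; default averages all rows of
#'   the first part present.
#' @return Mean reactivity (cm) over trials.
#' @export
session_reactivity <- function(reactivity, bodypart = NULL) {
  if (is.null(bodypart)) bodypart <- reactivity$bodypart[1]
  mean(reactivity$reactivity_cm[reactivity$bodypart == bodypart])
}
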