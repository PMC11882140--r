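#' Simulate a pose-tracking session
#'
#' Emulates DeepLabCut output for one infusion session at 10 fps: a rat
#' body following a bounded random walk, with movement bursts during
#' infusion windows whose total extra path length equals `reactivity_gain`
#' per trial, stationary landmarks with known physical spacing, and a
#' configurable fraction of low-likelihood frames whose coordinates are
#' corrupted (tracking dropouts).
#'
#' The below-chamber view tracks nose, forepaws and tail base with chamber
#' legs as landmarks; the above view tracks the ears with chamber corners
#' as landmarks.
#'
#' @param events An `event_log`.
#' @param view `"below"` or `"above"`.
#' @param reactivity_gain Extra path length (cm) added during each infusion
#'   window — the injected behavioral reactivity (default 0).
#' @param dropout_rate Fraction of frames per body part assigned likelihood
#'   below 0.95 with corrupted coordinates, in `[0, 1)` (default 0.05).
#' @param fps Frame rate (default 10).
#' @param px_per_cm True pixel scale of the simulated camera (default 12).
#' @param step_sd Per-axis SD of the baseline random-walk step, cm/frame
#'   (default 0.1).
#' @param arena_half_cm Half-width of the reflecting arena, cm (default 15).
#' @param landmark_spacing Physical side length of the square of landmarks,
#'   cm (default 20).
#' @param seed Optional integer seed.
#' @return A `pose_track`: list with `coords` (data frame of
#'   `<part>_x`, `<part>_y`, `<part>_likelihood` columns, pixels),
#'   `fps`, `bodyparts`, `landmarks`, `landmark_spacing` and `view`.
#' @export
simulate_pose_session <- function(events, view = c("below", "above"),
                                  reactivity_gain = 0, dropout_rate = 0.05,
                                  fps = 10, px_per_cm = 12, step_sd = 0.1,
                                  arena_half_cm = 15, landmark_spacing = 20,
                                  seed = NULL) {
  view <- match.arg(view)
  events <- validate_event_log(events)
  check_number(dropout_rate, "dropout_rate", lower = 0, upper = 1 - 1e-12)
  check_number(reactivity_gain, "reactivity_gain", lower = 0)
  if (!is.null(seed)) set.seed(seed)

  t_end <- max(events$onset + events$duration) + 15
  n <- floor(t_end * fps) + 1L
  times <- (seq_len(n) - 1) / fps

  ## baseline random walk of the body center (cm), reflected at the walls
  steps <- cbind(rnorm(n, 0, step_sd), rnorm(n, 0, step_sd))
  steps[1, ] <- 0
  ## infusion bursts: extra displacement collinear with the baseline step so
  ## path lengths add exactly; gain split evenly over the window's frames
  in_infusion <- rep(FALSE, n)
  for (i in seq_len(nrow(events)))
    in_infusion <- in_infusion |
      (times >= events$onset[i] & times < events$onset[i] + events$duration[i])
  ## boost only steps whose endpoints both lie inside the window, so the
  ## whole injected path length is visible to a [t0, t1) window measurement
  interior <- in_infusion & c(FALSE, in_infusion[-n])
  nf <- sum(times >= events$onset[1] & times < events$onset[1] + events$duration[1]) - 1L
  if (reactivity_gain > 0 && any(interior)) {
    len <- sqrt(rowSums(steps^2))
    len[len == 0] <- 1e-12
    boost <- reactivity_gain / nf
    steps[interior, ] <- steps[interior, ] * (1 + boost / len[interior])
  }
  center <- apply(steps, 2, cumsum)
  ## reflect into [-arena_half_cm, arena_half_cm]
  reflect <- function(x, h) {
    y <- (x + h) %% (4 * h)
    ifelse(y <= 2 * h, y - h, 3 * h - y)
  }
  center <- apply(center, 2, reflect, h = arena_half_cm)

  parts <- switch(view,
                  below = c("nose", "forepaw_left", "forepaw_right", "tail_base"),
                  above = c("ear_left", "ear_right"))
  offsets <- switch(view,
                    below = rbind(nose = c(0, 3), forepaw_left = c(-1.5, 1.5),
                                  forepaw_right = c(1.5, 1.5), tail_base = c(0, -4)),
                    above = rbind(ear_left = c(-1.2, 1.5), ear_right = c(1.2, 1.5)))
  lm_prefix <- if (view == "below") "chamber_leg" else "chamber_corner"
  landmarks <- paste0(lm_prefix, "_", 1:4)
  half <- landmark_spacing / 2
  lm_cm <- rbind(c(-half, -half), c(half, -half), c(half, half), c(-half, half))

  img_center <- c(320, 240)  # px; arena centered in the image
  coords <- data.frame(row.names = seq_len(n) - 1L)
  for (p in parts) {
    xy_cm <- sweep(center, 2, offsets[p, ], "+") +
      matrix(rnorm(2 * n, 0, 0.01), ncol = 2)        # tracking wobble
    xy <- sweep(xy_cm * px_per_cm, 2, img_center, "+")
    drop <- runif(n) < dropout_rate
    lik <- ifelse(drop, runif(n, 0, 0.9), runif(n, 0.95, 1))
    xy[drop, ] <- xy[drop, ] + matrix(rnorm(2 * sum(drop), 0, 5 * px_per_cm), ncol = 2)
    coords[[paste0(p, "_x")]] <- xy[, 1]
    coords[[paste0(p, "_y")]] <- xy[, 2]
    coords[[paste0(p, "_likelihood")]] <- lik
  }
  for (i in 1:4) {
    p <- landmarks[i]
    coords[[paste0(p, "_x")]] <- rep(lm_cm[i, 1] * px_per_cm + img_center[1], n)
    coords[[paste0(p, "_y")]] <- rep(lm_cm[i, 2] * px_per_cm + img_center[2], n)
    coords[[paste0(p, "_likelihood")]] <- rep(0.999, n)
  }

  structure(list(coords = coords, fps = fps,
                 bodyparts = parts, landmarks = landmarks,
                 landmark_spacing = landmark_spacing, view = view,
                 units = "px"),
            class = "pose_track")
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> %d frames at %g fps (%s view, units: %s)\n  parts: %s\n  landmarks: %s\n",
              nrow(x$coords), x$fps, x$view %||% "?", x$units,
              paste(x$bodyparts, collapse = ", "),
              paste(x$landmarks, collapse = ", ")))
  invisible(x)
}
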