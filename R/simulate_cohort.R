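#' Session labels of each CTA paradigm
#'
#' `"single"` and `"delayed"`: conditioning day then test day (the delayed
#' variant places TD 7 days later, which changes no labels).
#' `"single_extinction"`: CD then five extinction sessions E1-E5 (TD = E1).
#' `"repeated"`: three conditioning cycles C1-C3 then E1-E8.
#'
#' @param paradigm One of `"single"`, `"single_extinction"`, `"delayed"`,
#'   `"repeated"`.
#' @return Character vector of day labels in session order.
#' @export
paradigm_days <- function(paradigm = c("single", "single_extinction",
                                       "delayed", "repeated")) {
  paradigm <- match.arg(paradigm)
  switch(paradigm,
         single = c("CD", "TD"),
         delayed = c("CD", "TD"),
         single_extinction = c("CD", paste0("E", 1:5)),
         repeated = c(paste0("C", 1:3), paste0("E", 1:8)))
}

#' Default suppression trajectory of the Paired group
#'
#' Per-day `suppression_factor` values emulating CTA acquisition and
#' extinction: 1 before conditioning, at or below 0 once the aversion is
#' expressed, recovering toward 1 across extinction sessions (faster after
#' a single pairing than after three).  The Unpaired group is constant at 1.
#'
#' @inheritParams paradigm_days
#' @return Named numeric vector, one entry per session day.
#' @export
default_effect <- function(paradigm = c("single", "single_extinction",
                                        "delayed", "repeated")) {
  paradigm <- match.arg(paradigm)
  switch(paradigm,
         single = c(CD = 1, TD = -0.5),
         delayed = c(CD = 1, TD = -0.5),
         single_extinction = c(CD = 1, E1 = -0.5, E2 = 0.2, E3 = 0.7,
                               E4 = 0.9, E5 = 1),
         repeated = c(C1 = 1, C2 = 0.2, C3 = -0.6, E1 = -0.6, E2 = -0.4,
                      E3 = -0.1, E4 = 0.2, E5 = 0.6, E6 = 0.8, E7 = 0.9,
                      E8 = 1))
}

#' Simulate a full CTA cohort
#'
#' Generates per-rat, per-day synthetic data for one paradigm: photometry
#' sessions whose transient amplitude follows the injected suppression
#' trajectory (`effect`) in the Paired group and stays at 1 in the
#' Unpaired group; pose sessions whose infusion-window movement burst grows
#' as dopamine is suppressed (aversive reactivity); and, on extinction
#' days, two-bottle consumption whose preference is a linear function of
#' that day's suppression plus noise.
#'
#' @inheritParams paradigm_days
#' @param n_per_group Rats per group (default 10).
#' @param effect Named per-day suppression for the Paired group; defaults
#'   to [default_effect()].
#' @param params Baseline [sim_params()] shared by all sessions (its
#'   `suppression_factor` and `seed` are overridden per session).
#' @param n_trials Infusion trials per session (default 30).
#' @param pose Simulate pose tracks too (default `TRUE`).
#' @param reactivity_coupling `c(intercept, slope)`: injected reactivity
#'   gain (cm) = intercept + slope * (1 - suppression), so full appetitive
#'   responses give ~1 cm and strong aversion ~4 cm with the defaults.
#' @param preference_k Slope linking suppression to preference:
#'   preference = clip(0.5 + k * suppression, 0, 1) + noise (default 0.45).
#' @param preference_sd SD of the preference noise (default 0.05).
#' @param rat_effect_sd SD of the per-rat jitter on the suppression factor
#'   (default 0.1).
#' @param session_effect_sd SD of the per-session (rat x day) jitter on the
#'   suppression factor — day-to-day variability in a rat's responsiveness
#'   (default 0.15).
#' @param seed Master seed; all sessions derive from it (default 1).
#' @return A list of class `cta_cohort`: `paradigm`, `days`, `effect`, and
#'   `sessions` — one element per rat x day with `rat`, `group`, `day`,
#'   `session` (photometry), `truth`, optionally `pose` (track plus the
#'   injected `reactivity_gain`) and `preference` (`sucrose_g`, `water_g`,
#'   true mean).
#' @export
simulate_cohort <- function(paradigm = c("single", "single_extinction",
                                         "delayed", "repeated"),
                            n_per_group = 10, effect = NULL,
                            params = sim_params(), n_trials = 30,
                            pose = TRUE,
                            reactivity_coupling = c(intercept = 1, slope = 2),
                            preference_k = 0.45, preference_sd = 0.05,
                            rat_effect_sd = 0.1, session_effect_sd = 0.15,
                            seed = 1) {
  paradigm <- match.arg(paradigm)
  days <- paradigm_days(paradigm)
  effect <- effect %||% default_effect(paradigm)
  if (!all(days %in% names(effect)))
    stop_invalid("effect must name every day: %s", paste(days, collapse = ", "))
  has_pref <- paradigm %in% c("single_extinction", "repeated")
  set.seed(seed)
  rats <- data.frame(
    rat = c(sprintf("P%02d", seq_len(n_per_group)),
            sprintf("U%02d", seq_len(n_per_group))),
    group = rep(c("Paired", "Unpaired"), each = n_per_group))
  rat_jitter <- rnorm(nrow(rats), 0, rat_effect_sd)

  sessions <- list()
  for (i in seq_len(nrow(rats))) {
    for (day in days) {
      s_day <- if (rats$group[i] == "Paired") effect[[day]] else 1
      s <- min(1, max(-1, s_day + rat_jitter[i] +
                        rnorm(1, 0, session_effect_sd)))
      p <- params
      p$suppression_factor <- s
      events <- make_event_schedule(n_trials, solution = "sucrose")
      sim <- simulate_photometry_session(
        events, p,
        metadata = list(rat = rats$rat[i], group = rats$group[i], day = day))
      entry <- list(rat = rats$rat[i], group = rats$group[i], day = day,
                    session = sim$session, truth = sim$truth)
      if (pose) {
        gain <- max(0, reactivity_coupling[[1]] +
                      reactivity_coupling[[2]] * (1 - s))
        entry$pose <- list(track = simulate_pose_session(events, view = "above",
                                                         reactivity_gain = gain),
                           reactivity_gain = gain)
      }
      if (has_pref && startsWith(day, "E")) {
        mu <- min(1, max(0, 0.5 + preference_k * s))
        pref <- min(1, max(0, mu + rnorm(1, 0, preference_sd)))
        total <- max(1, rnorm(1, 20, 2))
        entry$preference <- list(sucrose_g = pref * total,
                                 water_g = (1 - pref) * total,
                                 true_mean = mu)
      }
      sessions[[length(sessions) + 1L]] <- entry
    }
  }
  structure(list(paradigm = paradigm, days = days, effect = effect,
                 groups = rats, sessions = sessions, seed = seed,
                 params = params),
            class = "cta_cohort")
}

#' @export
print.cta_cohort <- function(x, ...) {
  cat(sprintf("<cta_cohort> %s paradigm: %d rats x %d days (%s), %d sessions\n",
              x$paradigm, nrow(x$groups), length(x$days),
              paste(x$days, collapse = ", "), length(x$sessions)))
  invisible(x)
}
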