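#' Build an intraoral-infusion event schedule
#'
#' Generates the trial timeline used throughout the package: `n_trials`
#' brief infusions (5 s, 200 ul in the behavioral protocol) separated by
#' inter-trial intervals drawn uniformly from `[iti_min, iti_max]` seconds.
#' A lead-in precedes the first infusion so that pre-event baseline windows
#' always lie inside the recording.
#'
#' @param n_trials Number of infusion trials (default 30, one session).
#' @param duration Infusion duration in seconds (default 5).
#' @param iti_min,iti_max Bounds of the uniform inter-trial interval in
#'   seconds, measured from infusion offset to the next onset (defaults
#'   35 and 55).
#' @param solution Label attached to every trial: `"water"`, `"sucrose"`
#'   or `"quinine"`.
#' @param lead_in Seconds of recording before the first infusion onset
#'   (default 60).
#' @param seed Optional integer seed for the ITI draws.
#' @return A data frame of class `event_log` with columns `trial`
#'   (1-based), `onset` (s from session start), `duration` (s) and
#'   `solution`.  Onsets are strictly increasing and consecutive onsets are
#'   separated by `duration + U(iti_min, iti_max)`.
#' @examples
#' ev <- make_event_schedule(30, seed = 1)
#' range(diff(ev$onset))   # within [40, 60]
#' @export
make_event_schedule <- function(n_trials = 30, duration = 5,
                                iti_min = 35, iti_max = 55,
                                solution = c("sucrose", "water", "quinine"),
                                lead_in = 60, seed = NULL) {
  solution <- match.arg(solution)
  check_number(n_trials, "n_trials", lower = 1)
  check_number(duration, "duration", lower = 0, allow_equal_lower = FALSE)
  check_number(iti_min, "iti_min", lower = 0)
  check_number(iti_max, "iti_max", lower = 0)
  check_number(lead_in, "lead_in", lower = 0)
  if (iti_min > iti_max) stop_invalid("iti_min must not exceed iti_max")
  if (!is.null(seed)) set.seed(seed)
  itis <- runif(n_trials - 1, iti_min, iti_max)
  onsets <- lead_in + c(0, cumsum(duration + itis))
  ev <- data.frame(trial = seq_len(n_trials), onset = onsets,
                   duration = duration, solution = solution,
                   stringsAsFactors = FALSE)
  class(ev) <- c("event_log", "data.frame")
  validate_event_log(ev)
  ev
}

#' Validate an event log
#'
#' Checks the `event_log` invariants: strictly increasing onsets,
#' non-negative durations, and a 1-based contiguous trial index.
#'
#' @param events An `event_log` or plain data frame with columns `trial`,
#'   `onset`, `duration`.
#' @return The validated object (invisibly), with class `event_log`.
#' @export
validate_event_log <- function(events) {
  need <- c("trial", "onset", "duration")
  if (!all(need %in% names(events)))
    stop_invalid("event log must have columns %s", paste(need, collapse = ", "))
  if (any(events$duration <= 0)) stop_invalid("event durations must be positive")
  if (any(diff(events$onset) <= 0)) stop_invalid("event onsets must be strictly increasing")
  if (!identical(as.integer(events$trial), seq_len(nrow(events))))
    stop_invalid("trial index must be 1..n_trials")
  if (!inherits(events, "event_log")) class(events) <- c("event_log", class(events))
  invisible(events)
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> %d trials of %s, onsets %.1f-%.1f s\n",
              nrow(x), paste(unique(x$solution), collapse = "/"),
              min(x$onset), max(x$onset)))
  print.data.frame(head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...", nrow(x) - 5, "more trials\n")
  invisible(x)
}
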