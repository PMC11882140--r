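#' Write a pose track in the DeepLabCut CSV dialect
#'
#' Three header rows (scorer / bodyparts / coords) followed by one row per
#' frame, first column the frame index, then x, y, likelihood per part.
#'
#' @param track A `pose_track` (pixel units).
#' @param path Output file.
#' @param scorer Scorer string for the first header row.
#' @return `path`, invisibly.
#' @export
write_dlc_csv <- function(track, path, scorer = "ctaphot_sim") {
  parts <- c(track$bodyparts, track$landmarks)
  n <- nrow(track$coords)
  header1 <- c("scorer", rep(scorer, 3 * length(parts)))
  header2 <- c("bodyparts", rep(parts, each = 3))
  header3 <- c("coords", rep(c("x", "y", "likelihood"), length(parts)))
  body <- matrix("", n, 1 + 3 * length(parts))
  body[, 1] <- as.character(seq_len(n) - 1L)
  j <- 2L
  for (p in parts) for (suffix in c("_x", "_y", "_likelihood")) {
    body[, j] <- format(track$coords[[paste0(p, suffix)]], digits = 15, trim = TRUE,
                        scientific = FALSE)
    j <- j + 1L
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(header1, collapse = ","),
               paste(header2, collapse = ","),
               paste(header3, collapse = ",")), con)
  write.table(body, con, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a DeepLabCut-dialect pose CSV
#'
#' @param path CSV with the 3 header rows DeepLabCut writes (scorer /
#'   bodyparts / coords) and x, y, likelihood columns per body part.
#' @param fps Frame rate of the video (default 10).
#' @param landmarks Character vector naming which body parts are stationary
#'   landmarks; defaults to parts matching `"chamber"`.
#' @param landmark_spacing Physical spacing (cm) of the landmark polygon
#'   sides, for later calibration.
#' @return A `pose_track` in pixel units.
#' @export
read_dlc_csv <- function(path, fps = 10, landmarks = NULL,
                         landmark_spacing = NA_real_) {
  hdr <- readLines(path, n = 3L)
  h2 <- strsplit(hdr[2], ",")[[1]]
  h3 <- strsplit(hdr[3], ",")[[1]]
  if (!identical(tolower(h2[1]), "bodyparts") || !identical(tolower(h3[1]), "coords"))
    stop_invalid("'%s' is not in the DeepLabCut CSV dialect (bodyparts/coords header rows missing)",
                 path)
  dat <- read.csv(path, skip = 3, header = FALSE)
  parts <- unique(h2[-1])
  coords <- data.frame(row.names = seq_len(nrow(dat)))
  for (j in 2:length(h2)) {
    suffix <- switch(h3[j], x = "_x", y = "_y", likelihood = "_likelihood",
                     stop_invalid("unknown coords entry '%s' in %s", h3[j], path))
    coords[[paste0(h2[j], suffix)]] <- as.numeric(dat[[j]])
  }
  if (is.null(landmarks)) landmarks <- grep("chamber", parts, value = TRUE)
  structure(list(coords = coords, fps = fps,
                 bodyparts = setdiff(parts, landmarks), landmarks = landmarks,
                 landmark_spacing = landmark_spacing,
                 view = if (any(grepl("ear", parts))) "above" else "below",
                 units = "px"),
            class = "pose_track")
}

#' Write a photometry session to CSV
#'
#' Signals go to one CSV (`time,f465,f405` with the sampling rate recorded
#' in a comment line), events to another (`trial,onset_s,duration_s,solution`).
#'
#' @param session A `photometry_session`.
#' @param signals_path,events_path Output files.
#' @return Invisibly, the two paths.
#' @export
write_photometry_csv <- function(session, signals_path, events_path) {
  con <- file(signals_path, "w")
  writeLines(sprintf("# sampling_rate_hz: %.10g", session$sampling_rate), con)
  write.csv(data.frame(time = session$time, f465 = session$f465,
                       f405 = session$f405),
            con, row.names = FALSE)
  close(con)
  write.csv(data.frame(trial = session$events$trial,
                       onset_s = session$events$onset,
                       duration_s = session$events$duration,
                       solution = session$events$solution),
            events_path, row.names = FALSE)
  invisible(c(signals = signals_path, events = events_path))
}

#' Read an events CSV into an event log
#'
#' Columns `trial,onset_s,duration_s,solution`.  Rows arriving out of time
#' order are sorted by onset with a warning and the trial index rebuilt.
#'
#' @param path Events CSV.
#' @return An `event_log`.
#' @export
read_events_csv <- function(path) {
  dat <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "onset_s", "duration_s")
  if (!all(need %in% names(dat)))
    stop_invalid("events file %s lacks required column(s): %s", path,
                 paste(setdiff(need, names(dat)), collapse = ", "))
  if (is.unsorted(dat$onset_s, strictly = TRUE)) {
    warning(sprintf("events in %s are not in onset order; sorting", path),
            call. = FALSE)
    dat <- dat[order(dat$onset_s), ]
    dat$trial <- seq_len(nrow(dat))
  }
  ev <- data.frame(trial = as.integer(dat$trial), onset = dat$onset_s,
                   duration = dat$duration_s,
                   solution = dat$solution %||% "sucrose",
                   stringsAsFactors = FALSE)
  class(ev) <- c("event_log", "data.frame")
  validate_event_log(ev)
  ev
}

#' Read a photometry session from CSV files
#'
#' @param signals_path Signals CSV written by [write_photometry_csv()]
#'   (or any CSV with `time,f465,f405` columns; the sampling rate is read
#'   from the `# sampling_rate_hz:` comment or inferred from the time
#'   vector).
#' @param events_path Events CSV (see [read_events_csv()]).
#' @param metadata Named list of session metadata.
#' @return A `photometry_session`.
#' @export
read_photometry_session <- function(signals_path, events_path, metadata = list()) {
  first <- readLines(signals_path, n = 1L)
  fs <- NA_real_
  skip <- 0L
  if (startsWith(first, "#")) {
    fs <- as.numeric(sub(".*:", "", first))
    skip <- 1L
  }
  dat <- read.csv(signals_path, skip = skip)
  need <- c("time", "f465", "f405")
  if (!all(need %in% names(dat)))
    stop_invalid("signals file %s lacks required column(s): %s", signals_path,
                 paste(setdiff(need, names(dat)), collapse = ", "))
  if (is.unsorted(dat$time, strictly = TRUE))
    stop_invalid("time vector in %s is not strictly increasing", signals_path)
  if (!is.finite(fs)) fs <- 1 / median(diff(dat$time))
  events <- read_events_csv(events_path)
  photometry_session(dat$time, dat$f465, dat$f405, fs, events, metadata)
}
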