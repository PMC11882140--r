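#' Configuration of a paradigm-level analysis
#'
#' Collects everything [run_paradigm()] needs: the paradigm and its day
#' labels, cohort size, preprocessing settings, analysis windows, the
#' ROC contrasts (Unpaired-positive versus Paired-negative on each day),
#' and the master seed.
#'
#' @inheritParams paradigm_days
#' @param n_per_group Rats per group (default 10).
#' @param days Day labels; defaults to [paradigm_days()].
#' @param effect Paired-group suppression trajectory; defaults to
#'   [default_effect()].
#' @param filter_order,filter_low,filter_high Bandpass settings.
#' @param infusion_window,baseline_window Analysis windows in seconds
#'   relative to onset.
#' @param align_pre,align_post Trial-alignment extent in seconds.
#' @param pose Whether pose/reactivity is simulated and analyzed.
#' @param seed Master seed.
#' @return A list of class `paradigm_config`.
#' @export
paradigm_config <- function(paradigm = c("single", "single_extinction",
                                         "delayed", "repeated"),
                            n_per_group = 10, days = NULL, effect = NULL,
                            filter_order = 5, filter_low = 0.05,
                            filter_high = 2.25,
                            infusion_window = c(0, 5),
                            baseline_window = c(-5, 0),
                            align_pre = 5, align_post = 10,
                            pose = TRUE, seed = 1) {
  paradigm <- match.arg(paradigm)
  days <- days %||% paradigm_days(paradigm)
  if (anyDuplicated(days)) stop_invalid("day labels must be unique")
  cfg <- list(paradigm = paradigm, n_per_group = n_per_group, days = days,
              effect = effect %||% as.list(default_effect(paradigm)),
              filter_order = filter_order, filter_low = filter_low,
              filter_high = filter_high,
              infusion_window = infusion_window,
              baseline_window = baseline_window,
              align_pre = align_pre, align_post = align_post,
              pose = pose, seed = seed)
  structure(cfg, class = "paradigm_config")
}

#' Read / write a paradigm configuration as YAML
#'
#' @param path YAML file.
#' @return `read_paradigm_config` returns a `paradigm_config`;
#'   `write_paradigm_config` returns `path` invisibly.
#' @export
read_paradigm_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(paradigm_config, raw)
}

#' @rdname read_paradigm_config
#' @param config A `paradigm_config`.
#' @export
write_paradigm_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  saveRDS(unclass(config), tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Load a cohort from disk
#'
#' Reads a manifest-driven data tree: `manifest.csv` under `data_root`
#' must have columns `rat`, `group`, `day`, `signals`, `events` (paths
#' relative to `data_root`) and may have `pose` (DeepLabCut CSV),
#' `sucrose_g` and `water_g`.
#'
#' @param data_root Directory containing `manifest.csv`.
#' @param fps Frame rate of pose CSVs (default 10).
#' @param landmark_spacing Physical landmark spacing (cm) for pose
#'   calibration (default 20).
#' @return A `cta_cohort`-shaped list (no ground truth).
#' @export
load_cohort <- function(data_root, fps = 10, landmark_spacing = 20) {
  mf_path <- file.path(data_root, "manifest.csv")
  if (!file.exists(mf_path)) stop_invalid("missing manifest: %s", mf_path)
  mf <- read.csv(mf_path, stringsAsFactors = FALSE)
  need <- c("rat", "group", "day", "signals", "events")
  if (!all(need %in% names(mf)))
    stop_invalid("manifest lacks column(s): %s",
                 paste(setdiff(need, names(mf)), collapse = ", "))
  missing <- !file.exists(file.path(data_root, mf$signals))
  if (any(missing))
    stop_invalid("missing session file(s): %s",
                 paste(mf$signals[missing], collapse = ", "))
  sessions <- lapply(seq_len(nrow(mf)), function(i) {
    entry <- list(rat = mf$rat[i], group = mf$group[i], day = mf$day[i],
                  session = read_photometry_session(
                    file.path(data_root, mf$signals[i]),
                    file.path(data_root, mf$events[i]),
                    metadata = list(rat = mf$rat[i], group = mf$group[i],
                                    day = mf$day[i])))
    if (!is.null(mf$pose) && nzchar(mf$pose[i]))
      entry$pose <- list(track = read_dlc_csv(file.path(data_root, mf$pose[i]),
                                              fps = fps,
                                              landmark_spacing = landmark_spacing))
    if (!is.null(mf$sucrose_g) && is.finite(mf$sucrose_g[i]))
      entry$preference <- list(sucrose_g = mf$sucrose_g[i],
                               water_g = mf$water_g[i])
    entry
  })
  days <- unique(mf$day)
  structure(list(paradigm = "custom", days = days,
                 groups = unique(mf[c("rat", "group")]), sessions = sessions),
            class = "cta_cohort")
}

#' Run a paradigm-level analysis end to end
#'
#' Executes the full chain on every session of a cohort — control fit and
#' subtraction, zero-phase bandpass, session z-scoring, trial alignment,
#' infusion-window trial statistics, pose cleaning/calibration and
#' behavioral reactivity, preference scoring — then the paradigm's
#' comparisons: an Unpaired-vs-Paired ideal-observer ROC on each day's
#' pooled trial statistics, paired t (first vs last day) and, with three
#' or more days, a one-way RM ANOVA with Dunnett post hoc per group, a
#' two-way mixed ANOVA, and the dopamine-reactivity and
#' dopamine-preference regressions.
#'
#' @param config A `paradigm_config`.
#' @param cohort Optional pre-built `cta_cohort` (e.g. from
#'   [simulate_cohort()] or [load_cohort()]); simulated from `config`
#'   when omitted.
#' @param data_root Optional directory to load a cohort from (see
#'   [load_cohort()]); ignored when `cohort` is given.
#' @return An object of class `cta_report` with elements `trial_table`,
#'   `session_table`, `roc` (per-day AUC table + objects), `tests`,
#'   `regressions` and `provenance` (config hash, package version, seed).
#' @export
run_paradigm <- function(config, cohort = NULL, data_root = NULL) {
  if (!inherits(config, "paradigm_config")) stop_invalid("config must be a paradigm_config")
  if (is.null(cohort)) {
    cohort <- if (!is.null(data_root)) load_cohort(data_root)
    else simulate_cohort(config$paradigm, n_per_group = config$n_per_group,
                         effect = unlist(config$effect), pose = config$pose,
                         seed = config$seed)
  }

  trial_rows <- list()
  sess_rows <- list()
  for (entry in cohort$sessions) {
    pt <- preprocess_session(entry$session, order = config$filter_order,
                             low = config$filter_low, high = config$filter_high)
    tensor <- align_trials(pt, pre = config$align_pre, post = config$align_post)
    stats <- infusion_mean_zscore(tensor, window = config$infusion_window)
    trial_rows[[length(trial_rows) + 1L]] <-
      data.frame(rat = entry$rat, group = entry$group, day = entry$day,
                 trial = stats$trial, mean_z = stats$mean_z)
    react <- NA_real_
    if (!is.null(entry$pose)) {
      track <- calibrate_track(clean_pose(entry$pose$track))
      rt <- behavioral_reactivity(track, entry$session$events,
                                  baseline = config$baseline_window,
                                  infusion = config$infusion_window)
      react <- session_reactivity(rt)
    }
    pref <- if (!is.null(entry$preference))
      preference_score(entry$preference$sucrose_g, entry$preference$water_g)
    else NA_real_
    sess_rows[[length(sess_rows) + 1L]] <-
      data.frame(rat = entry$rat, group = entry$group, day = entry$day,
                 mean_z = attr(stats, "session_mean_z"),
                 reactivity_cm = react, preference = pref)
  }
  trial_table <- do.call(rbind, trial_rows)
  session_table <- do.call(rbind, sess_rows)
  days <- cohort$days

  ## per-day between-group ROC (positive = Unpaired)
  roc_objs <- list()
  roc_tab <- data.frame(day = character(0), auc = numeric(0),
                        discriminable = logical(0))
  for (day in days) {
    pos <- trial_table$mean_z[trial_table$day == day & trial_table$group == "Unpaired"]
    neg <- trial_table$mean_z[trial_table$day == day & trial_table$group == "Paired"]
    if (!length(pos) || !length(neg)) next
    r <- ideal_observer_roc(pos, neg)
    roc_objs[[day]] <- r
    roc_tab <- rbind(roc_tab, data.frame(day = day, auc = r$auc,
                                         discriminable = r$discriminable))
  }

  ## statistics plan
  tests <- list()
  wide_by_group <- function(grp) {
    sub <- session_table[session_table$group == grp, ]
    rm_wide(sub, subject = "rat", condition = "day", value = "mean_z")[, days, drop = FALSE]
  }
  for (grp in c("Paired", "Unpaired")) {
    w <- wide_by_group(grp)
    tests[[paste0("paired_t_", grp)]] <-
      paired_t(w[, 1], w[, ncol(w)])
    if (length(days) > 2)
      tests[[paste0("rm_anova_", grp)]] <-
        one_way_rm_anova(w, reference = days[1])
  }
  tests$mixed_anova <- mixed_two_way_anova(
    session_table, subject = "rat", group = "group", within = "day",
    value = "mean_z",
    posthoc = if (length(days) > 2) "sidak" else "lsd")

  regressions <- list()
  ok <- is.finite(session_table$reactivity_cm)
  if (sum(ok) >= 3 && var(session_table$reactivity_cm[ok]) > 0)
    regressions$dopamine_vs_reactivity <-
      linear_regression(session_table$reactivity_cm[ok], session_table$mean_z[ok])
  okp <- is.finite(session_table$preference)
  if (sum(okp) >= 3 && var(session_table$mean_z[okp]) > 0)
    regressions$preference_vs_dopamine <-
      linear_regression(session_table$mean_z[okp], session_table$preference[okp])

  structure(list(trial_table = trial_table, session_table = session_table,
                 roc = list(table = roc_tab, objects = roc_objs),
                 tests = tests, regressions = regressions,
                 provenance = list(config = config,
                                   config_hash = config_hash(config),
                                   package_version =
                                     as.character(utils::packageVersion("ctaphot")),
                                   seed = config$seed)),
            class = "cta_report")
}

#' @export
print.cta_report <- function(x, ...) {
  cfg <- x$provenance$config
  cat(sprintf("<cta_report> %s paradigm (seed %s, config %s)\n", cfg$paradigm,
              cfg$seed, substr(x$provenance$config_hash, 1, 8)))
  cat("per-day Unpaired-vs-Paired ROC:\n")
  print.data.frame(x$roc$table, row.names = FALSE, digits = 3)
  for (nm in names(x$tests)) {
    cat(nm, ": ", sep = "")
    if (inherits(x$tests[[nm]], "cta_test")) print(x$tests[[nm]])
    else cat("\n")
  }
  for (nm in names(x$regressions)) {
    cat(nm, ": ", sep = "")
    print(x$regressions[[nm]])
  }
  invisible(x)
}

#' @export
summary.cta_report <- function(object, ...) {
  print(object)
  for (nm in names(object$tests))
    if (!inherits(object$tests[[nm]], "cta_test")) {
      cat("\n", nm, ":\n", sep = "")
      print(object$tests[[nm]])
    }
  invisible(object)
}

#' Save an analysis report to disk
#'
#' Writes tidy CSVs (`trials.csv`, `sessions.csv`, `roc.csv`) and a JSON
#' summary (`report.json`) with the test results, regressions and
#' provenance — text formats only, so runs can be diffed.
#'
#' @param report A `cta_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$trial_table, file.path(dir, "trials.csv"), row.names = FALSE)
  write.csv(report$session_table, file.path(dir, "sessions.csv"), row.names = FALSE)
  write.csv(report$roc$table, file.path(dir, "roc.csv"), row.names = FALSE)
  tests <- lapply(report$tests, function(t) {
    if (inherits(t, "cta_test"))
      list(t = t$statistic, df = t$df, p = t$p)
    else if (inherits(t, "rm_anova"))
      list(F = t$F, df1 = t$df1, df2 = t$df2, epsilon = t$epsilon, p = t$p,
           posthoc = t$posthoc)
    else if (inherits(t, "mixed_anova"))
      list(table = t$table, posthoc_between = t$posthoc_between)
  })
  regs <- lapply(report$regressions, function(r)
    list(slope = r$slope, intercept = r$intercept, r_squared = r$r_squared,
         p = r$p_slope, n = r$n))
  jsonlite::write_json(
    list(provenance = report$provenance[c("config_hash", "package_version", "seed")],
         roc = report$roc$table, tests = tests, regressions = regs),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(dir)
}
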