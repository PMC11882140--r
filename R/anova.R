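## reshape helpers for repeated-measures tables --------------------------------

rm_wide <- function(data, subject = "subject", condition = "condition",
                    value = "value") {
  if (is.matrix(data)) {
    if (is.null(colnames(data))) colnames(data) <- paste0("c", seq_len(ncol(data)))
    return(data)
  }
  need <- c(subject, condition, value)
  if (!all(need %in% names(data)))
    stop_invalid("long data must have columns %s", paste(need, collapse = ", "))
  subj <- unique(data[[subject]])
  cond <- unique(data[[condition]])
  wide <- matrix(NA_real_, length(subj), length(cond),
                 dimnames = list(as.character(subj), as.character(cond)))
  for (i in seq_len(nrow(data)))
    wide[as.character(data[[subject]][i]), as.character(data[[condition]][i])] <-
      data[[value]][i]
  if (anyNA(wide))
    stop_invalid("missing cells in the subject x condition table; no imputation is performed")
  wide
}

## Greenhouse-Geisser epsilon from the condition covariance matrix
gg_epsilon <- function(wide) {
  k <- ncol(wide)
  S <- stats::cov(wide)
  ctr <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) + mean(S)
  tr <- sum(diag(ctr))
  denom <- (k - 1) * sum(ctr^2)
  if (denom == 0) return(1)   # no residual covariance: sphericity trivially holds
  eps <- tr^2 / denom
  min(max(eps, 1 / (k - 1)), 1)
}

## Monte-Carlo family-wise p-values for Dunnett many-to-one comparisons:
## quantiles of max |T| where T is multivariate t with pairwise correlation
## 0.5 (balanced design) on df degrees of freedom.  Seeded and restored.
dunnett_adjust <- function(t_obs, df, draws = 1e5, seed = 20240501) {
  m <- length(t_obs)
  max_t <- with_local_seed(seed, {
    shared <- rnorm(draws)
    s <- sqrt(rchisq(draws, df) / df)
    mx <- rep(-Inf, draws)
    for (j in seq_len(m)) {
      zj <- (rnorm(draws) + shared) / sqrt(2)   # corr 0.5 across comparisons
      mx <- pmax(mx, abs(zj / s))
    }
    mx
  })
  vapply(abs(t_obs), function(t0) mean(max_t >= t0), numeric(1))
}

#' One-way repeated-measures ANOVA with Dunnett post hoc
#'
#' Within-subject decomposition of a complete balanced subject x condition
#' table: `F = MS_condition / MS_error` where the error is the
#' subject-by-condition interaction.  Greenhouse-Geisser epsilon (from the
#' doubly centered condition covariance) multiplies both degrees of
#' freedom, yielding the non-integer dfs conventionally printed.  The
#' post hoc compares every condition to the reference condition (e.g. the
#' first conditioning day) with Dunnett's many-to-one procedure;
#' family-wise p-values come from seeded Monte-Carlo quantiles of the
#' multivariate t.
#'
#' @param data Either a subjects x conditions numeric matrix or a long
#'   data frame with columns `subject`, `condition`, `value`.
#' @param correction `"gg"` (Greenhouse-Geisser, default) or `"none"`.
#' @param posthoc `"dunnett"` (default) or `"none"`.
#' @param reference Reference condition for the post hoc; default the
#'   first column/level.
#' @param subject,condition,value Column names when `data` is long.
#' @param dunnett_draws,dunnett_seed Monte-Carlo settings for the Dunnett
#'   adjustment (defaults 1e5 draws, fixed seed).
#' @return An object of class `rm_anova`: `F`, `df1`, `df2` (corrected),
#'   `epsilon`, `p`, an SS `table`, and a `posthoc` data frame
#'   (`condition`, `mean_diff`, `t`, `df`, `p_unadjusted`, `p_adjusted`).
#' @export
one_way_rm_anova <- function(data, correction = c("gg", "none"),
                             posthoc = c("dunnett", "none"),
                             reference = NULL, subject = "subject",
                             condition = "condition", value = "value",
                             dunnett_draws = 1e5, dunnett_seed = 20240501) {
  correction <- match.arg(correction)
  posthoc <- match.arg(posthoc)
  wide <- rm_wide(data, subject, condition, value)
  n <- nrow(wide); k <- ncol(wide)
  if (n < 2 || k < 2) stop_invalid("need at least 2 subjects and 2 conditions")
  grand <- mean(wide)
  ss_subj <- k * sum((rowMeans(wide) - grand)^2)
  ss_cond <- n * sum((colMeans(wide) - grand)^2)
  ss_tot <- sum((wide - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  df_cond <- k - 1
  df_err <- (n - 1) * (k - 1)
  ms_cond <- ss_cond / df_cond
  ms_err <- ss_err / df_err
  f <- if (ms_err == 0) { if (ms_cond == 0) 0 else Inf } else ms_cond / ms_err
  eps <- if (correction == "gg") gg_epsilon(wide) else 1
  df1 <- eps * df_cond
  df2 <- eps * df_err
  p <- if (is.finite(f)) pf(f, df1, df2, lower.tail = FALSE) else 0
  if (ms_cond == 0 && ms_err == 0) p <- 1

  ph <- NULL
  if (posthoc == "dunnett") {
    ref <- reference %||% colnames(wide)[1]
    if (!ref %in% colnames(wide)) stop_invalid("reference condition '%s' not found", ref)
    others <- setdiff(colnames(wide), ref)
    diffs <- colMeans(wide)[others] - colMeans(wide)[[ref]]
    se <- sqrt(2 * ms_err / n)
    tstat <- if (se > 0) diffs / se else ifelse(diffs == 0, 0, sign(diffs) * Inf)
    p_un <- 2 * pt(abs(tstat), df_err, lower.tail = FALSE)
    p_adj <- pmax(dunnett_adjust(tstat, df_err, dunnett_draws, dunnett_seed), p_un)
    ph <- data.frame(condition = others, reference = ref,
                     mean_diff = unname(diffs), t = unname(tstat), df = df_err,
                     p_unadjusted = unname(p_un), p_adjusted = unname(p_adj))
  }

  tab <- data.frame(
    effect = c("subjects", "condition", "error"),
    ss = c(ss_subj, ss_cond, ss_err),
    df = c(n - 1, df_cond, df_err),
    ms = c(ss_subj / (n - 1), ms_cond, ms_err))
  structure(list(F = f, df1 = df1, df2 = df2, epsilon = eps, p = p,
                 correction = correction, table = tab, posthoc = ph,
                 means = colMeans(wide), n = n),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("one-way RM ANOVA: F(%.2f, %.2f) = %.3f, p = %s (GG epsilon = %.3f)\n",
              x$df1, x$df2, x$F, format.pval(x$p, digits = 3), x$epsilon))
  if (!is.null(x$posthoc)) {
    cat(sprintf("Dunnett vs %s:\n", x$posthoc$reference[1]))
    print.data.frame(x$posthoc[c("condition", "mean_diff", "t", "p_adjusted")],
                     row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Two-way mixed ANOVA (between-subject group x within-subject day)
#'
#' Sums-of-squares decomposition for a balanced design with one
#' between-subject factor and one within-subject factor: the group effect
#' is tested against subjects-within-group, day and group x day against
#' the day x subject error.  Post hoc comparisons of groups at each day
#' use the Prism-style pooled error
#' `(MS_subj_within_group + (d - 1) MS_error) / d` with Satterthwaite
#' degrees of freedom, adjusted across days by the Sidak inequality or
#' reported unadjusted (Fisher's LSD, meaningful alongside a significant
#' omnibus F).  Within-group day-versus-first-day comparisons use the
#' within error.
#'
#' @param data Long data frame with columns named by `subject`, `group`,
#'   `within`, `value`.  Every subject must belong to exactly one group
#'   and be measured on every day.
#' @param posthoc `"sidak"` (default), `"lsd"` or `"none"`.
#' @param subject,group,within,value Column names.
#' @return An object of class `mixed_anova` with an effects `table`
#'   (effect, ss, df, ms, F, p), `posthoc_between` (group comparison at
#'   each day), `posthoc_within` (day vs first day within each group),
#'   and cell `means`.
#' @export
mixed_two_way_anova <- function(data, posthoc = c("sidak", "lsd", "none"),
                                subject = "subject", group = "group",
                                within = "day", value = "value") {
  posthoc <- match.arg(posthoc)
  need <- c(subject, group, within, value)
  if (!all(need %in% names(data)))
    stop_invalid("data must have columns %s", paste(need, collapse = ", "))
  subj <- factor(data[[subject]])
  grp <- factor(data[[group]])
  day <- factor(data[[within]], levels = unique(data[[within]]))
  y <- data[[value]]
  ## each subject in exactly one group
  gmap <- tapply(as.character(grp), subj, function(g) length(unique(g)))
  if (any(gmap != 1)) stop_invalid("each subject must belong to exactly one group")
  counts <- table(subj, day)
  if (any(counts != 1)) stop_invalid("unbalanced design: every subject needs one value per day")
  g <- nlevels(grp); d <- nlevels(day)
  n_per <- table(tapply(as.character(grp), subj, unique))
  if (length(unique(n_per)) != 1)
    stop_invalid("groups must have equal size for this balanced decomposition")
  n <- unname(n_per[1])

  grand <- mean(y)
  m_subj <- tapply(y, subj, mean)
  m_grp <- tapply(y, grp, mean)
  m_day <- tapply(y, day, mean)
  m_cell <- tapply(y, list(grp, day), mean)

  ss_tot <- sum((y - grand)^2)
  ss_subj <- d * sum((m_subj - grand)^2)
  ss_grp <- n * d * sum((m_grp - grand)^2)
  ss_swg <- ss_subj - ss_grp
  ss_day <- g * n * sum((m_day - grand)^2)
  ss_int <- n * sum((m_cell - outer(m_grp, rep(1, d)) -
                       outer(rep(1, g), m_day) + grand)^2)
  ss_err <- ss_tot - ss_subj - ss_day - ss_int

  df_grp <- g - 1; df_swg <- g * (n - 1)
  df_day <- d - 1; df_int <- (g - 1) * (d - 1); df_err <- g * (n - 1) * (d - 1)
  ms <- c(grp = ss_grp / df_grp, swg = ss_swg / df_swg, day = ss_day / df_day,
          int = ss_int / df_int, err = ss_err / df_err)
  safe_f <- function(num, den) if (num == 0) 0 else num / den
  f_grp <- safe_f(ms[["grp"]], ms[["swg"]])
  f_day <- safe_f(ms[["day"]], ms[["err"]])
  f_int <- safe_f(ms[["int"]], ms[["err"]])
  tab <- data.frame(
    effect = c(group, "subjects within group", within,
               paste0(group, " x ", within), "error (within)"),
    ss = c(ss_grp, ss_swg, ss_day, ss_int, ss_err),
    df = c(df_grp, df_swg, df_day, df_int, df_err),
    ms = unname(c(ms["grp"], ms["swg"], ms["day"], ms["int"], ms["err"])),
    F = c(f_grp, NA, f_day, f_int, NA),
    p = c(pf(f_grp, df_grp, df_swg, lower.tail = FALSE), NA,
          pf(f_day, df_day, df_err, lower.tail = FALSE),
          pf(f_int, df_int, df_err, lower.tail = FALSE), NA))

  ph_between <- ph_within <- NULL
  if (posthoc != "none") {
    if (g != 2)
      warning("between-group post hoc implemented for 2 groups; skipping",
              call. = FALSE)
    else {
      ## groups compared at each day with the pooled between+within error
      ms_comp <- (ms[["swg"]] + (d - 1) * ms[["err"]]) / d
      df_comp <- (ms[["swg"]] + (d - 1) * ms[["err"]])^2 /
        (ms[["swg"]]^2 / df_swg + ((d - 1) * ms[["err"]])^2 / df_err)
      se <- sqrt(2 * ms_comp / n)
      diffs <- m_cell[1, ] - m_cell[2, ]
      tstat <- diffs / se
      p_un <- 2 * pt(abs(tstat), df_comp, lower.tail = FALSE)
      p_adj <- if (posthoc == "sidak") pmin(1, 1 - (1 - p_un)^d) else p_un
      ph_between <- data.frame(day = levels(day),
                               comparison = paste(levels(grp)[1], "-", levels(grp)[2]),
                               mean_diff = unname(diffs), t = unname(tstat),
                               df = df_comp, p_unadjusted = unname(p_un),
                               p_adjusted = unname(p_adj))
    }
    ## each later day vs the first day, within each group, on the within error
    se_w <- sqrt(2 * ms[["err"]] / n)
    rows <- list()
    for (gl in levels(grp)) for (dl in levels(day)[-1]) {
      diff <- m_cell[gl, dl] - m_cell[gl, levels(day)[1]]
      tstat <- diff / se_w
      p_un <- 2 * pt(abs(tstat), df_err, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(group = gl, comparison = paste(dl, "-", levels(day)[1]),
                   mean_diff = diff, t = tstat, df = df_err, p_unadjusted = p_un)
    }
    ph_within <- do.call(rbind, rows)
    m <- d - 1
    ph_within$p_adjusted <- if (posthoc == "sidak")
      pmin(1, 1 - (1 - ph_within$p_unadjusted)^m) else ph_within$p_unadjusted
  }

  structure(list(table = tab, posthoc_between = ph_between,
                 posthoc_within = ph_within, means = m_cell,
                 posthoc_method = posthoc, n_per_group = n),
            class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("two-way mixed ANOVA\n")
  tt <- x$table
  for (i in which(!is.na(tt$F)))
    cat(sprintf("  %s: F(%g, %g) = %.3f, p = %s\n", tt$effect[i], tt$df[i],
                tt$df[if (i == 1) 2 else 5], tt$F[i], format.pval(tt$p[i], digits = 3)))
  if (!is.null(x$posthoc_between)) {
    cat(sprintf("  post hoc (%s), groups at each %s:\n", x$posthoc_method,
                x$table$effect[3]))
    print.data.frame(x$posthoc_between[c("day", "mean_diff", "t", "p_adjusted")],
                     row.names = FALSE, digits = 4)
  }
  invisible(x)
}
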