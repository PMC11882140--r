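#' Data-adaptive ROC threshold grid
#'
#' Builds the sweep of classification thresholds used by
#' [ideal_observer_roc()]: the step is the mean of the differences between
#' consecutive sorted unique pooled values, and the grid spans from one
#' step below the pooled minimum to one step above the pooled maximum.
#'
#' @param values_a,values_b Trial statistics of the two conditions (each
#'   length >= 2).
#' @return Numeric threshold vector.  If all pooled values are identical
#'   the single observed value is returned with attribute
#'   `degenerate = TRUE`.
#' @examples
#' threshold_grid(c(0, 1), c(2, 3))   # step 1: -1, 0, 1, 2, 3, 4
#' @export
threshold_grid <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop_invalid("each group needs at least 2 values")
  pooled <- sort(unique(c(values_a, values_b)))
  if (length(pooled) == 1)
    return(structure(pooled, degenerate = TRUE))
  step <- mean(diff(pooled))
  seq(pooled[1] - step, pooled[length(pooled)] + step, by = step)
}

#' Ideal-observer ROC between two trial-statistic distributions
#'
#' Quantifies how well an ideal observer could classify a single trial's
#' infusion response as coming from the positive condition (e.g. sucrose,
#' or the Unpaired group) rather than the negative one (quinine, or the
#' Paired group).  For each threshold on the data-adaptive grid
#' ([threshold_grid()]), the hit rate is the fraction of positive values
#' strictly above the threshold and the false-alarm rate the fraction of
#' negative values strictly above it.  The AUC is the trapezoidal integral
#' of hit rate over false-alarm rate with endpoints (0,0) and (1,1)
#' appended; AUC above 0.7 flags the conditions as reliably discriminable.
#'
#' @param positive,negative Numeric trial statistics of the two conditions.
#' @return An object of class `io_roc`: `thresholds`, `hit_rate`,
#'   `false_alarm_rate`, `auc`, `discriminable` (`auc > 0.7`), `n`.
#' @examples
#' ideal_observer_roc(c(4, 5, 6), c(1, 2, 3))$auc   # 1: full separation
#' @export
ideal_observer_roc <- function(positive, negative) {
  if (!length(positive) || !length(negative))
    stop_invalid("both groups must be non-empty")
  thr <- threshold_grid(positive, negative)
  hit <- vapply(thr, function(th) mean(positive > th), numeric(1))
  fa <- vapply(thr, function(th) mean(negative > th), numeric(1))
  ord <- order(fa, hit)
  xs <- c(0, fa[ord], 1)
  ys <- c(0, hit[ord], 1)
  auc <- sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
  structure(list(thresholds = thr, hit_rate = hit, false_alarm_rate = fa,
                 auc = auc, discriminable = auc > 0.7,
                 degenerate = isTRUE(attr(thr, "degenerate")),
                 n = c(positive = length(positive), negative = length(negative))),
            class = "io_roc")
}

#' Rank-based AUC (pair-counting oracle)
#'
#' The probability that a randomly chosen positive value exceeds a randomly
#' chosen negative one, counting ties as one half — the Wilcoxon-Mann-
#' Whitney statistic.  Serves as an independent check on the grid-swept
#' [ideal_observer_roc()] AUC.
#'
#' @inheritParams ideal_observer_roc
#' @return AUC in `[0, 1]`.
#' @export
rank_auc_oracle <- function(positive, negative) {
  if (!length(positive) || !length(negative))
    stop_invalid("both groups must be non-empty")
  cmp <- outer(positive, negative, ">") + 0.5 * outer(positive, negative, "==")
  mean(cmp)
}

#' @export
print.io_roc <- function(x, ...) {
  cat(sprintf("<io_roc> AUC = %.3f (n+ = %d, n- = %d): %sdiscriminable%s\n",
              x$auc, x$n["positive"], x$n["negative"],
              if (x$discriminable) "" else "not ",
              if (x$degenerate) " [degenerate grid]" else ""))
  invisible(x)
}

#' @export
plot.io_roc <- function(x, ...) {
  ord <- order(x$false_alarm_rate, x$hit_rate)
  plot(c(0, x$false_alarm_rate[ord], 1), c(0, x$hit_rate[ord], 1),
       type = "l", xlab = "False-alarm rate", ylab = "Hit rate",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  abline(0, 1, lty = 3, col = "grey50")
  mtext(sprintf("AUC = %.2f", x$auc), side = 3, adj = 1, line = 0.2, cex = 0.9)
  invisible(x)
}
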