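#' Paired t-test on the change from one condition to another
#'
#' Two-tailed paired t on the per-subject differences `y - x`
#' (e.g. conditioning day to test day), with `n - 1` degrees of freedom and
#' the sample (n-1 denominator) SD.
#'
#' @param x,y Per-subject values under the two conditions, same order and
#'   length (n >= 2).
#' @return A list of class `cta_test`: `statistic` (t), `df`, `p`,
#'   `mean_diff`, `zero_variance` flag, `effect` label.  When the
#'   differences have zero variance, `statistic` is 0 (if the mean
#'   difference is 0) or signed `Inf`, `p` is `NA`, and `zero_variance`
#'   is `TRUE`.
#' @examples
#' paired_t(c(1, 2, 3), c(2, 3, 5))   # t = 4, df = 2
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  if (length(x) < 2) stop_invalid("need at least 2 pairs")
  d <- y - x
  if (sd(d) == 0) {
    out <- list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                df = length(d) - 1, p = NA_real_, mean_diff = mean(d),
                zero_variance = TRUE, effect = "paired t (y - x)")
  } else {
    tt <- t.test(y, x, paired = TRUE)
    out <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, mean_diff = unname(tt$estimate),
                zero_variance = FALSE, effect = "paired t (y - x)")
  }
  class(out) <- "cta_test"
  out
}

#' @export
print.cta_test <- function(x, ...) {
  cat(sprintf("%s: t(%g) = %.3f, p = %s%s\n", x$effect, x$df, x$statistic,
              format.pval(x$p, digits = 3),
              if (isTRUE(x$zero_variance)) " [zero-variance differences]" else ""))
  invisible(x)
}

#' Simple linear regression with confidence band
#'
#' OLS fit of `y` on `x` reporting the slope, intercept, r-squared, the
#' two-tailed p-value for slope different from zero, and a pointwise 95%
#' confidence band for the mean response — the quantities reported for the
#' dopamine-versus-reactivity and dopamine-versus-preference relationships.
#'
#' @param x Predictor (n >= 3, non-constant).
#' @param y Response.
#' @return An object of class `cta_regression`: `slope`, `intercept`,
#'   `r_squared`, `p_slope`, `n`, and the underlying `lm` fit.
#' @examples
#' linear_regression(c(0, 1, 2), c(0, 2, 2))   # slope 1, r^2 = 0.75
#' @export
linear_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_invalid("need at least 3 finite (x, y) pairs")
  if (var(x) == 0) stop_invalid("predictor is constant; slope undefined")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))   # "perfect fit" warning on exact data
  out <- list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
              r_squared = sm$r.squared,
              p_slope = sm$coefficients[2, 4], n = length(x), fit = fit)
  class(out) <- "cta_regression"
  out
}

#' Confidence band of a fitted regression
#'
#' @param object A `cta_regression`.
#' @param x_new Predictor values at which to evaluate the band; defaults
#'   to a 100-point grid over the observed range.
#' @param level Confidence level (default 0.95).
#' @param ... Unused.
#' @return Data frame with `x`, `fit`, `lwr`, `upr`.
#' @export
predict.cta_regression <- function(object, x_new = NULL, level = 0.95, ...) {
  if (is.null(x_new)) {
    xr <- range(object$fit$model$x)
    x_new <- seq(xr[1], xr[2], length.out = 100)
  }
  pr <- predict(object$fit, newdata = data.frame(x = x_new),
                interval = "confidence", level = level)
  data.frame(x = x_new, fit = pr[, "fit"], lwr = pr[, "lwr"], upr = pr[, "upr"])
}

#' @export
print.cta_regression <- function(x, ...) {
  cat(sprintf("linear regression (n = %d): slope = %.4g, intercept = %.4g, r^2 = %.3f, p = %s\n",
              x$n, x$slope, x$intercept, x$r_squared, format.pval(x$p_slope, digits = 3)))
  invisible(x)
}

#' @export
plot.cta_regression <- function(x, ...) {
  d <- x$fit$model
  band <- predict(x)
  plot(d$x, d$y, xlab = "x", ylab = "y", ...)
  polygon(c(band$x, rev(band$x)), c(band$lwr, rev(band$upr)),
          col = grey(0.5, 0.25), border = NA)
  lines(band$x, band$fit)
  invisible(x)
}

#' Two-bottle sucrose preference score
#'
#' Preference = sucrose consumed (g) / total fluid consumed (g), from the
#' 2-h home-cage two-bottle test.  Vectorized over sessions.
#'
#' @param sucrose_g,water_g Grams of sucrose solution and water consumed
#'   (non-negative).
#' @return Preference fraction in `[0, 1]`; `NA` (with a warning) for
#'   sessions with zero total consumption.
#' @examples
#' preference_score(3, 1)   # 0.75
#' @export
preference_score <- function(sucrose_g, water_g) {
  if (any(sucrose_g < 0, na.rm = TRUE) || any(water_g < 0, na.rm = TRUE))
    stop_invalid("consumption must be non-negative")
  total <- sucrose_g + water_g
  if (any(total == 0, na.rm = TRUE))
    warning("zero total consumption; preference undefined for those sessions",
            call. = FALSE)
  ifelse(total > 0, sucrose_g / total, NA_real_)
}
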