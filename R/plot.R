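#' Peri-event plot of a trial tensor
#'
#' Draws the across-trial mean z-scored response aligned to infusion onset
#' with a +/- SEM ribbon, onset marked and the infusion window shaded —
#' the standard peri-event summary below a trial heat map.
#'
#' @param x A `trial_tensor`.
#' @param shade Window to shade in seconds relative to onset (default
#'   `c(0, 5)`, the infusion).
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.trial_tensor <- function(x, shade = c(0, 5), ...) {
  rel <- attr(x, "rel_time")
  m <- colMeans(x)
  sem <- apply(x, 2, sd) / sqrt(nrow(x))
  plot(rel, m, type = "n", xlab = "Time from infusion onset (s)",
       ylab = "z-score", ylim = range(m + sem, m - sem), ...)
  if (!is.null(shade))
    polygon(c(shade, rev(shade)), rep(range(m + sem, m - sem), each = 2)[c(1, 1, 2, 2)],
            col = grey(0.8, 0.4), border = NA)
  polygon(c(rel, rev(rel)), c(m + sem, rev(m - sem)),
          col = grey(0.4, 0.3), border = NA)
  lines(rel, m, lwd = 1.5)
  abline(v = 0, lty = 3)
  invisible(x)
}

#' Heat map of per-trial aligned responses
#'
#' One row per trial (trial 1 at the top), color mapping the z-scored
#' response across peri-event time.
#'
#' @param tensor A `trial_tensor`.
#' @param ... Passed to [image()].
#' @return The tensor, invisibly.
#' @export
trial_heatmap <- function(tensor, ...) {
  rel <- attr(tensor, "rel_time")
  nt <- nrow(tensor)
  image(rel, seq_len(nt), t(tensor[nt:1, , drop = FALSE]),
        col = hcl.colors(64, "viridis"),
        xlab = "Time from infusion onset (s)", ylab = "Trial", yaxt = "n", ...)
  axis(2, at = c(1, nt), labels = c(nt, 1))
  abline(v = 0, lty = 3, col = "white")
  invisible(tensor)
}
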