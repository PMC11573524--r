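# Minimal base-graphics forest plot of MR result rows.

#' Forest plot of MR results
#'
#' Draws point estimates and 95% intervals on the odds-ratio scale (log
#' axis), one row per result, labelled `exposure | method` when those
#' columns are present.
#'
#' @param results Data frame of MR result rows (as produced by
#'   [mr_estimates()] or the pipeline's `mr_results` table) with columns
#'   `or`, `or_ci_low`, `or_ci_high`.
#' @param ref Reference line (default OR = 1).
#' @param xlab X-axis label.
#' @return Invisibly, `results`.
#' @export
plot_forest <- function(results, ref = 1, xlab = "Odds ratio (95% CI)") {
  stopifnot(all(c("or", "or_ci_low", "or_ci_high") %in% names(results)))
  results <- results[!is.na(results$or), , drop = FALSE]
  n <- nrow(results)
  if (n == 0L) stop("nothing to plot", call. = FALSE)
  labels <- if (!is.null(results$exposure)) {
    paste(results$exposure, results$method, sep = " | ")
  } else {
    results$method
  }
  y <- rev(seq_len(n))
  old <- graphics::par(mar = c(4, 12, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(results$or, y, log = "x", pch = 15,
                 xlim = range(c(results$or_ci_low, results$or_ci_high, ref)),
                 ylim = c(0.5, n + 0.5), yaxt = "n", ylab = "", xlab = xlab)
  graphics::segments(results$or_ci_low, y, results$or_ci_high, y)
  graphics::abline(v = ref, lty = 2, col = "grey40")
  graphics::axis(2, at = y, labels = labels, las = 1, cex.axis = 0.8)
  invisible(results)
}
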