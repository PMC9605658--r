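#' Scatter and Bland-Altman panels for one parameter
#'
#' One row per method pair: left, the scatter of method A against method B
#' with the least-squares line and the Pearson rho and p in the title;
#' right, the Bland-Altman plot (difference against pairwise mean) with the
#' bias line and both the +/- 1 SD and the +/- `loa_multiplier` SD limits.
#'
#' @param records long-format scan records (see [run_agreement_battery()]).
#' @param param one of `"suvmean"`, `"mtv_ml"`, `"tlg"`.
#' @param timepoint which scans to plot.
#' @param path output PNG path (`NULL` draws to the active device).
#' @param loa_multiplier limits-of-agreement multiplier.
#' @return invisibly, the path (or `NULL`).
#' @export
plot_agreement_panels <- function(records, param, timepoint = "PET1",
                                  path = NULL, loa_multiplier = 1.96) {
  pairs <- method_pairs()
  if (!is.null(path)) {
    grDevices::png(path, width = 1400, height = 350 * length(pairs),
                   res = 110)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(length(pairs), 2),
                      mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(op), add = TRUE)
  wide <- reshape_param(records, param, timepoint)
  for (pair in pairs) {
    a <- wide[[paste0(param, ".", pair[1])]]
    b <- wide[[paste0(param, ".", pair[2])]]
    ok <- is.finite(a) & is.finite(b)
    a <- a[ok]; b <- b[ok]
    lab <- paste(pair[1], "vs", pair[2])
    if (length(a) >= 3 && stats::sd(a) > 0 && stats::sd(b) > 0) {
      pr <- pearson_regression(a, b)
      graphics::plot(a, b, xlab = pair[1], ylab = pair[2],
                     main = sprintf("%s %s @ %s: rho = %.2f, p = %.3g",
                                    param, lab, timepoint, pr$rho, pr$p))
      graphics::abline(pr$intercept, pr$slope, col = "firebrick")
      ba <- bland_altman(a, b, loa_multiplier = loa_multiplier)
      graphics::plot(ba$means, ba$diffs, xlab = "mean of methods",
                     ylab = paste(pair[1], "-", pair[2]),
                     main = sprintf("bias = %.3g, SD = %.3g",
                                    ba$bias, ba$sd))
      graphics::abline(h = ba$bias, col = "firebrick")
      graphics::abline(h = ba$bias + c(-1, 1) * ba$sd,
                       col = "grey40", lty = 3)
      graphics::abline(h = c(ba$loa_low, ba$loa_high),
                       col = "grey40", lty = 2)
    } else {
      for (i in 1:2) {
        graphics::plot.new()
        graphics::title(main = paste(lab, "- insufficient data"))
      }
    }
  }
  invisible(path)
}
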