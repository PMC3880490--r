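#' Plot a shape signature
#'
#' Bar plot of the global 1D segment-length distribution with the
#' per-fragment intra histograms overlaid as lines, the standard way to
#' eyeball what a descriptor says about a molecule's shape.
#'
#' @param sig a `fragsig_signature`.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the global histogram.
#' @export
plot_signature <- function(sig, ...) {
  g <- global_histogram(sig)
  bw <- g$bin_width
  mids <- (seq_along(g$heights) - 0.5) * bw
  graphics::barplot(g$heights, names.arg = sprintf("%.1f", mids),
                    xlab = "segment length (A)", ylab = "probability",
                    main = sig$id, border = NA, col = "grey80", ...)
  xs <- seq_along(g$heights)
  cols <- grDevices::hcl.colors(max(2, length(sig$frag_sigs)), "Dark 2")
  k <- 0
  for (fs in sig$frag_sigs) {
    k <- k + 1
    h <- normalize(fs$h1)$heights
    graphics::lines((xs - 0.5)[seq_along(h)] * 1.2, h, col = cols[k], lwd = 2)
  }
  graphics::legend("topright", bty = "n", lwd = 2, col = cols[seq_len(k)],
                   legend = paste("fragment", names(sig$frag_sigs)))
  invisible(g)
}

#' Plot an ROC curve from [roc_points()]
#'
#' @param roc tibble with `fpr`, `tpr` columns.
#' @param ... passed to [graphics::plot()].
#' @return `roc`, invisibly.
#' @export
plot_roc <- function(roc, ...) {
  graphics::plot(c(0, roc$fpr, 1), c(0, roc$tpr, 1), type = "s",
                 xlab = "false positive rate", ylab = "true positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(roc)
}
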