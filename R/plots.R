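#' Scatter plots of PC scores in three views
#'
#' Draws three panels - PC1 x PC2, PC1 x PC3, PC2 x PC3 - with one color
#' and plotting symbol per group and a single legend. The caller controls
#' the device (screen, pdf, png).
#'
#' @param scores numeric matrix with at least 3 columns of PC scores.
#' @param groups optional group labels (one per row); a single group is
#'   plotted in one color.
#' @param main overall title prefix.
#' @return invisible `NULL`.
#' @export
plot3Views <- function(scores, groups = NULL, main = "") {
  scores <- as.matrix(scores)
  if (ncol(scores) < 3L) {
    .argError("plot3Views needs at least 3 score columns (got %d)",
              ncol(scores))
  }
  if (is.null(groups)) groups <- rep(1L, nrow(scores))
  if (length(groups) != nrow(scores)) {
    .argError("groups must have one entry per row of scores")
  }
  fg <- factor(groups)
  cols <- grDevices::hcl.colors(max(3L, nlevels(fg)), "Dark 3")[as.integer(fg)]
  pchs <- ((as.integer(fg) - 1L) %% 5L) + 1L
  opar <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(opar))
  panes <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (i in seq_along(panes)) {
    xy <- panes[[i]]
    graphics::plot(scores[, xy[1L]], scores[, xy[2L]], col = cols, pch = pchs,
                   xlab = paste0("PC", xy[1L]), ylab = paste0("PC", xy[2L]),
                   main = if (i == 2L && nzchar(main)) main else "")
    if (i == 1L) {
      graphics::legend("topright",
                       legend = levels(fg),
                       col = grDevices::hcl.colors(max(3L, nlevels(fg)),
                                                   "Dark 3")[seq_len(nlevels(fg))],
                       pch = ((seq_len(nlevels(fg)) - 1L) %% 5L) + 1L,
                       cex = 0.8, bty = "n")
    }
  }
  invisible(NULL)
}
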