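#' Scatter plot of 2D gene coordinates colored by dominance group
#'
#' Works for PCA score pairs and t-SNE layouts alike.  Genes dominated by
#' the first class are drawn red, by the second class blue, and
#' non-significant genes grey.
#'
#' @param coords two-column matrix of per-gene coordinates (rows = genes).
#' @param dominance optional [dominance_ttest()] table aligned by
#'   `gene_symbol` with the coordinate row names.
#' @param main plot title.
#' @param ... further arguments to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_gene_map <- function(coords, dominance = NULL, main = "", ...) {
  col <- rep("grey60", nrow(coords))
  if (!is.null(dominance) && !is.null(rownames(coords))) {
    grp <- dominance$group[match(rownames(coords), dominance$gene_symbol)]
    lv <- levels(dominance$group)
    col[grp == lv[1L]] <- "red3"
    col[grp == lv[2L]] <- "blue3"
  }
  graphics::plot(coords[, 1L], coords[, 2L], col = col, pch = 16, cex = 0.6,
                 xlab = colnames(coords)[1L] %||% "dim 1",
                 ylab = colnames(coords)[2L] %||% "dim 2",
                 main = main, ...)
  invisible(NULL)
}
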