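#' Hierarchical clustering of fold-change rows
#'
#' Agglomerative clustering of the genes x time-points log2 fold-change
#' matrix (rows only; columns stay in chronological order), with the
#' heatmap.2-style defaults of Euclidean distance and complete linkage.
#' [stats::hclust()] breaks distance ties deterministically by original row
#' index, so the leaf order is reproducible. A constant matrix (all pairwise
#' distances zero) returns the input order with a warning.
#'
#' @param mat numeric matrix, >= 2 rows.
#' @param distance distance method for [stats::dist()].
#' @param linkage agglomeration method for [stats::hclust()].
#' @return list of class `fc_cluster`: `order` (leaf order), `hclust`
#'   (the merge tree, or NULL for a constant matrix), `labels`.
#' @export
hierarchical_cluster <- function(mat, distance = "euclidean",
                                 linkage = "complete") {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("hierarchical_cluster: needs >= 2 rows")
  if (any(!is.finite(mat))) stop("hierarchical_cluster: non-finite entries")
  d <- dist(mat, method = distance)
  if (all(d == 0)) {
    warning("all pairwise distances are zero; returning input order")
    return(structure(list(order = seq_len(nrow(mat)), hclust = NULL,
                          labels = rownames(mat)), class = "fc_cluster"))
  }
  hc <- hclust(d, method = linkage)
  structure(list(order = hc$order, hclust = hc, labels = rownames(mat)),
            class = "fc_cluster")
}

#' Export a clustered fold-change heatmap
#'
#' Writes a PNG heatmap of the matrix in leaf order under a diverging palette
#' centred at zero (magenta = decreased, green = increased, matching the
#' field's treated-vs-vehicle convention) plus a CSV of the matrix in display
#' order.
#'
#' @param mat numeric matrix (genes x time points).
#' @param leaf_order integer row order (e.g. from
#'   [hierarchical_cluster()]`$order`); default keeps input order.
#' @param file_png,file_csv output paths (either may be NULL to skip).
#' @param palette vector of colors, diverging and odd-length so the middle
#'   color sits at zero.
#' @return invisibly, a list with the ordered matrix and the paths written.
#' @export
heatmap_export <- function(mat, leaf_order = seq_len(nrow(mat)),
                           file_png = NULL, file_csv = NULL,
                           palette = colorRampPalette(
                             c("magenta", "black", "green"))(101)) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat))) stop("heatmap_export: non-finite entries")
  if (length(palette) %% 2 != 1)
    stop("heatmap_export: palette must have odd length (center at 0)")
  ordered <- mat[leaf_order, , drop = FALSE]
  if (!is.null(file_png)) {
    lim <- max(abs(mat), 1e-12)
    png(file_png, width = 480, height = 640)
    op <- par(mar = c(4, 1, 1, 6))
    image(x = seq_len(ncol(ordered)), y = seq_len(nrow(ordered)),
          z = t(ordered[rev(seq_len(nrow(ordered))), , drop = FALSE]),
          zlim = c(-lim, lim), col = palette, axes = FALSE,
          xlab = "", ylab = "")
    axis(1, at = seq_len(ncol(ordered)), labels = colnames(ordered))
    if (nrow(ordered) <= 60)
      axis(4, at = seq_len(nrow(ordered)),
           labels = rev(rownames(ordered)), las = 2, cex.axis = 0.6)
    par(op); dev.off()
  }
  if (!is.null(file_csv)) {
    df <- data.frame(gene = rownames(ordered) %||% seq_len(nrow(ordered)),
                     ordered, check.names = FALSE)
    write.csv(df, file_csv, row.names = FALSE)
  }
  invisible(list(matrix = ordered, png = file_png, csv = file_csv))
}
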