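#' Export the sample-membership heatmap and its numeric companion
#'
#' Renders the samples x biclusters membership matrix on a diverging
#' blue-white-red scale centred at 0, after dropping samples that belong to
#' no bicluster.  The exact plotted values are always written to a companion
#' TSV next to the image, so downstream checks never need to parse pixels.
#'
#' @param sample_membership numeric matrix, samples x biclusters, values in
#'   `[-1, +1]` (e.g. `membership_matrices(bs)$col_membership`).
#' @param path image path; the extension selects the device (`.png` or
#'   `.pdf`).
#' @param tsv_path companion TSV path; defaults to `path` with a `.tsv`
#'   extension.
#' @return invisibly, a list with the plotted matrix and the two paths.
#' @export
export_membership_heatmap <- function(sample_membership, path,
                                      tsv_path = paste0(sub("\\.[A-Za-z]+$", "", path), ".tsv")) {
  m <- as.matrix(sample_membership)
  if (any(!is.finite(m)) || any(abs(m) > 1))
    stop("membership scores must be finite and within [-1, +1]")
  keep <- rowSums(m != 0) > 0
  plotted <- m[keep, , drop = FALSE]
  df <- data.frame(sample = rownames(plotted), plotted,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!nrow(plotted)) {
    warning("no sample belongs to any bicluster; writing an empty plot")
    grDevices::png(path)
    plot.new()
    graphics::title("no sample belongs to any bicluster")
    grDevices::dev.off()
    return(invisible(list(matrix = plotted, image = path, tsv = tsv_path)))
  }
  pheatmap::pheatmap(
    plotted,
    cluster_rows = nrow(plotted) > 2,
    cluster_cols = FALSE,
    breaks = seq(-1, 1, length.out = 101),
    color = grDevices::colorRampPalette(c("blue", "white", "red"))(100),
    border_color = NA,
    filename = path,
    silent = TRUE)
  invisible(list(matrix = plotted, image = path, tsv = tsv_path))
}
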