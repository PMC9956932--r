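#' Scatter plot of one batch's clustering result
#'
#' Renders a batch in the pipeline's visual convention: compact clusters
#' colored and numbered 1..K in the legend, mean-stage outliers drawn as
#' red dots labeled "-1", and std-stage selections drawn as "+" markers
#' labeled "-2". Axes are named after the two strains.
#'
#' @param profile an `aggregated_profile`.
#' @param batch a `batch` object.
#' @param labeling the batch's `dbscan_labeling` (aligned with
#'   `batch$positions`).
#' @param std_positions integer positions (into the profile) flagged by the
#'   std stage; empty by default.
#' @param space `"mean"` (default) or `"std"`: which 2-D projection to draw.
#' @param file optional output path (png/svg/pdf by extension); when `NULL`
#'   the ggplot object is only returned.
#' @param width,height device size in inches when writing a file.
#' @return The ggplot object, invisibly when a file is written.
#' @export
plot_batch <- function(profile, batch, labeling, std_positions = integer(0),
                       space = c("mean", "std"), file = NULL,
                       width = 6, height = 5) {
  space <- match.arg(space)
  pos <- batch$positions
  pts <- profile_points(profile, space)[pos, , drop = FALSE]
  lab <- as.character(labeling$labels)
  lab[pos %in% std_positions] <- "-2"
  lvl <- c(sort(unique(labeling$labels[labeling$labels > 0L])), -1L, -2L)
  lvl <- as.character(lvl[as.character(lvl) %in% lab])
  df <- data.frame(x = pts[, 1L], y = pts[, 2L],
                   cluster = factor(lab, levels = lvl))
  so <- attr(profile, "strain_order")
  axis_prefix <- if (space == "mean") "mean log expression" else "sd log expression"
  cols <- cluster_palette(lvl)
  shp <- ifelse(lvl == "-2", 3L, 16L)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, colour = cluster,
                                        shape = cluster)) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::scale_colour_manual(values = cols, name = "cluster") +
    ggplot2::scale_shape_manual(values = stats::setNames(shp, lvl),
                                name = "cluster") +
    ggplot2::labs(x = paste(axis_prefix, so[1L]),
                  y = paste(axis_prefix, so[2L]),
                  title = sprintf("batch %d (%s space)", batch$index, space)) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height)
    return(invisible(p))
  }
  p
}

cluster_palette <- function(levels) {
  cols <- stats::setNames(rep("grey40", length(levels)), levels)
  pos <- setdiff(levels, c("-1", "-2"))
  if (length(pos))
    cols[pos] <- grDevices::hcl.colors(max(3L, length(pos)), "Dark 3")[seq_along(pos)]
  if ("-1" %in% levels) cols["-1"] <- "red"
  if ("-2" %in% levels) cols["-2"] <- "black"
  cols
}

#' Per-batch summary of a pipeline run
#'
#' @param calls a `de_calls` object from [run_pipeline()].
#' @param file optional TSV output path.
#' @return A data.frame with one row per batch (`batch`, `n_genes`,
#'   `n_clusters`, `n_mean_outliers`, `n_std_outliers`) plus a `total` row
#'   whose counts equal the column sums and the call-set cardinalities by
#'   stage.
#' @export
summarize_run <- function(calls, file = NULL) {
  bs <- attr(calls, "batch_stats")
  if (is.null(bs))
    stop("calls carry no batch_stats attribute; was this produced by run_pipeline()?")
  bs$batch <- as.character(bs$batch)
  total <- data.frame(batch = "total",
                      n_genes = sum(bs$n_genes),
                      n_clusters = sum(bs$n_clusters),
                      n_mean_outliers = sum(bs$n_mean_outliers),
                      n_std_outliers = sum(bs$n_std_outliers))
  out <- rbind(bs, total)
  if (!is.null(file))
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  out
}
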