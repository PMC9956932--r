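#' Remove genes containing any zero (or non-positive) value
#'
#' The pipeline's first step: a gene is retained only if its expression is
#' strictly positive in every sample, which guarantees the subsequent log
#' transform is defined. No pseudocount is added by default; genes with
#' zeros are dropped outright.
#'
#' @param x a raw-scale `expr_matrix`.
#' @return The matrix restricted to fully positive genes, original gene
#'   order preserved. The number of removed genes is reported via
#'   `message()`.
#' @export
filter_zero_genes <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "raw") stop("filter_zero_genes expects a raw-scale matrix")
  keep <- apply(x$values > 0, 1L, all)
  if (!any(keep)) stop("pipeline error: no genes survive zero filter")
  n_removed <- sum(!keep)
  if (n_removed > 0L)
    message(sprintf("filter_zero_genes: removed %d of %d genes containing zeros",
                    n_removed, length(keep)))
  expression_matrix(x$values[keep, , drop = FALSE], scale = "raw")
}

#' Log-transform an expression matrix
#'
#' @param x a raw-scale `expr_matrix` with strictly positive values (apply
#'   [filter_zero_genes()] first).
#' @param base logarithm base; 2 by default, the transcriptomics
#'   convention. All downstream radius and threshold parameters live on
#'   this log scale, and the base is recorded in call-file headers.
#' @param pseudocount optional offset added before taking logs; 0 by
#'   default (the method drops zero-containing genes instead of offsetting).
#' @return A log-scale `expr_matrix`.
#' @export
log_transform <- function(x, base = 2, pseudocount = 0) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "raw") stop("log_transform expects a raw-scale matrix")
  v <- x$values + pseudocount
  if (any(v <= 0)) {
    bad <- which(v <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "value error: non-positive value at gene '%s' (run filter_zero_genes first)",
      rownames(v)[bad[1L]]))
  }
  expression_matrix(log(v, base = base), scale = "log", log_base = base)
}

#' Aggregate log expression into per-strain mean and standard deviation
#'
#' For every gene and each of the two strains, computes the arithmetic mean
#' and the sample standard deviation (denominator n - 1) of the log
#' expression over that strain's samples. These four numbers per gene are
#' the only quantities the clustering stages ever see.
#'
#' @param x a log-scale `expr_matrix`.
#' @param design a [strain_design()] covering every sample of `x`.
#' @return An `aggregated_profile`: a data.frame with columns `gene_id`,
#'   `mean_1`, `mean_2`, `std_1`, `std_2`, where suffix 1/2 follows
#'   `strain_order(design)` (attached as attribute `strain_order`).
#' @export
aggregate_strains <- function(x, design) {
  stopifnot(inherits(x, "expr_matrix"), inherits(design, "strain_design"))
  if (x$scale != "log") stop("aggregate_strains expects a log-scale matrix")
  missing <- setdiff(sample_ids(x), design$sample_id)
  if (length(missing))
    stop("design error: sample(s) missing from design: ",
         paste(missing, collapse = ", "))
  so <- strain_order(design)
  prof <- data.frame(gene_id = gene_ids(x), stringsAsFactors = FALSE)
  for (k in 1:2) {
    ss <- design$sample_id[design$strain == so[k]]
    ss <- ss[ss %in% sample_ids(x)]
    v <- x$values[, ss, drop = FALSE]
    prof[[paste0("mean_", k)]] <- rowMeans(v)
    prof[[paste0("std_", k)]] <- apply(v, 1L, stats::sd)
  }
  prof <- prof[, c("gene_id", "mean_1", "mean_2", "std_1", "std_2")]
  structure(prof, strain_order = so,
            log_base = x$log_base,
            class = c("aggregated_profile", "data.frame"))
}

#' Extract the 2-D point set of a profile
#'
#' @param profile an `aggregated_profile`.
#' @param space `"mean"` for (mean_1, mean_2), `"std"` for (std_1, std_2).
#' @return A numeric n x 2 matrix.
#' @export
profile_points <- function(profile, space = c("mean", "std")) {
  space <- match.arg(space)
  cols <- paste0(space2prefix(space), c("_1", "_2"))
  m <- as.matrix(profile[, cols])
  rownames(m) <- profile$gene_id
  m
}

space2prefix <- function(space) c(mean = "mean", std = "std")[[space]]

#' Write an aggregated profile as TSV
#' @param profile an `aggregated_profile`.
#' @param path output file path.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
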