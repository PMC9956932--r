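# small fixture builders shared across test files

make_expr <- function(values, genes = NULL, samples = NULL,
                      scale = "raw", log_base = NA_real_) {
  values <- as.matrix(values)
  rownames(values) <- genes %||% paste0("g", seq_len(nrow(values)))
  colnames(values) <- samples %||% paste0("s", seq_len(ncol(values)))
  expression_matrix(values, scale = scale, log_base = log_base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a 2 + 2 design matching make_expr defaults for 4 samples
tiny_design <- function(n1 = 2, n2 = 2) {
  strain_design(paste0("s", seq_len(n1 + n2)),
                rep(c("A", "B"), c(n1, n2)))
}

# random 2-D point cloud
rand_points <- function(n, sd = 1) {
  matrix(stats::rnorm(2 * n, sd = sd), ncol = 2)
}

# random DBSCAN test instance: points, metric, r, n_min
rand_instance <- function(max_n = 50) {
  n <- sample(2:max_n, 1)
  pts <- rand_points(n, sd = sample(c(0.3, 1, 3), 1))
  metric <- if (n >= 3) {
    sample(c("euclidean", "cityblock", "chebyshev", "minkowski",
             "mahalanobis"), 1)
  } else {
    sample(c("euclidean", "cityblock", "chebyshev", "minkowski"), 1)
  }
  spec <- switch(metric,
    minkowski = metric_spec("minkowski", p = sample(c(0.5, 1, 2, 3), 1)),
    mahalanobis = metric_spec("mahalanobis", ridge = 1e-6),
    metric_spec(metric))
  D <- pairwise_distances(pts, spec)
  list(D = D, r = stats::runif(1, 0.05, 2), n_min = sample(1:8, 1))
}
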