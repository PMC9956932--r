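#' Specify a pairwise distance metric
#'
#' The clustering stages operate on precomputed pairwise distance matrices
#' over 2-D point sets. Five metrics are supported. Euclidean, cityblock
#' and Chebyshev are the usual Lp special cases; Minkowski accepts any
#' p > 0, including fractional p < 1, where the formula is still evaluated
#' even though the triangle inequality fails — DBSCAN only requires a
#' symmetric dissimilarity. Mahalanobis whitens by an estimated 2x2
#' covariance, which stretches neighborhoods along the elongated cloud that
#' equally expressed genes form around the equivalence diagonal.
#'
#' @param name one of `"euclidean"`, `"cityblock"`, `"chebyshev"`,
#'   `"minkowski"`, `"mahalanobis"`.
#' @param p Minkowski exponent (> 0); ignored for other metrics.
#' @param covariance_mode for Mahalanobis: `"per_batch"` estimates the
#'   covariance from the points being clustered (default), `"global"` uses
#'   a covariance supplied by the caller (the pipeline estimates it from
#'   all genes), `"identity"` reduces to Euclidean.
#' @param ridge non-negative regularizer added as `ridge * I` to the
#'   covariance; `NULL` (default) uses `1e-8 * trace(C) / 2` so that
#'   near-singular clouds never abort a run.
#' @return A `metric_spec` object.
#' @export
metric_spec <- function(name = c("euclidean", "cityblock", "chebyshev",
                                 "minkowski", "mahalanobis"),
                        p = 2, covariance_mode = c("per_batch", "global",
                                                   "identity"),
                        ridge = NULL) {
  name <- match.arg(name)
  covariance_mode <- match.arg(covariance_mode)
  if (name == "minkowski" && (!is.numeric(p) || length(p) != 1L || p <= 0))
    stop("minkowski exponent p must be a single positive number")
  if (!is.null(ridge) && (!is.numeric(ridge) || ridge < 0))
    stop("ridge must be non-negative")
  structure(list(name = name, p = p, covariance_mode = covariance_mode,
                 ridge = ridge),
            class = "metric_spec")
}

#' @export
print.metric_spec <- function(x, ...) {
  extra <- switch(x$name,
                  minkowski = sprintf(" (p = %g)", x$p),
                  mahalanobis = sprintf(" (covariance = %s)", x$covariance_mode),
                  "")
  cat(sprintf("<metric_spec> %s%s\n", x$name, extra))
  invisible(x)
}

#' Sample covariance of a 2-D point set, with ridge regularization
#'
#' @param points n x 2 numeric matrix, n >= 3.
#' @param ridge non-negative scalar added to the diagonal.
#' @return Symmetric 2 x 2 matrix `cov(points) + ridge * I` (denominator
#'   n - 1); positive definite whenever `ridge > 0`.
#' @export
estimate_covariance <- function(points, ridge = 0) {
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    stop("insufficient points: covariance estimation needs n >= 3")
  stats::cov(points) + ridge * diag(ncol(points))
}

#' Pairwise distance matrix under a metric specification
#'
#' @param points n x 2 numeric matrix, n >= 2, finite.
#' @param spec a [metric_spec()].
#' @param covariance optional 2 x 2 covariance matrix, used when
#'   `spec$covariance_mode == "global"` (ignored otherwise).
#' @return Dense symmetric n x n matrix with zero diagonal.
#' @export
pairwise_distances <- function(points, spec = metric_spec("euclidean"),
                               covariance = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 points")
  if (!all(is.finite(points))) stop("points must be finite")
  stopifnot(inherits(spec, "metric_spec"))
  D <- switch(spec$name,
    euclidean  = stats::dist(points, method = "euclidean"),
    cityblock  = stats::dist(points, method = "manhattan"),
    chebyshev  = stats::dist(points, method = "maximum"),
    minkowski  = stats::dist(points, method = "minkowski", p = spec$p),
    mahalanobis = mahalanobis_dist(points, spec, covariance)
  )
  D <- as.matrix(D)
  diag(D) <- 0
  dimnames(D) <- NULL
  D
}

# whiten by the Cholesky factor of C^-1, then Euclidean distances
mahalanobis_dist <- function(points, spec, covariance) {
  C <- switch(spec$covariance_mode,
    identity  = diag(ncol(points)),
    per_batch = estimate_covariance(points, ridge = 0),
    global    = {
      if (is.null(covariance))
        stop("covariance_mode = 'global' needs a `covariance` argument")
      covariance
    })
  ridge <- spec$ridge
  if (is.null(ridge))   # identity is already well-conditioned; leave it exact
    ridge <- if (spec$covariance_mode == "identity") 0
             else 1e-8 * sum(diag(C)) / ncol(points)
  C <- C + ridge * diag(ncol(points))
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("numerical error: singular covariance; set ridge > 0"))
  R <- tryCatch(chol(Cinv), error = function(e)
    stop("numerical error: covariance not positive definite; set ridge > 0"))
  stats::dist(points %*% t(R), method = "euclidean")
}
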