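#' DBSCAN clustering from a precomputed distance matrix
#'
#' Plain O(n^2) DBSCAN over a dense pairwise distance matrix. The
#' conventions, fixed here because they affect which genes surface as
#' outliers, are: the neighborhood of a point is the closed ball
#' `{j : D[i, j] <= r}` and includes the point itself (so `n_min = 1`
#' makes every point core); clusters are the connected components of core
#' points under mutual r-reachability; a non-core point within `r` of at
#' least one core point (a border point) joins the cluster of the
#' lowest-index such core point, which makes the labeling independent of
#' visit order; all remaining points get label -1 (noise). Cluster ids are
#' renumbered 1..K by the lowest point index each cluster contains. The
#' procedure is fully deterministic.
#'
#' @param D dense symmetric distance matrix with zero diagonal, e.g. from
#'   [pairwise_distances()].
#' @param r neighborhood radius (same units as `D`, i.e. log-expression
#'   units in this pipeline); must be > 0.
#' @param n_min minimum number of neighbors (self included) for a core
#'   point; must be >= 1.
#' @return A `dbscan_labeling`: list with integer vector `labels` (1..K or
#'   -1) and logical vector `core`.
#' @export
dbscan_cluster <- function(D, r, n_min) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D)) stop("D must be square")
  if (!is.numeric(r) || length(r) != 1L || r <= 0) stop("r must be > 0")
  n_min <- as.integer(n_min)
  if (is.na(n_min) || n_min < 1L) stop("n_min must be >= 1")

  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= r))
  core <- lengths(nb) >= n_min

  labels <- integer(n)              # 0 = unassigned
  k <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    k <- k + 1L
    labels[i] <- k
    queue <- i
    while (length(queue)) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      reach <- nb[[j]]
      reach <- reach[core[reach] & labels[reach] == 0L]
      labels[reach] <- k
      queue <- c(queue, reach)
    }
  }

  for (i in which(!core)) {
    cn <- nb[[i]][core[nb[[i]]]]
    labels[i] <- if (length(cn)) labels[min(cn)] else -1L
  }

  labels <- canonical_labels(labels)
  structure(list(labels = labels, core = core), class = "dbscan_labeling")
}

# renumber positive labels 1..K by the lowest member index of each cluster
canonical_labels <- function(labels) {
  pos <- unique(labels[labels > 0L])
  if (!length(pos)) return(labels)
  first_idx <- vapply(pos, function(k) min(which(labels == k)), 1L)
  remap <- integer(max(pos))
  remap[pos[order(first_idx)]] <- seq_along(pos)
  idx <- labels > 0L
  labels[idx] <- remap[labels[idx]]
  labels
}

#' @export
print.dbscan_labeling <- function(x, ...) {
  k <- max(0L, x$labels)
  cat(sprintf("<dbscan_labeling> %d points, %d cluster(s), %d noise\n",
              length(x$labels), k, sum(x$labels == -1L)))
  invisible(x)
}

#' Number of noise points in a labeling
#'
#' Noise points (label -1) are the quantity of interest: in mean space they
#' are the mean-stage differential expression calls.
#'
#' @param labeling a `dbscan_labeling`.
#' @return Integer count of points labeled -1.
#' @export
count_outliers <- function(labeling) {
  stopifnot(inherits(labeling, "dbscan_labeling"))
  sum(labeling$labels == -1L)
}
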