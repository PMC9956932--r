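# Brute-force DBSCAN reference: explicit neighborhood enumeration, core
# components via igraph on the core-core adjacency graph, border points
# attached to their lowest-index core neighbor, clusters renumbered by
# lowest member index. Independent of the package's queue-expansion scan.

oracle_dbscan <- function(D, r, n_min) {
  n <- nrow(D)
  A <- D <= r                         # closed ball, diagonal TRUE
  core <- rowSums(A) >= n_min
  labels <- rep(-1L, n)
  if (any(core)) {
    Acore <- A[core, core, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(Acore, mode = "undirected",
                                             diag = FALSE)
    labels[core] <- as.integer(igraph::components(g)$membership)
    for (i in which(!core)) {
      cn <- which(A[i, ] & core)
      if (length(cn)) labels[i] <- labels[min(cn)]
    }
    pos <- unique(labels[labels > 0L])
    first <- vapply(pos, function(k) min(which(labels == k)), 1L)
    remap <- integer(max(pos))
    remap[pos[order(first)]] <- seq_along(pos)
    idx <- labels > 0L
    labels[idx] <- remap[labels[idx]]
  }
  list(labels = labels, core = core)
}
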