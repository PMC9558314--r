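# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and Qhull where possible).

# All Delaunay edges of a 2D point set by the empty-circumcircle test over
# every triple: an edge belongs to the triangulation iff it is an edge of
# some triangle whose circumcircle contains no other point.
brute_delaunay_edges_2d <- function(pts, tol = 1e-12) {
  n <- nrow(pts)
  edges <- matrix(integer(0), 0, 2)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    cc <- circumcircle(pts[i, ], pts[j, ], pts[k, ])
    if (is.null(cc)) next
    d2 <- rowSums(sweep(pts, 2, cc$center)^2)
    others <- setdiff(seq_len(n), c(i, j, k))
    if (all(d2[others] > cc$r2 * (1 + tol))) {
      edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
    }
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-14) return(NULL)  # collinear
  ux <- ((sum(a^2)) * (b[2] - c[2]) + (sum(b^2)) * (c[2] - a[2]) +
           (sum(c^2)) * (a[2] - b[2])) / d
  uy <- ((sum(a^2)) * (c[1] - b[1]) + (sum(b^2)) * (a[1] - c[1]) +
           (sum(c^2)) * (b[1] - a[1])) / d
  list(center = c(ux, uy), r2 = sum((a - c(ux, uy))^2))
}

# k nearest neighbors by full distance matrix, ties by lower index.
brute_knn_edges <- function(pts, k) {
  n <- nrow(pts)
  edges <- matrix(integer(0), 0, 2)
  for (i in seq_len(n)) {
    d <- sqrt(rowSums(sweep(pts, 2, pts[i, ])^2))
    ord <- order(d, seq_len(n))
    nb <- setdiff(ord, i)[seq_len(k)]
    edges <- rbind(edges, cbind(pmin(i, nb), pmax(i, nb)))
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

# widest (maximin) path value between two nodes over all simple paths
brute_maximin <- function(edges, weights, from, to, n) {
  ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0, n - igraph::vcount(ig)))
  paths <- igraph::all_simple_paths(ig, from, to)
  key <- paste(edges[, 1], edges[, 2])
  wmap <- stats::setNames(weights, key)
  best <- -Inf
  for (p in paths) {
    v <- as.integer(p)
    ek <- paste(pmin(v[-length(v)], v[-1]), pmax(v[-length(v)], v[-1]))
    best <- max(best, min(wmap[ek]))
  }
  best
}

# random connected graph on n nodes (spanning tree + extra edges), seeded
random_connected_graph <- function(n, extra = n, seed = 1) {
  set.seed(seed)
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1, 1), integer(1)))
  more <- t(replicate(extra, sort(sample.int(n, 2))))
  edges <- rbind(cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2])),
                 more)
  edges <- unique(edges[edges[, 1] != edges[, 2], , drop = FALSE])
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# minimal neighborhood_graph straight from an edge list (test-only back door)
graph_from_edges <- function(pts, edges) {
  grid <- topo_grid(pts)
  csr <- gridtopo:::edges_to_csr(edges, grid$n)
  structure(list(grid = grid, edges = edges, adj_ptr = csr$ptr,
                 adj_idx = csr$idx, hull_mask = rep(FALSE, grid$n),
                 construction = "manual", provenance = list()),
            class = "neighborhood_graph")
}

expect_partition <- function(basins, n) {
  expect_length(basins$attractor, n)
  expect_false(anyNA(basins$attractor))
  expect_true(all(basins$attractor %in% basins$local_maxima))
  expect_true(all(basins$attractor[basins$local_maxima] ==
                    basins$local_maxima))
}
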