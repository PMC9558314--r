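#' Neighborhood graphs over point grids
#'
#' A `neighborhood_graph` connects grid points into an undirected graph so
#' that topography (maxima, ascent paths, saddles) can be read off the graph
#' alone. Adjacency is stored in compressed sparse row form (`adj_ptr`,
#' `adj_idx`, 1-based, neighbor lists sorted) together with a per-node
#' convex-hull flag: the analysis of gradient and ascent quality is
#' meaningful only for *bulk* nodes (those not on the hull), so every
#' diagnostic reports bulk-only fractions while hull nodes are still
#' processed.
#'
#' @name neighborhood_graph
NULL

new_graph <- function(grid, edges, hull_mask, construction, provenance = list()) {
  csr <- edges_to_csr(edges, grid$n)
  structure(list(grid = grid, edges = edges,
                 adj_ptr = csr$ptr, adj_idx = csr$idx,
                 hull_mask = hull_mask, construction = construction,
                 provenance = provenance),
            class = "neighborhood_graph")
}

# Edge matrix (m x 2, 1-based, i<j) -> sorted CSR adjacency.
edges_to_csr <- function(edges, n) {
  if (nrow(edges) == 0)
    return(list(ptr = rep(0L, n + 1L), idx = integer(0)))
  from <- c(edges[, 1], edges[, 2])
  to <- c(edges[, 2], edges[, 1])
  o <- order(from, to)
  counts <- tabulate(from, nbins = n)
  list(ptr = c(0L, cumsum(counts)), idx = to[o])
}

#' @export
print.neighborhood_graph <- function(x, ...) {
  cat("<neighborhood_graph> ", x$construction, ": ", x$grid$n, " nodes, ",
      nrow(x$edges), " edges, ", sum(x$hull_mask), " hull nodes\n", sep = "")
  invisible(x)
}

#' Neighbors of one node
#' @param graph a `neighborhood_graph`.
#' @param i node index (1-based).
#' @return sorted integer vector of neighbor indices.
#' @export
neighbors_of <- function(graph, i) {
  graph$adj_idx[(graph$adj_ptr[i] + 1L):graph$adj_ptr[i + 1L]]
}

#' Delaunay neighborhood graph
#'
#' Triangulates the grid (Qhull) and takes the union of simplex edges as the
#' neighborhood graph. A triangulation is connected, undirected, and every
#' bulk node is basis- and move-preserving, which is exactly what on-graph
#' steepest ascent needs; the Delaunay triangulation additionally matches
#' the adjacency of Voronoi cells and avoids oversized neighborhoods.
#'
#' Structured grids (uniform lattices, spherical shells) are cocircular /
#' cospherical and hence degenerate for the empty-circumcircle criterion. A
#' deterministic seeded jitter of `1e-9 * (bounding-box diagonal)` is applied
#' to the coordinates *used for triangulation only*; all downstream geometry
#' uses the original points. The seed is recorded in the graph provenance.
#'
#' In 1D the triangulation degenerates to the sorted chain.
#'
#' @param grid a [topo_grid()].
#' @param jitter_seed integer seed of the degeneracy-breaking jitter.
#' @return a `neighborhood_graph` with construction tag `"delaunay"`.
#' @export
build_delaunay <- function(grid, jitter_seed = 1L) {
  stopifnot(inherits(grid, "topo_grid"))
  d <- grid$dim
  rk <- affine_rank(grid$points)
  if (grid$n < d + 1 || rk < d)
    stop("cannot triangulate: ", grid$n, " points spanning only ", rk,
         " of ", d, " dimensions (need >= d+1 affinely independent points)")
  if (d == 1) {
    o <- order(grid$points[, 1])
    edges <- cbind(o[-grid$n], o[-1])
    edges <- t(apply(edges, 1, sort))
    hull <- rep(FALSE, grid$n)
    hull[o[c(1, grid$n)]] <- TRUE
    return(new_graph(grid, edges, hull, "delaunay",
                     list(jitter_seed = jitter_seed, jitter = 0)))
  }
  bbox_diag <- sqrt(sum((apply(grid$points, 2, max) - apply(grid$points, 2, min))^2))
  mag <- 1e-9 * bbox_diag
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(jitter_seed)
  jit <- matrix(runif(grid$n * d, -mag, mag), ncol = d)
  res <- tryCatch(qhull()$delaunay_edges(grid$points + jit),
                  error = function(e) {
                    # highly structured grids can exceed Qhull's merge
                    # tolerance even after jittering; retry with Qhull's own
                    # deterministic joggle
                    qhull()$delaunay_edges(grid$points + jit, "QJ")
                  })
  edges <- res[[1]] + 1L
  storage.mode(edges) <- "integer"
  hull <- rep(FALSE, grid$n)
  hull[res[[2]] + 1L] <- TRUE
  new_graph(grid, edges, hull, "delaunay",
            list(jitter_seed = jitter_seed, jitter = mag,
                 nsimplex = res[[3]]))
}

#' k-nearest-neighbor graph
#'
#' Connects `i` and `j` iff `j` is among the `k` nearest neighbors of `i`
#' *or* vice versa (the reverse condition makes the graph undirected).
#' Provided chiefly to demonstrate its failure modes: such graphs may be
#' disconnected and bulk nodes need not be move-preserving, which introduces
#' fictitious local maxima and minima. Distance ties are broken by lower
#' node index.
#'
#' @param grid a [topo_grid()].
#' @param k number of neighbors, `1 <= k < n`.
#' @return a `neighborhood_graph` with construction tag `"knn(k)"`.
#' @export
build_knn <- function(grid, k) {
  stopifnot(inherits(grid, "topo_grid"))
  k <- as.integer(k)
  if (k < 1 || k >= grid$n)
    stop("k must satisfy 1 <= k < n (n = ", grid$n, "), got ", k)
  n <- grid$n
  # query extra candidates so exact distance ties resolve by index, not by
  # kd-tree traversal order
  kq <- min(n, k + 8L)
  nn <- RANN::nn2(grid$points, grid$points, k = kq)
  from <- integer(0); to <- integer(0)
  sel <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    cand_idx <- nn$nn.idx[i, ]
    cand_d <- nn$nn.dists[i, ]
    keep <- cand_idx != i
    cand_idx <- cand_idx[keep]; cand_d <- cand_d[keep]
    o <- order(cand_d, cand_idx)
    sel[i, ] <- cand_idx[o][seq_len(k)]
  }
  edges <- cbind(rep(seq_len(n), k), as.vector(sel))
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- unique(edges)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  storage.mode(edges) <- "integer"
  hull <- hull_mask_of(grid)
  new_graph(grid, edges, hull, sprintf("knn(%d)", k), list(k = k))
}

# Convex-hull vertex mask for any grid.
hull_mask_of <- function(grid) {
  hull <- rep(FALSE, grid$n)
  if (grid$dim == 1) {
    hull[c(which.min(grid$points[, 1]), which.max(grid$points[, 1]))] <- TRUE
  } else {
    hull[qhull()$hull_vertices(grid$points) + 1L] <- TRUE
  }
  hull
}

#' Validate a neighborhood graph
#'
#' Diagnostic report of the four requirements a neighborhood graph should
#' meet for faithful topography: connectedness, undirectedness, and - over
#' bulk (non-hull) nodes only - the basis-preserving property (neighbor
#' displacements span all `d` directions, so a least-squares gradient
#' exists) and the move-preserving property (every direction has a neighbor
#' with positive projection, so the gradient can be followed). The
#' move-preserving test checks that the origin lies strictly inside the
#' convex hull of the unit displacement vectors.
#'
#' Never raises: intended for diagnosing constructions that are *expected*
#' to fail (k-nearest-neighbor graphs).
#'
#' @param graph a `neighborhood_graph`.
#' @return list with `connected`, `undirected`, `basis_preserving_fraction`,
#'   `move_preserving_fraction` (fractions over bulk nodes; `NaN` if the
#'   graph has no bulk).
#' @export
validate_graph <- function(graph) {
  stopifnot(inherits(graph, "neighborhood_graph"))
  n <- graph$grid$n; d <- graph$grid$dim
  ig <- igraph::graph_from_edgelist(graph$edges, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, n - igraph::vcount(ig)))
  connected <- igraph::is_connected(ig)
  bulk <- which(!graph$hull_mask)
  if (length(bulk) == 0)
    return(list(connected = connected, undirected = TRUE,
                basis_preserving_fraction = NaN,
                move_preserving_fraction = NaN))
  basis_ok <- vapply(bulk, function(i) {
    nb <- neighbors_of(graph, i)
    if (length(nb) < d) return(FALSE)
    diffs <- graph$grid$points[nb, , drop = FALSE] -
      matrix(graph$grid$points[i, ], length(nb), d, byrow = TRUE)
    qr(diffs, tol = 1e-10)$rank == d
  }, logical(1))
  if (d == 1) {
    move_ok <- vapply(bulk, function(i) {
      nb <- neighbors_of(graph, i)
      dx <- graph$grid$points[nb, 1] - graph$grid$points[i, 1]
      any(dx > 0) && any(dx < 0)
    }, logical(1))
  } else {
    move_ok <- qhull()$move_preserving_mask(
      graph$grid$points, graph$adj_ptr, graph$adj_idx - 1L, bulk - 1L)
  }
  list(connected = connected,
       undirected = TRUE,  # guaranteed by the symmetric CSR construction
       basis_preserving_fraction = mean(basis_ok),
       move_preserving_fraction = mean(move_ok))
}

#' Nearest grid point lookup
#'
#' Maps arbitrary query points to their nearest grid point (Euclidean),
#' through a kd-tree; exact distance ties resolve to the lowest node index.
#' This lookup defines the nearest-neighbor interpolant of a field and the
#' Voronoi-cell membership used by the off-graph ascent.
#'
#' @param grid a [topo_grid()].
#' @param query numeric vector (one point) or matrix (n x d) of queries.
#' @return integer vector of grid indices, one per query.
#' @export
nearest_grid_point <- function(grid, query) {
  stopifnot(inherits(grid, "topo_grid"))
  if (is.null(dim(query))) query <- matrix(query, ncol = grid$dim)
  stopifnot(ncol(query) == grid$dim)
  kq <- min(grid$n, 8L)
  nn <- RANN::nn2(grid$points, query, k = kq)
  if (kq == 1L) return(nn$nn.idx[, 1])
  apply_tie_break(nn$nn.idx, nn$nn.dists)
}

# lowest index among candidates within relative tolerance of the minimum distance
apply_tie_break <- function(idx, dists) {
  dmin <- dists[, 1]
  tol <- dmin * 1e-12 + 1e-300
  out <- integer(nrow(idx))
  for (q in seq_len(nrow(idx))) {
    tied <- idx[q, dists[q, ] <= dmin[q] + tol[q]]
    out[q] <- min(tied)
  }
  out
}
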