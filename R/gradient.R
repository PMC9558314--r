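#' Least-squares gradient on a neighborhood graph
#'
#' Approximates the field gradient at every node from neighborhood data
#' alone, by minimizing the residual norm of a first-order Taylor expansion
#' over the neighbors: the normal equations `M g = b` with
#' `M = sum (y-x)(y-x)^T` and `b = sum (y-x)(f(y)-f(x))`. On a
#' basis-preserving node `M` has full rank and `g` is unique; exact for
#' affine fields. Where `M` is rank-deficient (possible on hull nodes or
#' pathological neighborhoods) the minimum-norm solution restricted to the
#' spanned subspace is returned and the node is flagged in `singular_mask`
#' rather than raising: poor hull neighborhoods must not abort a whole-grid
#' analysis.
#'
#' The residual norm is unweighted. A inverse-square distance weighting is
#' available (`weighting = "inv_dist2"`) but off by default.
#'
#' @param graph a `neighborhood_graph`.
#' @param field a [scalar_field()] on the graph's grid.
#' @param weighting `"none"` (default) or `"inv_dist2"`.
#' @return object of class `gradient_field`: `vectors` (n x d matrix, field
#'   units per bohr) and `singular_mask`.
#' @export
ls_gradient <- function(graph, field, weighting = c("none", "inv_dist2")) {
  stopifnot(inherits(graph, "neighborhood_graph"))
  weighting <- match.arg(weighting)
  field <- as_field(field, graph$grid$n)
  pts <- graph$grid$points
  if (weighting == "inv_dist2") {
    res <- ls_gradient_weighted(graph, field)
  } else {
    res <- cpp_ls_gradient(pts, graph$adj_ptr, graph$adj_idx - 1L, field$values)
  }
  structure(list(vectors = res$vectors, singular_mask = res$singular_mask,
                 grid = graph$grid),
            class = "gradient_field")
}

# Plain-R weighted variant (rarely used; kept in R for clarity).
ls_gradient_weighted <- function(graph, field) {
  n <- graph$grid$n; d <- graph$grid$dim
  vectors <- matrix(0, n, d)
  singular <- logical(n)
  for (i in seq_len(n)) {
    nb <- neighbors_of(graph, i)
    dy <- graph$grid$points[nb, , drop = FALSE] -
      matrix(graph$grid$points[i, ], length(nb), d, byrow = TRUE)
    df <- field$values[nb] - field$values[i]
    w <- 1 / rowSums(dy^2)
    M <- crossprod(dy * sqrt(w))
    b <- colSums(dy * (w * df))
    e <- eigen(M, symmetric = TRUE)
    pos <- e$values > max(e$values, 0) * 1e-10
    singular[i] <- sum(pos) < d
    g <- rep(0, d)
    for (k in which(pos))
      g <- g + e$vectors[, k] * sum(e$vectors[, k] * b) / e$values[k]
    vectors[i, ] <- g
  }
  list(vectors = vectors, singular_mask = singular)
}

#' @export
print.gradient_field <- function(x, ...) {
  cat("<gradient_field> ", nrow(x$vectors), " nodes, ",
      sum(x$singular_mask), " singular\n", sep = "")
  invisible(x)
}

#' Nearest-neighbor gradient field
#'
#' Evaluates the piecewise-constant extension of the node gradients to all
#' of space: a query point takes the gradient of its nearest grid node, so
#' the field is constant on each Voronoi cell. This is the vector field the
#' off-graph (bias-corrected) ascent integrates.
#'
#' @param grid a [topo_grid()].
#' @param gradients a `gradient_field` from [ls_gradient()].
#' @param query one point (vector) or several (matrix, n x d).
#' @return matrix (n_query x d) of gradients; attribute `"singular"` flags
#'   queries whose nearest node had a rank-deficient neighborhood (the
#'   restricted gradient is still returned).
#' @export
nn_gradient <- function(grid, gradients, query) {
  idx <- nearest_grid_point(grid, query)
  out <- gradients$vectors[idx, , drop = FALSE]
  sing <- gradients$singular_mask[idx]
  if (any(sing))
    warning(sum(sing), " query point(s) map to nodes with rank-deficient ",
            "neighborhoods; restricted gradients returned")
  attr(out, "singular") <- sing
  out
}
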