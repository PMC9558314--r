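#' Graph local maxima
#'
#' Nodes whose field value strictly exceeds that of every neighbor. These
#' are the on-graph representatives of the maxima of the underlying
#' function; on a triangulation of a sufficiently dense grid there is
#' exactly one per point-like maximum, while poorer constructions
#' (k-nearest-neighbor graphs) introduce fictitious ones. A constant field
#' has no graph local maxima: the inequality is strict.
#'
#' @param graph a `neighborhood_graph`.
#' @param field a [scalar_field()] on the graph's grid.
#' @return integer vector of node indices, ascending.
#' @export
local_maxima <- function(graph, field) {
  stopifnot(inherits(graph, "neighborhood_graph"))
  field <- as_field(field, graph$grid$n)
  sort(cpp_local_maxima(graph$adj_ptr, graph$adj_idx - 1L, field$values) + 1L)
}

new_basin_assignment <- function(attractor, method) {
  structure(list(attractor = attractor,
                 local_maxima = sort(unique(attractor)),
                 method = method),
            class = "basin_assignment")
}

#' @export
print.basin_assignment <- function(x, ...) {
  cat("<basin_assignment> (", x$method, ") ", length(x$attractor),
      " nodes in ", length(x$local_maxima), " basins\n", sep = "")
  invisible(x)
}

#' Basin assignment by on-graph steepest ascent
#'
#' Assigns every node to the basin of attraction of a graph local maximum by
#' repeatedly stepping to the neighbor maximizing the slope
#' `(f(y) - f(x)) / |y - x|`. A path that touches an already-assigned node
#' adopts that node's attractor (shortcutting), which leaves results
#' unchanged while avoiding re-tracing shared ascent tails. Slope ties break
#' to the lower node index, so the assignment is fully deterministic;
#' plateau steps are only taken toward lower indices, which guarantees
#' termination. Assignments are invariant under positive affine rescaling of
#' the field.
#'
#' @param graph a `neighborhood_graph`.
#' @param field a [scalar_field()] on the graph's grid.
#' @param shortcut logical; `FALSE` re-traces every path fully (slow oracle
#'   mode used in validation).
#' @return object of class `basin_assignment`: `attractor` (per-node index
#'   of its local maximum), `local_maxima`, `method`.
#' @export
assign_basins_on_graph <- function(graph, field, shortcut = TRUE) {
  stopifnot(inherits(graph, "neighborhood_graph"))
  field <- as_field(field, graph$grid$n)
  if (length(cpp_local_maxima(graph$adj_ptr, graph$adj_idx - 1L, field$values)) == 0)
    stop("field has no graph local maxima")
  att <- cpp_assign_basins(graph$grid$points, graph$adj_ptr,
                           graph$adj_idx - 1L, field$values, shortcut) + 1L
  new_basin_assignment(att, "on_graph")
}

#' Basin assignment by bias-corrected off-graph ascent
#'
#' On-graph ascent suffers a *grid bias*: paths constrained to graph edges
#' drift systematically from the true gradient path, distorting basin
#' boundaries even in the infinite-density limit. This method instead lets
#' each trajectory move freely in space, following the nearest-neighbor
#' gradient field (piecewise constant on Voronoi cells, built from the
#' least-squares node gradients) with a fixed step, until it enters the
#' Voronoi cell of a local maximum or of an already-assigned node; the seed
#' node then adopts that attractor.
#'
#' The step length adapts to local grid density: `step_scale` times the
#' median length of the edges at the trajectory's current nearest node
#' (quadrature grids for molecules are radially graded, so a global step
#' would be wrong almost everywhere). Trajectories exceeding the step cap
#' (degenerate flat regions) fall back to on-graph ascent from their seed,
#' with a warning.
#'
#' @param graph a `neighborhood_graph`.
#' @param field a [scalar_field()] on the graph's grid.
#' @param gradients optional `gradient_field`; computed via [ls_gradient()]
#'   if missing.
#' @param step_scale step length as a fraction of the local median edge
#'   length.
#' @param step_cap maximum steps per trajectory; default `10 * n^(1/d)`.
#' @return object of class `basin_assignment` with `method = "off_graph"`.
#' @export
assign_basins_off_graph <- function(graph, field, gradients = NULL,
                                    step_scale = 0.5, step_cap = NULL) {
  stopifnot(inherits(graph, "neighborhood_graph"))
  field <- as_field(field, graph$grid$n)
  n <- graph$grid$n; d <- graph$grid$dim
  pts <- graph$grid$points
  if (is.null(gradients)) gradients <- ls_gradient(graph, field)
  if (is.null(step_cap)) step_cap <- ceiling(10 * n^(1 / d))
  maxima <- local_maxima(graph, field)
  if (length(maxima) == 0) stop("field has no graph local maxima")

  # median incident edge length per node
  elen <- sqrt(rowSums((pts[graph$edges[, 1], , drop = FALSE] -
                        pts[graph$edges[, 2], , drop = FALSE])^2))
  med_len <- vapply(split(c(elen, elen), c(graph$edges[, 1], graph$edges[, 2])),
                    median, numeric(1))[as.character(seq_len(n))]
  med_len[is.na(med_len)] <- mean(elen)

  attractor <- rep(NA_integer_, n)
  attractor[maxima] <- maxima
  seeds <- which(is.na(attractor))
  pos <- pts[seeds, , drop = FALSE]
  cur <- seeds                      # nearest node of each live trajectory
  live <- seq_along(seeds)
  steps <- 0L
  g <- gradients$vectors
  while (length(live) > 0 && steps < step_cap) {
    # finish trajectories whose current cell owner is assigned
    done <- !is.na(attractor[cur])
    if (any(done)) {
      attractor[seeds[live[done]]] <- attractor[cur[done]]
      live <- live[!done]; pos <- pos[!done, , drop = FALSE]; cur <- cur[!done]
      if (length(live) == 0) break
    }
    dir <- g[cur, , drop = FALSE]
    nrm <- sqrt(rowSums(dir^2))
    stuck <- nrm == 0
    if (any(stuck)) {
      # zero nearest-neighbor gradient: leave for the on-graph fallback
      live_keep <- !stuck
      live <- live[live_keep]; pos <- pos[live_keep, , drop = FALSE]
      cur <- cur[live_keep]; dir <- dir[live_keep, , drop = FALSE]
      nrm <- nrm[live_keep]
      if (length(live) == 0) break
    }
    pos <- pos + dir / nrm * (step_scale * med_len[cur])
    cur <- RANN::nn2(pts, pos, k = 1)$nn.idx[, 1]
    steps <- steps + 1L
  }
  if (any(is.na(attractor))) {
    pending <- which(is.na(attractor))
    warning(length(pending), " trajectory(ies) exceeded the step cap or ",
            "stalled; falling back to on-graph ascent for those seeds")
    on_g <- cpp_assign_basins(pts, graph$adj_ptr, graph$adj_idx - 1L,
                              field$values, TRUE) + 1L
    attractor[pending] <- on_g[pending]
  }
  new_basin_assignment(attractor, "off_graph")
}

#' Cluster local maxima into maxima families
#'
#' A maxima family is a connected, locally maximal region: a point-like peak
#' gives a singleton family, while extended structures (rings, shells,
#' isosurfaces) are represented by many graph local maxima of nearly equal
#' value that belong together. Around each local maximum `x` a flood fill
#' collects the connected nodes within tolerance of it under the deviation
#' measure `d(x, y) = (f(x) - f(y)) / (f(x) - f_min)` - the fractional drop
#' in the function value on the way from `x` down to the global minimum
#' value `f_min`, so `d` is in `[0, 1]` regardless of the scale of `f` and
#' regions around smaller maxima are automatically smaller. Overlapping
#' flood fills are merged transitively; the merged groups are the families.
#'
#' @param graph a `neighborhood_graph`.
#' @param field a [scalar_field()] on the graph's grid.
#' @param basins a `basin_assignment` for the same graph/field.
#' @param t tolerance in (0, 1]; nodes with `d(x, y) < t` join the fill of
#'   `x`. The default 0.25 resolves well-separated peaks while still fusing
#'   ring- and shell-like maxima.
#' @return object of class `maxima_families`: `family_of` (named map from
#'   local-maximum index to family id), `families` (list of maxima-index
#'   sets), `flood_fills` (per family, covered grid nodes), `tolerance`.
#'   Family ids are ordered by descending attractor field value, then node
#'   index.
#' @export
cluster_maxima_families <- function(graph, field, basins, t = 0.25) {
  stopifnot(inherits(graph, "neighborhood_graph"),
            inherits(basins, "basin_assignment"))
  field <- as_field(field, graph$grid$n)
  if (!is.numeric(t) || length(t) != 1 || t <= 0 || t > 1)
    stop("family tolerance t must lie in (0, 1], got ", format(t))
  maxima <- basins$local_maxima
  res <- cpp_flood_families(graph$adj_ptr, graph$adj_idx - 1L, field$values,
                            maxima - 1L, t, min(field$values))
  root <- res$family_root + 1L           # per-maximum merged-fill root
  groups <- split(seq_along(maxima), root)
  # order families by (descending max field value, ascending node index)
  fmax <- vapply(groups, function(ix) max(field$values[maxima[ix]]), numeric(1))
  fnode <- vapply(groups, function(ix) min(maxima[ix]), numeric(1))
  ord <- order(-fmax, fnode)
  groups <- groups[ord]
  families <- lapply(groups, function(ix) maxima[ix])
  fills <- lapply(groups, function(ix)
    sort(unique(unlist(res$fills[ix]))) + 1L)
  family_of <- integer(length(maxima))
  for (fid in seq_along(groups)) family_of[groups[[fid]]] <- fid
  names(family_of) <- maxima
  structure(list(family_of = family_of, families = unname(families),
                 flood_fills = unname(fills), tolerance = t),
            class = "maxima_families")
}

#' @export
print.maxima_families <- function(x, ...) {
  cat("<maxima_families> ", length(x$family_of), " local maxima in ",
      length(x$families), " families (t = ", x$tolerance, ")\n", sep = "")
  invisible(x)
}

#' Integrate a field over basins of attraction
#'
#' Accumulates `Q_M = sum over {x : A(x) in M} of w(x) * rho(x)` per maxima
#' family `M`: the Bader charge when `rho` is the electron density, but the
#' integrand may differ from the field that defined the basins (e.g. a
#' kinetic-energy density integrated over density basins). Because basins
#' partition the grid, the family totals always sum to the plain quadrature
#' total `sum(w * rho)` exactly.
#'
#' @param basins a `basin_assignment`.
#' @param families a `maxima_families`, or `NULL` to treat every local
#'   maximum as its own family.
#' @param field the `scalar_field` to integrate.
#' @param grid the [topo_grid()] carrying integration weights.
#' @param voronoi_fallback if the grid has no weights, use Monte-Carlo
#'   Voronoi cell volumes clipped to the convex hull ([voronoi_weights()]);
#'   set `FALSE` to make missing weights an error.
#' @return named numeric vector of integrals, one per family id.
#' @export
integrate_basins <- function(basins, families, field, grid,
                             voronoi_fallback = TRUE) {
  stopifnot(inherits(basins, "basin_assignment"), inherits(grid, "topo_grid"))
  field <- as_field(field, grid$n)
  w <- grid$weights
  if (is.null(w)) {
    if (!voronoi_fallback)
      stop("grid has no integration weights and the Voronoi-volume fallback ",
           "is disabled")
    w <- voronoi_weights(grid)
  }
  if (is.null(families)) {
    fam_of_max <- setNames(seq_along(basins$local_maxima), basins$local_maxima)
  } else {
    stopifnot(inherits(families, "maxima_families"))
    fam_of_max <- families$family_of
  }
  fam_of_node <- fam_of_max[as.character(basins$attractor)]
  nfam <- max(fam_of_max)
  q <- vapply(seq_len(nfam), function(fid)
    sum(w[fam_of_node == fid] * field$values[fam_of_node == fid]), numeric(1))
  setNames(q, seq_len(nfam))
}
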