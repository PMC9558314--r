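#' Critical networks: maximum spanning tree, pruning, gap-filling, cleaving
#'
#' A *critical path* between two local maxima is the path that maximizes the
#' minimum field value encountered (the path's *critical value*); its lowest
#' node plays the role of the first-order saddle - in Bader analysis, the
#' bond critical point on a bond path. With edge weights set to the mean of
#' the endpoint values, critical paths are exactly the widest (maximin)
#' paths, all of which live on the maximum spanning tree. Pruning the tree
#' of non-maximum leaves yields the *critical tree*; gap-filling restores
#' near-degenerate alternative links (ring closures) to produce the full
#' *critical network*; cleaving removes paths along which the field dips
#' strongly, isolating subtrees of nearly constant value (stagnation lines).
#'
#' @name critical_network
NULL

new_critical_network <- function(n, edges, filled, maxima, critical_points,
                                 provenance) {
  structure(list(n = n, edges = edges, filled = filled, maxima = maxima,
                 critical_points = critical_points, provenance = provenance),
            class = "critical_network")
}

#' @export
print.critical_network <- function(x, ...) {
  cat("<critical_network> ", nrow(x$edges), " edges (", sum(x$filled),
      " gap-filled), ", length(x$maxima), " maxima, ",
      nrow(x$critical_points), " critical points [",
      paste(names(Filter(isTRUE, x$provenance)), collapse = ", "), "]\n",
      sep = "")
  invisible(x)
}

#' Maximum spanning tree under mean-endpoint edge weights
#'
#' @param graph a connected `neighborhood_graph`.
#' @param field a [scalar_field()] on its grid.
#' @return integer matrix (n-1 x 2) of tree edges. Ties in edge weight are
#'   broken lexicographically by edge index, so symmetric fields (benzene
#'   rings) give reproducible trees.
#' @export
max_spanning_tree <- function(graph, field) {
  stopifnot(inherits(graph, "neighborhood_graph"))
  field <- as_field(field, graph$grid$n)
  w <- (field$values[graph$edges[, 1]] + field$values[graph$edges[, 2]]) / 2
  res <- cpp_max_spanning_tree(graph$edges - 1L, w, graph$grid$n)
  if (res$n_components > 1)
    stop("graph is disconnected (", res$n_components,
         " components); a spanning tree requires a connected graph")
  graph$edges[res$edge_idx + 1L, , drop = FALSE]
}

#' Prune a spanning tree to the critical tree
#'
#' Iteratively removes leaf nodes that are not local maxima until every leaf
#' is a maximum. What remains is the union of all critical paths. For every
#' maxima pair connected without passing through a third maximum, the
#' minimum-value node on the connecting path is recorded as that pair's
#' critical point.
#'
#' @param tree edge matrix from [max_spanning_tree()] (any spanning tree of
#'   the grid's graph).
#' @param field the [scalar_field()] used to build the tree.
#' @param maxima integer vector of local-maximum node indices (non-empty).
#' @return a `critical_network` (acyclic, contains every maximum).
#' @export
prune_to_critical_tree <- function(tree, field, maxima) {
  field <- as_field(field)
  n <- length(field$values)
  stopifnot(length(maxima) > 0)
  is_max <- rep(FALSE, n); is_max[maxima] <- TRUE
  keep <- cpp_prune_leaves(n, tree - 1L, is_max)
  kept_edges <- tree[keep[tree[, 1]] & keep[tree[, 2]], , drop = FALSE]
  net <- new_critical_network(
    n, kept_edges, filled = rep(FALSE, nrow(kept_edges)),
    maxima = sort(maxima), critical_points = NULL,
    provenance = list(pruned_tree = TRUE, gap_filled = FALSE, cleaved = FALSE))
  net$critical_points <- critical_points_of(net, field)
  net
}

# Critical points per maxima pair joined on the current network without an
# interior maximum: node of minimum field value along the connecting path.
critical_points_of <- function(net, field) {
  paths <- cpp_critical_paths(net$n, net$edges - 1L, net$maxima - 1L)
  if (length(paths) == 0)
    return(data.frame(from = integer(0), to = integer(0), node = integer(0),
                      value = numeric(0), filled = logical(0)))
  recs <- lapply(paths, function(p) {
    nodes <- p$path + 1L
    k <- which.min(field$values[nodes])
    data.frame(from = p$from + 1L, to = p$to + 1L, node = nodes[k],
               value = field$values[nodes[k]], filled = FALSE)
  })
  out <- do.call(rbind, recs)
  out[order(out$from, out$to), , drop = FALSE]
}

#' Close near-degenerate cycles in a critical tree (gap-filling)
#'
#' A spanning tree is acyclic, so when two routes between maxima have nearly
#' equal critical values (the two ways around an aromatic ring) exactly one
#' is kept and one bond goes missing. Gap-filling recovers such links: for
#' every maxima pair whose connecting path on the current network crosses
#' more than two basins, but whose basins are adjacent in the full graph,
#' the maximum spanning tree of the two-basin subgraph proposes a candidate
#' path; it is accepted iff it stays clear of the subgraph boundary (a path
#' forced onto the boundary has its lowest point at the rim of the shared
#' interface, the signature of a non-critical link). Accepted edges are
#' flagged `filled`; gap-filling never removes an edge.
#'
#' @param network a `critical_network` from [prune_to_critical_tree()].
#' @param graph the full `neighborhood_graph`.
#' @param field the [scalar_field()].
#' @param basins `basin_assignment` computed on the same graph.
#' @return the augmented `critical_network`.
#' @export
gap_fill <- function(network, graph, field, basins) {
  stopifnot(inherits(network, "critical_network"),
            inherits(graph, "neighborhood_graph"),
            inherits(basins, "basin_assignment"))
  field <- as_field(field, graph$grid$n)
  att <- basins$attractor
  maxima <- network$maxima
  # basin-pair adjacency from full-graph edges
  ea <- att[graph$edges[, 1]]; eb <- att[graph$edges[, 2]]
  cross <- ea != eb
  adj_pairs <- unique(cbind(pmin(ea[cross], eb[cross]),
                            pmax(ea[cross], eb[cross])))
  adj_key <- paste(adj_pairs[, 1], adj_pairs[, 2])
  edges <- network$edges
  filled <- network$filled
  new_cps <- list()
  # maxima pairs already joined by an interior-maximum-free path
  direct_paths <- cpp_critical_paths(network$n, edges - 1L, maxima - 1L)
  ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, network$n - igraph::vcount(ig)))
  for (i in seq_along(maxima)) {
    for (j in seq_along(maxima)) {
      if (j <= i) next
      x <- maxima[i]; y <- maxima[j]
      # step 3: already critically linked if the pair is joined on the
      # current network either (a) within two basins, or (b) by a path free
      # of interior maxima - (b) guards against duplicate links when a few
      # misassigned nodes put a third basin label onto a genuine direct path
      sp <- suppressWarnings(
        igraph::shortest_paths(ig, x, y, mode = "all")$vpath[[1]])
      if (length(sp) > 0 &&
          length(unique(att[as.integer(sp)])) <= 2) next
      if (any(vapply(direct_paths, function(p)
            (p$from + 1L) == min(x, y) && (p$to + 1L) == max(x, y),
            logical(1)))) next
      # step 5: basins must be adjacent
      bx <- att[x]; by <- att[y]
      if (!(paste(min(bx, by), max(bx, by)) %in% adj_key)) next
      # steps 6-7: two-basin subgraph, its MST, the x-y path on it
      sub_nodes <- which(att == bx | att == by)
      node_id <- integer(network$n); node_id[sub_nodes] <- seq_along(sub_nodes)
      in_sub <- node_id > 0
      se <- graph$edges[in_sub[graph$edges[, 1]] & in_sub[graph$edges[, 2]], ,
                        drop = FALSE]
      sw <- (field$values[se[, 1]] + field$values[se[, 2]]) / 2
      sub_edges <- cbind(node_id[se[, 1]], node_id[se[, 2]])
      mst <- cpp_max_spanning_tree(sub_edges - 1L, sw, length(sub_nodes))
      tree_e <- sub_edges[mst$edge_idx + 1L, , drop = FALSE]
      sg <- igraph::graph_from_edgelist(tree_e, directed = FALSE)
      sg <- igraph::add_vertices(sg, max(0L, length(sub_nodes) - igraph::vcount(sg)))
      pxy <- suppressWarnings(
        igraph::shortest_paths(sg, node_id[x], node_id[y], mode = "all")$vpath[[1]])
      if (length(pxy) == 0) next   # basins touch but subgraph tree disconnected
      path_nodes <- sub_nodes[as.integer(pxy)]
      # step 8: reject if the path touches the subgraph boundary
      boundary <- vapply(path_nodes, function(z) {
        any(!in_sub[neighbors_of(graph, z)])
      }, logical(1))
      if (any(boundary)) next
      # step 9: fill the gap
      pe <- cbind(pmin(path_nodes[-length(path_nodes)], path_nodes[-1]),
                  pmax(path_nodes[-length(path_nodes)], path_nodes[-1]))
      have <- paste(edges[, 1], edges[, 2])
      is_new <- !(paste(pe[, 1], pe[, 2]) %in% have)
      if (any(is_new)) {
        edges <- rbind(edges, pe[is_new, , drop = FALSE])
        filled <- c(filled, rep(TRUE, sum(is_new)))
        ig <- igraph::add_edges(ig, t(pe[is_new, , drop = FALSE]))
      }
      k <- which.min(field$values[path_nodes])
      new_cps[[length(new_cps) + 1]] <-
        data.frame(from = min(x, y), to = max(x, y), node = path_nodes[k],
                   value = field$values[path_nodes[k]], filled = TRUE)
      direct_paths[[length(direct_paths) + 1]] <-
        list(from = min(x, y) - 1L, to = max(x, y) - 1L)
    }
  }
  cps <- rbind(network$critical_points, do.call(rbind, new_cps))
  cps <- cps[order(cps$from, cps$to), , drop = FALSE]
  net <- new_critical_network(network$n, edges, filled, maxima, cps,
                              modifyList(network$provenance,
                                         list(gap_filled = TRUE)))
  net
}

#' Cleave non-flat critical paths
#'
#' Splits the critical network into subtrees within which the field varies
#' only weakly. Per critical path between maxima `x` and `y`, node values
#' are rescaled as `s(z) = (f(z) - f_min) / (f_scale - f_min)` with
#' `f_scale = max(f(x), f(y))` and `f_min` the global minimum over the grid,
#' so the larger endpoint sits at `s = 1`. The path's deviation is
#' `1 - min s` along it (option `stat = "mean"` uses the mean of `1 - s`
#' instead); paths with deviation at or above `t_flat` are removed. On a
#' flat field (`f_scale == f_min`) the deviation is defined as 0.
#'
#' `t_flat = "auto"` places the threshold at the first local minimum of a
#' Gaussian kernel density estimate (Scott bandwidth) of the deviation
#' distribution, separating the flat mode near 0 from the rest; if the
#' estimate is unimodal the threshold falls back to 0.1.
#'
#' @param network a `critical_network`.
#' @param field the full-grid [scalar_field()].
#' @param t_flat numeric threshold in (0, 1] or `"auto"`.
#' @param stat path deviation statistic: `"min"` (default) or `"mean"`.
#' @return the cleaved `critical_network` (never gains edges).
#' @export
cleave <- function(network, field, t_flat = "auto", stat = c("min", "mean")) {
  stopifnot(inherits(network, "critical_network"))
  stat <- match.arg(stat)
  field <- as_field(field)
  fmin <- min(field$values)
  paths <- cpp_critical_paths(network$n, network$edges - 1L,
                              network$maxima - 1L)
  if (length(paths) == 0) return(network)
  devs <- vapply(paths, function(p) {
    nodes <- p$path + 1L
    f_scale <- max(field$values[nodes[1]], field$values[nodes[length(nodes)]])
    if (f_scale == fmin) return(0)
    s <- (field$values[nodes] - fmin) / (f_scale - fmin)
    if (stat == "min") 1 - min(s) else mean(1 - s)
  }, numeric(1))
  if (identical(t_flat, "auto")) t_flat <- auto_flat_tolerance(devs)
  stopifnot(is.numeric(t_flat), length(t_flat) == 1, t_flat > 0)
  drop_edges <- character(0)
  for (k in which(devs >= t_flat)) {
    nodes <- paths[[k]]$path + 1L
    pe <- cbind(pmin(nodes[-length(nodes)], nodes[-1]),
                pmax(nodes[-length(nodes)], nodes[-1]))
    drop_edges <- c(drop_edges, paste(pe[, 1], pe[, 2]))
  }
  key <- paste(network$edges[, 1], network$edges[, 2])
  keep <- !(key %in% drop_edges)
  net <- new_critical_network(
    network$n, network$edges[keep, , drop = FALSE], network$filled[keep],
    network$maxima, network$critical_points,
    modifyList(network$provenance, list(cleaved = TRUE,
                                        t_flat = t_flat)))
  net$critical_points <- critical_points_of(net, field)
  net
}

# First local minimum of a Gaussian KDE of the deviations; 0.1 when the
# estimate is unimodal or there is nothing to estimate.
auto_flat_tolerance <- function(devs) {
  if (length(devs) < 3 || stats::sd(devs) < 1e-12) return(0.1)
  kde <- stats::density(devs, bw = "nrd", n = 512)
  y <- kde$y
  interior <- which(diff(sign(diff(y))) > 0) + 1L   # local minima of the KDE
  if (length(interior) == 0) return(0.1)
  kde$x[interior[1]]
}
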