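# chain fixture: 1D grid with prescribed node values (Delaunay = the chain)
chain_fixture <- function(values) {
  grid <- topo_grid(matrix(seq_along(values), ncol = 1))
  graph <- build_delaunay(grid)
  list(grid = grid, graph = graph, field = scalar_field(values))
}

test_that("maximum spanning tree handles the path and triangle exemplars", {
  fx <- chain_fixture(c(3, 1, 2, 5))
  tree <- max_spanning_tree(fx$graph, fx$field)
  expect_equal(nrow(tree), 3)          # the path is its own spanning tree
  # triangle with node values 3, 2, 1: drop the lightest edge (2-3)
  pts <- rbind(c(0, 0), c(1, 0), c(0.5, 1))
  gr <- graph_from_edges(pts, rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  tree2 <- max_spanning_tree(gr, scalar_field(c(3, 2, 1)))
  expect_equal(unname(tree2), rbind(c(1L, 2L), c(1L, 3L)))
})

test_that("disconnected graphs are rejected with a component count", {
  pts <- rbind(c(0, 0), c(1, 0), c(5, 0), c(6, 0))
  gr <- graph_from_edges(pts, rbind(c(1L, 2L), c(3L, 4L)))
  expect_error(max_spanning_tree(gr, scalar_field(1:4)), "2 components")
})

test_that("tree paths attain the brute-force widest-path (maximin) value", {
  for (seed in 1:12) {
    n <- 8 + (seed %% 5) * 4
    edges <- random_connected_graph(n, extra = n, seed = seed)
    set.seed(seed + 100)
    pts <- cbind(runif(n), runif(n))
    f <- scalar_field(runif(n))
    gr <- graph_from_edges(pts, edges)
    w <- (f$values[edges[, 1]] + f$values[edges[, 2]]) / 2
    tree <- max_spanning_tree(gr, f)
    maxima <- local_maxima(gr, f)
    if (length(maxima) < 2) next
    ig_tree <- igraph::graph_from_edgelist(tree, directed = FALSE)
    ig_tree <- igraph::add_vertices(ig_tree, max(0, n - igraph::vcount(ig_tree)))
    wmap <- stats::setNames(w, paste(edges[, 1], edges[, 2]))
    pairs <- utils::combn(maxima, 2)
    for (pc in seq_len(ncol(pairs))) {
      a <- pairs[1, pc]; b <- pairs[2, pc]
      path <- as.integer(igraph::shortest_paths(ig_tree, a, b)$vpath[[1]])
      ek <- paste(pmin(path[-length(path)], path[-1]),
                  pmax(path[-length(path)], path[-1]))
      expect_equal(min(wmap[ek]), brute_maximin(edges, w, a, b, n),
                   ignore_attr = TRUE)
    }
  }
})

test_that("pruning keeps maxima, records the saddle node, shrinks stars", {
  fx <- chain_fixture(c(3, 1, 2, 5))
  tree <- max_spanning_tree(fx$graph, fx$field)
  maxima <- local_maxima(fx$graph, fx$field)
  expect_equal(maxima, c(1L, 4L))
  net <- prune_to_critical_tree(tree, fx$field, maxima)
  expect_equal(nrow(net$edges), 3)     # nothing to prune on a path
  expect_equal(net$critical_points$node, 2L)
  expect_equal(net$critical_points$value, 1)

  # star: center 5 with leaves 1, 2, 3 -> all leaves pruned
  pts <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1))
  gr <- graph_from_edges(pts, cbind(1L, 2:4))
  f <- scalar_field(c(5, 1, 2, 3))
  net2 <- prune_to_critical_tree(max_spanning_tree(gr, f), f, 1L)
  expect_equal(nrow(net2$edges), 0)
  expect_equal(nrow(net2$critical_points), 0)
})

test_that("two-Gaussian field prunes to one path through the saddle", {
  grid <- make_grid("random", n = 1500, lower = c(-2.5, -2.5),
                    upper = c(2.5, 2.5), seed = 17, weights = "none")
  model <- make_field("two_gaussian", a = c(-1, 0), b = c(1, 0))
  graph <- build_delaunay(grid)
  f <- eval_field(model, grid)
  maxima <- local_maxima(graph, f)
  net <- prune_to_critical_tree(max_spanning_tree(graph, f), f, maxima)
  expect_equal(nrow(net$critical_points), 1)
  # all pruned-tree nodes have degree <= 2 on a single path
  deg <- table(factor(c(net$edges), levels = seq_len(grid$n)))
  expect_lte(max(deg), 2)
  # critical value vs the analytic saddle (midpoint): 2 exp(-1)
  expect_equal(net$critical_points$value, 2 * exp(-1), tolerance = 0.02)
})

hexagon_fixture <- function(n = 4000, seed = 2) {
  th <- pi / 3 * (0:5)
  centers <- cbind(cos(th), sin(th))
  set.seed(seed)
  centers <- centers + matrix(rnorm(12, sd = 1e-3), ncol = 2)  # break symmetry
  model <- make_field("gaussian_mixture", centers = centers,
                      heights = rep(1, 6), widths = rep(0.45, 6))
  grid <- make_grid("random", n = n, lower = c(-1.8, -1.8), upper = c(1.8, 1.8),
                    seed = seed + 10, weights = "none")
  graph <- build_delaunay(grid)
  list(grid = grid, graph = graph, model = model,
       field = eval_field(model, grid), centers = centers)
}

test_that("gap-filling closes the benzene-like ring exactly once", {
  fx <- hexagon_fixture()
  maxima <- local_maxima(fx$graph, fx$field)
  expect_equal(length(maxima), 6)
  net <- prune_to_critical_tree(max_spanning_tree(fx$graph, fx$field),
                                fx$field, maxima)
  # the tree links 5 of the 6 consecutive ring pairs
  expect_equal(nrow(net$critical_points), 5)
  basins <- assign_basins_on_graph(fx$graph, fx$field)
  filled <- gap_fill(net, fx$graph, fx$field, basins)
  expect_equal(nrow(filled$critical_points), 6)
  expect_equal(sum(filled$critical_points$filled), 1)
  expect_gt(sum(filled$filled), 0)
  # gap-filling never removes edges; filled edges are genuinely new
  expect_true(all(paste(net$edges[, 1], net$edges[, 2]) %in%
                    paste(filled$edges[, 1], filled$edges[, 2])))
  expect_equal(sum(!filled$filled), nrow(net$edges))
  # every consecutive ring pair is linked: 6 critical points, one per bond
  ring_nodes <- nearest_grid_point(fx$grid, fx$centers)
  cp_pairs <- paste(filled$critical_points$from, filled$critical_points$to)
  expect_length(unique(cp_pairs), 6)
})

test_that("paths forced onto the basin boundary are not critically linked", {
  # three peaks: B and C flank A so that the direct B-C interface is thin
  # and its widest path would hug the A boundary
  centers <- rbind(c(0, 0.45), c(-1.05, -0.55), c(1.05, -0.55))
  model <- make_field("gaussian_mixture", centers = centers,
                      heights = c(1.25, 1, 1), widths = rep(0.45, 3))
  grid <- make_grid("random", n = 3500, lower = c(-2.2, -1.8),
                    upper = c(2.2, 1.6), seed = 33, weights = "none")
  graph <- build_delaunay(grid)
  f <- eval_field(model, grid)
  maxima <- local_maxima(graph, f)
  expect_equal(length(maxima), 3)
  net <- prune_to_critical_tree(max_spanning_tree(graph, f), f, maxima)
  basins <- assign_basins_on_graph(graph, f)
  filled <- gap_fill(net, graph, f, basins)
  # A-B and A-C linked by the tree; the B-C gap must NOT be filled
  expect_equal(nrow(filled$critical_points), 2)
  expect_equal(sum(filled$critical_points$filled), 0)
})

test_that("cleaving removes exactly the deep-valley paths", {
  # chain of equal maxima joined by shallow dips plus one deep-valley link
  vals <- c(0, 1, 0.95, 1, 0.95, 1, 0.2, 1, 0.95, 1)
  fx <- chain_fixture(vals)
  maxima <- local_maxima(fx$graph, fx$field)
  net <- prune_to_critical_tree(max_spanning_tree(fx$graph, fx$field),
                                fx$field, maxima)
  devs_expected <- c(0.05, 0.05, 0.8, 0.05)
  cleaved <- cleave(net, fx$field, t_flat = 0.25)
  comp <- igraph::components(igraph::graph_from_edgelist(cleaved$edges,
                                                         directed = FALSE))
  kept_maxima_comps <- unique(comp$membership[intersect(maxima,
                                                        unique(c(cleaved$edges)))])
  expect_equal(length(kept_maxima_comps), 2)  # split at the deep valley
  expect_lt(nrow(cleaved$edges), nrow(net$edges))
  # a flat field cleaves nothing
  flat <- chain_fixture(c(0, 1, 1, 1, 1))
  m2 <- c(2L, 5L)  # plateau ends under strict maximality: craft values instead
  vals2 <- c(0, 1, 0.999, 1, 0.999, 1)
  flat <- chain_fixture(vals2)
  mx <- local_maxima(flat$graph, flat$field)
  net2 <- prune_to_critical_tree(max_spanning_tree(flat$graph, flat$field),
                                 flat$field, mx)
  cl2 <- cleave(net2, flat$field, t_flat = 0.25)
  expect_equal(nrow(cl2$edges), nrow(net2$edges))
})

test_that("critical values are invariant under monotone transforms", {
  grid <- make_grid("random", n = 1200, lower = c(-2.5, -2.5),
                    upper = c(2.5, 2.5), seed = 23, weights = "none")
  model <- make_field("two_gaussian", a = c(-1, 0.2), b = c(1, -0.2))
  graph <- build_delaunay(grid)
  f <- eval_field(model, grid)
  maxima <- local_maxima(graph, f)
  net1 <- prune_to_critical_tree(max_spanning_tree(graph, f), f, maxima)
  f3 <- scalar_field(f$values^3)
  net3 <- prune_to_critical_tree(max_spanning_tree(graph, f3), f3,
                                 local_maxima(graph, f3))
  expect_equal(net3$critical_points$value, net1$critical_points$value^3,
               tolerance = 1e-12)
  expect_equal(net3$critical_points$node, net1$critical_points$node)
})

test_that("stagnation-style fields cleave into multiple components", {
  # -|J| of an azimuthal ring current on a 3D grid: the z-axis is a
  # stagnation line of equal (zero) values; transverse links dip strongly
  model <- make_field("ring_current")
  grid <- make_grid("uniform", lower = c(-1.5, -1.5, -1.5),
                    upper = c(1.5, 1.5, 1.5), spacing = 0.25)
  graph <- build_delaunay(grid)
  f <- negate(eval_field(model, grid))
  maxima <- local_maxima(graph, f)
  net <- prune_to_critical_tree(max_spanning_tree(graph, f), f, maxima)
  cleaved <- cleave(net, f, t_flat = "auto")
  comp <- igraph::components(igraph::graph_from_edgelist(
    cleaved$edges, directed = FALSE))
  expect_gte(sum(comp$csize > 1), 2)
  expect_true(cleaved$provenance$cleaved)
})
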