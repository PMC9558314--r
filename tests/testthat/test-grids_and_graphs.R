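test_that("grid constructor enforces invariants", {
  expect_error(topo_grid(matrix(1, 2, 4)), "dimension")
  expect_error(topo_grid(cbind(c(0, 1), c(0, NA))), "finite")
  expect_error(topo_grid(cbind(0:2), weights = c(1, 2)), "one weight per point")
  expect_error(topo_grid(cbind(0:2), weights = c(1, -1, 1)), "nonnegative")
  # duplicates merged, weights summed
  pts <- rbind(c(0, 0), c(1, 0), c(0, 0), c(0, 1))
  expect_warning(g <- topo_grid(pts, weights = c(1, 2, 3, 4)), "duplicate")
  expect_equal(g$n, 3)
  expect_equal(g$weights[1], 4)  # 1 + 3 at the origin
  expect_equal(sum(g$weights), 10)
})

test_that("Delaunay graph of a triangle is the triangle", {
  g <- topo_grid(rbind(c(0, 0), c(1, 0), c(0, 1)))
  gr <- build_delaunay(g)
  expect_equal(nrow(gr$edges), 3)
  expect_true(all(vapply(1:3, function(i) length(neighbors_of(gr, i)),
                         integer(1)) == 2))
  expect_true(all(gr$hull_mask))
})

test_that("Delaunay edges match the brute-force empty-circumcircle oracle", {
  # the quad with the asymmetric corner: 4 boundary edges + 1 diagonal
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1.1))
  gr <- build_delaunay(topo_grid(pts))
  oracle <- brute_delaunay_edges_2d(pts)
  expect_equal(nrow(gr$edges), 5)
  expect_equal(unname(gr$edges), unname(oracle))
  # larger random instances
  for (seed in 1:3) {
    set.seed(seed)
    pts <- matrix(runif(60), ncol = 2)
    gr <- build_delaunay(topo_grid(pts))
    expect_equal(unname(gr$edges), unname(brute_delaunay_edges_2d(pts)),
                 label = paste("seed", seed))
  }
})

test_that("Delaunay adjacency equals Voronoi-facet adjacency", {
  set.seed(11)
  pts <- matrix(runif(80), ncol = 2)
  gr <- build_delaunay(topo_grid(pts))
  vor <- gridtopo:::qhull()$voronoi_adjacency(pts) + 1L
  vor <- vor[order(vor[, 1], vor[, 2]), , drop = FALSE]
  expect_equal(unname(gr$edges), unname(vor))
})

test_that("Delaunay graphs validate cleanly in the bulk", {
  set.seed(5)
  g <- topo_grid(matrix(runif(400), ncol = 2))
  rep2 <- validate_graph(build_delaunay(g))
  expect_true(rep2$connected)
  expect_true(rep2$undirected)
  expect_equal(rep2$basis_preserving_fraction, 1)
  expect_equal(rep2$move_preserving_fraction, 1)
  # 3D too
  set.seed(6)
  g3 <- topo_grid(matrix(runif(450), ncol = 3))
  rep3 <- validate_graph(build_delaunay(g3))
  expect_true(rep3$connected)
  expect_equal(rep3$move_preserving_fraction, 1)
})

test_that("uniform lattices (cospherical degeneracies) triangulate reproducibly", {
  g <- make_grid("uniform", n = c(6, 6), spacing = 1)
  gr1 <- build_delaunay(g, jitter_seed = 3)
  gr2 <- build_delaunay(g, jitter_seed = 3)
  expect_identical(gr1$edges, gr2$edges)
  expect_equal(gr1$provenance$jitter_seed, 3)
  expect_true(validate_graph(gr1)$connected)
})

test_that("degenerate inputs raise informative errors", {
  expect_error(build_delaunay(topo_grid(cbind(0:4, 0:4))),
               "affinely independent")
  expect_error(build_delaunay(topo_grid(rbind(c(0, 0), c(1, 1)))),
               "spanning only")
})

test_that("1D 'triangulation' is the sorted chain", {
  x <- c(3, 1, 2, 5, 4)
  gr <- build_delaunay(topo_grid(x))
  expect_equal(nrow(gr$edges), 4)
  expect_equal(sum(gr$hull_mask), 2)
  expect_true(gr$hull_mask[which.min(x)] && gr$hull_mask[which.max(x)])
})

test_that("knn graph matches hand enumeration and is undirected", {
  # equally spaced 1D points, k = 1, ties to the lower index: every interior
  # point picks its left neighbor, node 1 picks node 2, so the undirected
  # union is the full chain
  g <- topo_grid(matrix(0:9, ncol = 1))
  gr <- build_knn(g, 1)
  expect_equal(unname(gr$edges), cbind(1:9, 2:10))
  expect_equal(unname(gr$edges), unname(brute_knn_edges(g$points, 1)))
  # unequal spacing does fragment: close pairs with wide gaps between them
  g2 <- topo_grid(matrix(c(0, 0.1, 5, 5.1, 10, 10.1), ncol = 1))
  gr2 <- build_knn(g2, 1)
  expect_equal(unname(gr2$edges), cbind(c(1, 3, 5), c(2, 4, 6)))
  expect_false(validate_graph(gr2)$connected)
  # brute-force agreement on scattered points
  set.seed(2)
  pts <- matrix(runif(60), ncol = 2)
  for (k in c(2, 3)) {
    gr <- build_knn(topo_grid(pts), k)
    expect_equal(unname(gr$edges), unname(brute_knn_edges(pts, k)))
  }
  # k = n - 1 gives the complete graph
  gr <- build_knn(topo_grid(pts[1:8, ]), 7)
  expect_equal(nrow(gr$edges), choose(8, 2))
  expect_error(build_knn(g, 0), "k must satisfy")
  expect_error(build_knn(g, 10), "k must satisfy")
})

test_that("sparse knn graphs fail the move-preserving requirement", {
  set.seed(4)
  pts <- matrix(runif(300), ncol = 2)
  rep_knn <- validate_graph(build_knn(topo_grid(pts), 2))
  expect_lt(rep_knn$move_preserving_fraction, 1)
})

test_that("a half-plane neighborhood is not move-preserving", {
  # center node with neighbors at +x, -x, +y only: no move has positive
  # projection on -y
  pts <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1))
  gr <- graph_from_edges(pts, cbind(1L, 2:4))
  ok <- gridtopo:::qhull()$move_preserving_mask(pts, gr$adj_ptr,
                                                gr$adj_idx - 1L, 0L)
  expect_false(ok[1])
  # adding -y restores it
  pts2 <- rbind(pts, c(0, -1))
  gr2 <- graph_from_edges(pts2, cbind(1L, 2:5))
  ok2 <- gridtopo:::qhull()$move_preserving_mask(pts2, gr2$adj_ptr,
                                                 gr2$adj_idx - 1L, 0L)
  expect_true(ok2[1])
})

test_that("nearest_grid_point agrees with a linear scan and breaks ties low", {
  g <- topo_grid(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)))
  expect_equal(nearest_grid_point(g, c(1, 0)), 2L)
  centroid <- colMeans(g$points)
  expect_equal(nearest_grid_point(g, centroid), 1L)  # 3-way tie -> lowest
  set.seed(9)
  pts <- matrix(runif(500 * 3), ncol = 3)
  grid <- topo_grid(pts)
  q <- matrix(runif(900), ncol = 3)
  got <- nearest_grid_point(grid, q)
  brute <- apply(q, 1, function(x)
    which.min(colSums((t(pts) - x)^2)))
  expect_equal(got, brute)
})
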