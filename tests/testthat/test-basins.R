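two_gauss_fixture <- function(n = 600, seed = 1, a = c(-1, 0), b = c(1, 0)) {
  grid <- make_grid("random", n = n, lower = c(-2.5, -2.5), upper = c(2.5, 2.5),
                    seed = seed, weights = "none")
  model <- make_field("two_gaussian", a = a, b = b)
  graph <- build_delaunay(grid)
  list(grid = grid, graph = graph, model = model,
       field = eval_field(model, grid))
}

test_that("a single Gaussian yields exactly one local maximum, at the peak", {
  grid <- make_grid("random", n = 500, lower = c(-2, -2), upper = c(2, 2),
                    seed = 21, weights = "none")
  model <- make_field("two_gaussian", a = c(0.2, -0.1), b = c(0.2, -0.1))
  graph <- build_delaunay(grid)
  m <- local_maxima(graph, eval_field(model, grid))
  expect_length(m, 1)
  expect_equal(m, nearest_grid_point(grid, c(0.2, -0.1)))
  # the 2-nearest-neighbor graph on the same field invents extra maxima
  m_knn <- local_maxima(build_knn(grid, 2), eval_field(model, grid))
  expect_gt(length(m_knn), 1)
})

test_that("constant fields have no graph local maxima and cannot be assigned", {
  set.seed(2)
  grid <- topo_grid(matrix(runif(80), ncol = 2))
  graph <- build_delaunay(grid)
  f <- scalar_field(rep(1.5, grid$n))
  expect_length(local_maxima(graph, f), 0)
  expect_error(assign_basins_on_graph(graph, f), "no graph local maxima")
})

test_that("two separated Gaussians give two basins containing their centers", {
  fx <- two_gauss_fixture()
  basins <- assign_basins_on_graph(fx$graph, fx$field)
  expect_partition(basins, fx$grid$n)
  expect_length(basins$local_maxima, 2)
  expect_setequal(basins$local_maxima,
                  nearest_grid_point(fx$grid, rbind(c(-1, 0), c(1, 0))))
  # roughly balanced split for symmetric peaks
  tab <- table(basins$attractor)
  expect_gt(min(tab) / sum(tab), 0.3)
})

test_that("shortcutting never changes the assignment", {
  for (seed in 1:5) {
    set.seed(seed)
    grid <- topo_grid(matrix(runif(60), ncol = 2))
    graph <- build_delaunay(grid)
    f <- scalar_field(runif(grid$n))
    fast <- assign_basins_on_graph(graph, f, shortcut = TRUE)
    slow <- assign_basins_on_graph(graph, f, shortcut = FALSE)
    expect_identical(fast$attractor, slow$attractor)
  }
})

test_that("assignments are invariant under positive affine field maps", {
  fx <- two_gauss_fixture(seed = 8)
  base <- assign_basins_on_graph(fx$graph, fx$field)
  scaled <- assign_basins_on_graph(
    fx$graph, scalar_field(37.5 * fx$field$values - 4))
  expect_identical(base$attractor, scaled$attractor)
  gf <- ls_gradient(fx$graph, fx$field)
  gf2 <- ls_gradient(fx$graph, scalar_field(37.5 * fx$field$values - 4))
  off1 <- assign_basins_off_graph(fx$graph, fx$field, gf)
  off2 <- assign_basins_off_graph(fx$graph,
                                  scalar_field(37.5 * fx$field$values - 4), gf2)
  expect_identical(off1$attractor, off2$attractor)
})

test_that("off-graph ascent reduces to on-graph for a single maximum", {
  grid <- make_grid("random", n = 400, lower = c(-2, -2), upper = c(2, 2),
                    seed = 3, weights = "none")
  model <- make_field("two_gaussian", a = c(0, 0), b = c(0, 0))
  graph <- build_delaunay(grid)
  f <- eval_field(model, grid)
  on <- assign_basins_on_graph(graph, f)
  off <- assign_basins_off_graph(graph, f)
  expect_identical(off$attractor, on$attractor)
  # seeds that are themselves maxima stay put
  expect_equal(off$attractor[off$local_maxima], off$local_maxima)
})

test_that("ring fields merge all their maxima into one family", {
  grid <- make_grid("random", n = 2000, lower = c(-2, -2), upper = c(2, 2),
                    seed = 5, weights = "none")
  graph <- build_delaunay(grid)
  f <- eval_field(make_field("ring"), grid)
  basins <- assign_basins_on_graph(graph, f)
  expect_gt(length(basins$local_maxima), 1)  # extended maximum, many nodes
  fams <- cluster_maxima_families(graph, f, basins, t = 0.25)
  expect_length(fams$families, 1)
})

test_that("well-separated equal peaks stay in separate singleton families", {
  fx <- two_gauss_fixture(n = 800, seed = 12)
  basins <- assign_basins_on_graph(fx$graph, fx$field)
  fams <- cluster_maxima_families(fx$graph, fx$field, basins, t = 0.25)
  expect_length(fams$families, 2)
  expect_true(all(lengths(fams$families) == 1))
  # the flood fills stay clear of the inter-peak valley
  expect_length(intersect(fams$flood_fills[[1]], fams$flood_fills[[2]]), 0)
})

test_that("t = 1 merges everything on a connected graph; bad t errors", {
  fx <- two_gauss_fixture(seed = 13)
  basins <- assign_basins_on_graph(fx$graph, fx$field)
  fams <- cluster_maxima_families(fx$graph, fx$field, basins, t = 1)
  expect_length(fams$families, 1)
  expect_error(cluster_maxima_families(fx$graph, fx$field, basins, t = 0),
               "must lie in")
  expect_error(cluster_maxima_families(fx$graph, fx$field, basins, t = 1.5),
               "must lie in")
})

test_that("basin integrals conserve the total and recover known charges", {
  # conservation is exact by the partition property
  fx <- two_gauss_fixture(n = 700, seed = 9)
  w <- voronoi_weights(fx$grid, seed = 2)
  fx$grid$weights <- w
  basins <- assign_basins_on_graph(fx$graph, fx$field)
  fams <- cluster_maxima_families(fx$graph, fx$field, basins, 0.25)
  q <- integrate_basins(basins, fams, fx$field, fx$grid)
  expect_equal(sum(q), sum(w * fx$field$values), tolerance = 1e-12)

  # isotropic 3D Gaussian with unit analytic integral, +-6 sigma box
  sigma <- 1 / sqrt(2)  # exp(-|x|^2) * pi^{-3/2} normalizes to 1
  grid3 <- make_grid("uniform", lower = rep(-6 * sigma, 3),
                     upper = rep(6 * sigma, 3), spacing = 12 * sigma / 24)
  rho <- scalar_field(exp(-rowSums(grid3$points^2)) / pi^1.5)
  graph3 <- build_delaunay(grid3)
  b3 <- assign_basins_on_graph(graph3, rho)
  q3 <- integrate_basins(b3, NULL, rho, grid3)
  expect_length(q3, 1)
  expect_equal(unname(q3[1]), 1, tolerance = 0.01)
})

test_that("promolecule basin populations recover the electron counts", {
  centers <- rbind(c(-5, 0, 0), c(5, 0, 0))
  model <- make_field("promolecule", centers = centers,
                      populations = c(2, 8), alphas = c(1.7, 2.2))
  grid <- make_grid("atom_centered", centers = centers, n_radial = 35,
                    n_angular = 60, r_outer = 10)
  graph <- build_delaunay(grid)
  f <- eval_field(model, grid)
  basins <- assign_basins_on_graph(graph, f)
  fams <- cluster_maxima_families(graph, f, basins, 0.25)
  q <- integrate_basins(basins, fams, f, grid)
  expect_length(q, 2)
  # family ids are ordered by descending peak value: N=8 center is higher
  expect_equal(unname(q), c(8, 2), tolerance = 0.01)
})

test_that("missing weights fall back to Voronoi volumes or error when disabled", {
  fx <- two_gauss_fixture(n = 150, seed = 30)
  basins <- assign_basins_on_graph(fx$graph, fx$field)
  expect_error(integrate_basins(basins, NULL, fx$field, fx$grid,
                                voronoi_fallback = FALSE),
               "no integration weights")
  q <- integrate_basins(basins, NULL, fx$field, fx$grid)
  expect_true(all(is.finite(q)) && all(q > 0))
})
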