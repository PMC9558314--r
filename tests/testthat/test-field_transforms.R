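test_that("pointwise transforms behave and compose", {
  f <- scalar_field(c(-2, 0, 1.5), name = "f")
  expect_equal(negate(negate(f))$values, f$values)
  expect_equal(abs_field(f)$values, c(2, 0, 1.5))
  expect_equal(abs_field(negate(f))$values, abs_field(f)$values)
  aux <- isosurface_aux(f, 1.5)
  expect_true(all(aux$values > 0 & aux$values <= 1))
  expect_equal(aux$values[3], 1)
  expect_equal(vector_magnitude(f, f, f)$values, sqrt(3) * abs(f$values))
  expect_error(vector_magnitude(f, f, scalar_field(1:2)), "different grids")
  expect_equal(vector_magnitude(scalar_field(c(1, 1)), scalar_field(c(0, 0)),
                                scalar_field(c(0, 0)))$values, c(1, 1))
})

test_that("minima are found as maxima of the negated field", {
  grid <- make_grid("random", n = 900, lower = c(-2.5, -2.5),
                    upper = c(2.5, 2.5), seed = 14, weights = "none")
  model <- make_field("two_gaussian", a = c(-1, 0), b = c(1, 0))
  f <- negate(eval_field(model, grid))   # two wells -> two negated-maxima
  graph <- build_delaunay(grid)
  basins <- assign_basins_on_graph(graph, negate(f))
  expect_length(basins$local_maxima, 2)
})

test_that("isosurface families count the connected isosurface components", {
  # two separated 3D peaks at half maximum: two disjoint shells
  centers <- rbind(c(-1.6, 0, 0), c(1.6, 0, 0))
  model <- make_field("gaussian_mixture", centers = centers,
                      widths = c(0.7, 0.7))
  grid <- make_grid("uniform", lower = c(-3, -1.4, -1.4),
                    upper = c(3, 1.4, 1.4), spacing = 0.2)
  f <- eval_field(model, grid)
  aux <- isosurface_aux(f, max(f$values) / 2)
  graph <- build_delaunay(grid)
  basins <- assign_basins_on_graph(graph, aux)
  fams <- cluster_maxima_families(graph, aux, basins, t = 0.25)
  expect_equal(length(fams$families), 2)
  # a single peak gives one shell
  model1 <- make_field("gaussian_mixture", centers = rbind(c(0, 0, 0)),
                       widths = 0.7)
  grid1 <- make_grid("uniform", lower = rep(-1.4, 3), upper = rep(1.4, 3),
                     spacing = 0.2)
  f1 <- eval_field(model1, grid1)
  aux1 <- isosurface_aux(f1, max(f1$values) / 2)
  graph1 <- build_delaunay(grid1)
  fams1 <- cluster_maxima_families(graph1, aux1,
                                   assign_basins_on_graph(graph1, aux1),
                                   t = 0.25)
  expect_equal(length(fams1$families), 1)
})

test_that("radial shell fields produce one family per |profile| lobe", {
  model <- make_field("shell_profile", shell_a = 4, shell_b = 1,
                      center = c(0, 0))
  grid <- make_grid("atom_centered", centers = rbind(c(0, 0)),
                    n_radial = 60, n_angular = 90, r_inner = 0.05,
                    r_outer = 2.2)
  f <- abs_field(eval_field(model, grid))
  graph <- build_delaunay(grid)
  basins <- assign_basins_on_graph(graph, f)
  fams <- cluster_maxima_families(graph, f, basins, t = 0.25)
  # |sin(4r)| on (0, 2.2] has lobes (0, pi/4), (pi/4, pi/2), (pi/2, 3pi/4)
  # except the outermost partial lobe: 2.2 < 3pi/4 + pi/4; count = 3
  expect_equal(length(fams$families), 3)
})

test_that("the ring-current magnitude vanishes on the axis", {
  model <- make_field("ring_current")
  z_axis <- cbind(0, 0, seq(-1, 1, 0.2))
  expect_equal(model$value(z_axis), rep(0, nrow(z_axis)))
  off <- model$value(cbind(0.5, 0, 0))
  expect_gt(off, 0)
  m <- vector_magnitude(scalar_field(model$components$jx(z_axis)),
                        scalar_field(model$components$jy(z_axis)),
                        scalar_field(model$components$jz(z_axis)))
  expect_equal(m$values, rep(0, nrow(z_axis)))
})
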