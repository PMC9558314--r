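test_that("model gradients agree with central finite differences", {
  models <- list(
    make_field("two_gaussian", a = c(-1, 0.3), b = c(0.8, -0.2)),
    make_field("ring", center = c(0.1, -0.2), radius = 1.3),
    make_field("gaussian_mixture", centers = rbind(c(0, 0), c(1, 1)),
               heights = c(1, 2), widths = c(0.8, 1.2)),
    make_field("promolecule", centers = rbind(c(-2, 0, 0), c(2, 0, 0)),
               populations = c(2, 8), alphas = c(1.7, 2.2)),
    make_field("shell_profile", center = c(0, 0, 0)),
    make_field("ring_current"))
  dims <- c(2, 2, 2, 3, 3, 3)
  h <- 1e-5
  for (mi in seq_along(models)) {
    model <- models[[mi]]; d <- dims[mi]
    set.seed(mi)
    X <- matrix(runif(100 * d, -1.8, 1.8), ncol = d)
    g <- model$gradient(X)
    for (k in seq_len(d)) {
      Xp <- X; Xp[, k] <- Xp[, k] + h
      Xm <- X; Xm[, k] <- Xm[, k] - h
      fd <- (model$value(Xp) - model$value(Xm)) / (2 * h)
      denom <- pmax(sqrt(rowSums(g^2)), 1e-8)
      expect_lt(max(abs(fd - g[, k]) / denom), 1e-6,
                label = paste(model$model, "dim", k))
    }
  }
})

test_that("uniform grids carry exact cell-volume weights", {
  g <- make_grid("uniform", n = c(10, 10, 10), spacing = 0.5)
  expect_equal(g$n, 1000)
  expect_true(all(g$weights == 0.125))
  # weights sum to the box volume spanned by the cells
  expect_equal(sum(g$weights), (10 * 0.5)^3)
  expect_error(make_grid("uniform", n = c(4, 4)), "spacing")
})

test_that("random grids are seed-reproducible with positive Voronoi weights", {
  g1 <- make_grid("random", n = 300, lower = c(0, 0), upper = c(1, 2), seed = 7)
  g2 <- make_grid("random", n = 300, lower = c(0, 0), upper = c(1, 2), seed = 7)
  expect_identical(g1$points, g2$points)
  expect_identical(g1$weights, g2$weights)
  expect_true(all(g1$weights > 0))
  # 2D Voronoi areas clipped to the box tile it exactly
  expect_equal(sum(g1$weights), 2, tolerance = 1e-5)
  g3 <- make_grid("random", n = 300, lower = c(0, 0), upper = c(1, 2), seed = 8)
  expect_false(identical(g1$points, g3$points))
})

test_that("atom-centered grids have the advertised size and quadrature quality", {
  g <- make_grid("atom_centered", centers = rbind(c(0, 0, 0)),
                 n_radial = 20, n_angular = 38)
  expect_equal(g$n, 760)
  expect_true(all(g$weights > 0))
  # two-center promolecule integrates to its analytic electron count
  centers <- rbind(c(-1.2, 0, 0), c(1.2, 0, 0))
  model <- make_field("promolecule", centers = centers,
                      populations = c(2, 8), alphas = c(1.7, 2.2))
  grid <- make_grid("atom_centered", centers = centers, n_radial = 45,
                    n_angular = 110, r_outer = 12)
  total <- sum(grid$weights * model$value(grid$points))
  expect_equal(total, model$topology$total, tolerance = 0.005)
})

test_that("topology descriptors match the constructions", {
  same <- make_field("two_gaussian", a = c(0, 0), b = c(0, 0))
  expect_equal(same$topology$n_maxima, 1L)
  ring <- make_field("ring")
  on_ring <- cbind(cos(seq(0, 2 * pi, 0.5)), sin(seq(0, 2 * pi, 0.5)))
  expect_equal(ring$value(on_ring), rep(0, nrow(on_ring)))
  expect_lt(max(ring$value(matrix(runif(40, -2, 2), ncol = 2))), 1e-12)
  promo <- make_field("promolecule", centers = rbind(c(0, 0, 0)),
                      populations = 4, alphas = 2)
  expect_equal(promo$topology$total, 4)
})
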