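#' Synthetic grids
#'
#' Deterministic (seeded) generators for the three grid families the
#' analysis is exercised on:
#'
#' * `"uniform"` - a lattice with spacing `spacing` and per-point weight
#'   `spacing^d` (the cell volume). Specify either `n` points per dimension
#'   from `origin`, or a `lower`/`upper` box.
#' * `"random"` - `n` points uniform in a box, with Voronoi-cell-volume
#'   weights (exact in 1D/2D via midpoints/deldir clipped to the box;
#'   Monte-Carlo hull-clipped cells in 3D, seeded). Weights can be skipped
#'   (`weights = "none"`) when only topology is needed.
#' * `"atom_centered"` - per center, geometric radial shells times a
#'   quasi-uniform (Fibonacci spiral) sphere layout, with weights given by
#'   the product of a log-space radial quadrature (`r^3 h` in 3D) and equal
#'   angular weights, multiplied by Becke partition-of-unity weights so that
#'   overlapping per-center grids never double count. This emulates the
#'   radially graded molecular quadrature grids used in electronic-structure
#'   codes, without their tabulated angular rules.
#'
#' @param kind `"uniform"`, `"random"` or `"atom_centered"`.
#' @param lower,upper numeric box corners (uniform/random).
#' @param spacing lattice spacing in bohr (uniform).
#' @param n points per dimension (uniform, with `origin`) or total point
#'   count (random).
#' @param origin lattice origin (uniform with `n`).
#' @param seed integer seed (random; and the 3D Voronoi-weight sampler).
#' @param weights `"voronoi"` or `"none"` (random grids only).
#' @param centers numeric matrix of centers, one row each (atom_centered).
#' @param n_radial,n_angular shells per center and points per shell.
#' @param r_inner,r_outer innermost/outermost shell radius (bohr).
#' @return a [topo_grid()] with weights (except `weights = "none"`).
#' @export
make_grid <- function(kind = c("uniform", "random", "atom_centered"),
                      lower = NULL, upper = NULL, spacing = NULL,
                      n = NULL, origin = NULL, seed = 1L,
                      weights = c("voronoi", "none"),
                      centers = NULL, n_radial = 40L, n_angular = 86L,
                      r_inner = 0.01, r_outer = 12) {
  kind <- match.arg(kind)
  weights <- match.arg(weights)
  switch(kind,
    uniform = {
      if (is.null(spacing) || spacing <= 0) stop("uniform grid needs spacing > 0")
      if (!is.null(n)) {
        if (is.null(origin)) origin <- rep(0, length(n))
        axes <- lapply(seq_along(n), function(k)
          origin[k] + (seq_len(n[k]) - 1) * spacing)
      } else {
        if (is.null(lower) || is.null(upper)) stop("uniform grid needs n or lower/upper")
        axes <- lapply(seq_along(lower), function(k)
          seq(lower[k], upper[k], by = spacing))
      }
      pts <- as.matrix(expand.grid(axes))
      dimnames(pts) <- NULL
      topo_grid(pts, weights = rep(spacing^ncol(pts), nrow(pts)))
    },
    random = {
      if (is.null(n) || is.null(lower) || is.null(upper))
        stop("random grid needs n, lower, upper")
      d <- length(lower)
      old <- get_rng_state(); on.exit(restore_rng_state(old))
      set.seed(seed)
      pts <- matrix(runif(n * d), ncol = d)
      pts <- sweep(sweep(pts, 2, upper - lower, "*"), 2, lower, "+")
      g <- topo_grid(pts)
      if (weights == "voronoi") g <- add_voronoi_box_weights(g, lower, upper, seed)
      g
    },
    atom_centered = {
      if (is.null(centers)) stop("atom_centered grid needs centers")
      centers <- as.matrix(centers)
      make_atom_centered_grid(centers, n_radial, n_angular, r_inner, r_outer)
    })
}

add_voronoi_box_weights <- function(grid, lower, upper, seed) {
  d <- grid$dim
  if (d == 1) {
    o <- order(grid$points[, 1]); x <- grid$points[o, 1]
    cuts <- c(lower[1], (x[-1] + x[-length(x)]) / 2, upper[1])
    w <- numeric(grid$n); w[o] <- diff(cuts)
    grid$weights <- w
  } else if (d == 2 && requireNamespace("deldir", quietly = TRUE)) {
    dd <- deldir::deldir(grid$points[, 1], grid$points[, 2],
                         rw = c(lower[1], upper[1], lower[2], upper[2]))
    stopifnot(nrow(dd$summary) == grid$n)  # summary preserves input order
    grid$weights <- dd$summary$dir.area
  } else {
    grid$weights <- voronoi_weights(grid, seed = seed)
  }
  grid
}

# Fibonacci spiral on the unit sphere (deterministic quasi-uniform layout).
fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 1
  z <- (2 * k + 1) / n - 1
  phi <- k * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Becke partition weights: fuzzy Voronoi cells from thrice-iterated
# smoothstep of the confocal elliptical coordinate, no size adjustment.
becke_weights <- function(points, centers) {
  ncen <- nrow(centers)
  if (ncen == 1) return(matrix(1, nrow(points), 1))
  npt <- nrow(points)
  rk <- sapply(seq_len(ncen), function(k)
    sqrt(rowSums(sweep(points, 2, centers[k, ])^2)))
  P <- matrix(1, npt, ncen)
  for (a in seq_len(ncen)) {
    for (b in seq_len(ncen)) {
      if (a == b) next
      mu <- (rk[, a] - rk[, b]) / sqrt(sum((centers[a, ] - centers[b, ])^2))
      s <- mu
      for (it in 1:3) s <- 1.5 * s - 0.5 * s^3
      P[, a] <- P[, a] * 0.5 * (1 - s)
    }
  }
  P / rowSums(P)
}

make_atom_centered_grid <- function(centers, n_radial, n_angular,
                                    r_inner, r_outer) {
  d <- ncol(centers)
  if (!d %in% 2:3) stop("atom-centered grids are 2D or 3D")
  h <- log(r_outer / r_inner) / (n_radial - 1)
  radii <- r_inner * exp(h * (seq_len(n_radial) - 1))
  if (d == 3) {
    sphere <- fibonacci_sphere(n_angular)
    w_ang <- 4 * pi / n_angular
    w_rad <- radii^3 * h                 # log-space rule for f r^2 dr
  } else {
    th <- 2 * pi * (seq_len(n_angular) - 1) / n_angular
    sphere <- cbind(cos(th), sin(th))
    w_ang <- 2 * pi / n_angular
    w_rad <- radii^2 * h                 # log-space rule for f r dr
  }
  # rotate each shell's layout by the golden angle (and each center's by a
  # fixed offset) so shells and centers never replicate one point pattern:
  # replicated cospherical layouts are needlessly degenerate for the
  # triangulation, and staggering costs the quadrature nothing
  golden <- pi * (3 - sqrt(5))
  rotz <- function(m, th) {
    cs <- cos(th); sn <- sin(th)
    out <- m
    out[, 1] <- cs * m[, 1] - sn * m[, 2]
    out[, 2] <- sn * m[, 1] + cs * m[, 2]
    out
  }
  one_center_of <- function(k) {
    do.call(rbind, lapply(seq_len(n_radial), function(i)
      rotz(sphere, (i - 1) * golden + (k - 1) * 0.7) * radii[i]))
  }
  w_one <- rep(w_rad, each = n_angular) * w_ang
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
    sweep(one_center_of(k), 2, centers[k, ], "+")))
  one_center <- one_center_of(1)
  w <- rep(w_one, nrow(centers))
  w <- w * becke_weights(pts, centers)[cbind(seq_len(nrow(pts)),
                                             rep(seq_len(nrow(centers)),
                                                 each = nrow(one_center)))]
  topo_grid(pts, weights = w)
}

#' Analytic model fields with known topology
#'
#' Closed-form scalar fields (value plus analytic gradient plus a topology
#' descriptor) used to test every algorithm without any electronic-structure
#' input:
#'
#' * `"two_gaussian"` - `exp(-|x-a|^2) + exp(-|x-b|^2)`: two point maxima
#'   (one if `a == b`).
#' * `"ring"` - `-(|x - center| - radius)^2`: a spatially extended maximum
#'   on the ring/sphere `|x| = radius`, global maximum value 0.
#' * `"gaussian_mixture"` - `sum_k h_k exp(-|x-c_k|^2 / w_k^2)`.
#' * `"promolecule"` - superposed spherical exponential atomic densities
#'   `sum_k N_k (alpha_k^3/pi) exp(-2 alpha_k |x - R_k|)`; each term
#'   integrates to exactly `N_k` electrons, so basin populations have
#'   analytic references.
#' * `"shell_profile"` - radial `sin(a r) exp(-b r)`: alternating concentric
#'   shells, a stand-in for the density-Laplacian shell structure.
#' * `"ring_current"` - azimuthal vector field
#'   `J = A (-y, x, 0) exp(-(|x|^2))`; the model's scalar value is `|J|`,
#'   which vanishes on the z-axis (a stagnation line). Component functions
#'   are exposed in `$components`.
#'
#' @param model model name (see above).
#' @param a,b centers of the two Gaussians (`two_gaussian`).
#' @param center,radius ring center and radius (`ring`); `center` is also
#'   used by `shell_profile` and `ring_current`.
#' @param centers,heights,widths mixture parameters (`gaussian_mixture`).
#' @param populations,alphas promolecule electron counts and decay
#'   exponents (with `centers` as nuclear positions).
#' @param shell_a,shell_b radial frequency and decay (`shell_profile`).
#' @param amplitude overall scale (`ring_current`).
#' @return object of class `model_field`: functions `value(X)` and
#'   `gradient(X)` (rows = points), a `topology` descriptor list, and for
#'   vector models a `components` list.
#' @export
make_field <- function(model = c("two_gaussian", "ring", "gaussian_mixture",
                                 "promolecule", "shell_profile", "ring_current"),
                       a = c(-1, 0), b = c(1, 0),
                       center = NULL, radius = 1,
                       centers = NULL, heights = NULL, widths = NULL,
                       populations = NULL, alphas = NULL,
                       shell_a = 4, shell_b = 1, amplitude = 1) {
  model <- match.arg(model)
  out <- switch(model,
    two_gaussian = {
      a <- as.numeric(a); b <- as.numeric(b)
      val <- function(X) {
        X <- as_points(X, length(a))
        exp(-rowSums(sweep(X, 2, a)^2)) + exp(-rowSums(sweep(X, 2, b)^2))
      }
      grad <- function(X) {
        X <- as_points(X, length(a))
        da <- sweep(X, 2, a); db <- sweep(X, 2, b)
        -2 * (da * exp(-rowSums(da^2)) + db * exp(-rowSums(db^2)))
      }
      list(value = val, gradient = grad,
           topology = list(n_maxima = if (all(a == b)) 1L else 2L,
                           maxima = if (all(a == b)) rbind(a) else rbind(a, b),
                           max_value = if (all(a == b)) 2 else NULL))
    },
    ring = {
      if (is.null(center)) center <- c(0, 0)
      center <- as.numeric(center)
      val <- function(X) {
        X <- as_points(X, length(center))
        -(sqrt(rowSums(sweep(X, 2, center)^2)) - radius)^2
      }
      grad <- function(X) {
        X <- as_points(X, length(center))
        dx <- sweep(X, 2, center)
        r <- sqrt(rowSums(dx^2))
        scale <- ifelse(r > 0, -2 * (r - radius) / r, 0)
        dx * scale
      }
      list(value = val, gradient = grad,
           topology = list(n_families = 1L, max_value = 0,
                           extended = TRUE, radius = radius))
    },
    gaussian_mixture = {
      if (is.null(centers)) stop("gaussian_mixture needs centers")
      centers <- as.matrix(centers)
      m <- nrow(centers)
      if (is.null(heights)) heights <- rep(1, m)
      if (is.null(widths)) widths <- rep(1, m)
      val <- function(X) {
        X <- as_points(X, ncol(centers))
        out <- 0
        for (k in seq_len(m))
          out <- out + heights[k] * exp(-rowSums(sweep(X, 2, centers[k, ])^2) / widths[k]^2)
        out
      }
      grad <- function(X) {
        X <- as_points(X, ncol(centers))
        g <- matrix(0, nrow(X), ncol(X))
        for (k in seq_len(m)) {
          dx <- sweep(X, 2, centers[k, ])
          g <- g - dx * (2 * heights[k] / widths[k]^2 *
                           exp(-rowSums(dx^2) / widths[k]^2))
        }
        g
      }
      list(value = val, gradient = grad,
           topology = list(n_maxima = m, maxima = centers))
    },
    promolecule = {
      if (is.null(centers)) stop("promolecule needs centers")
      centers <- as.matrix(centers)
      m <- nrow(centers)
      if (is.null(populations)) populations <- rep(1, m)
      if (is.null(alphas)) alphas <- rep(1, m)
      val <- function(X) {
        X <- as_points(X, ncol(centers))
        out <- 0
        for (k in seq_len(m)) {
          r <- sqrt(rowSums(sweep(X, 2, centers[k, ])^2))
          out <- out + populations[k] * alphas[k]^3 / pi * exp(-2 * alphas[k] * r)
        }
        out
      }
      grad <- function(X) {
        X <- as_points(X, ncol(centers))
        g <- matrix(0, nrow(X), ncol(X))
        for (k in seq_len(m)) {
          dx <- sweep(X, 2, centers[k, ])
          r <- sqrt(rowSums(dx^2))
          amp <- populations[k] * alphas[k]^3 / pi * exp(-2 * alphas[k] * r)
          scale <- ifelse(r > 0, -2 * alphas[k] / r, 0)
          g <- g + dx * (amp * scale)
        }
        g
      }
      list(value = val, gradient = grad,
           topology = list(n_maxima = m, maxima = centers,
                           populations = populations,
                           total = sum(populations)))
    },
    shell_profile = {
      if (is.null(center)) center <- c(0, 0, 0)
      center <- as.numeric(center)
      val <- function(X) {
        X <- as_points(X, length(center))
        r <- sqrt(rowSums(sweep(X, 2, center)^2))
        sin(shell_a * r) * exp(-shell_b * r)
      }
      grad <- function(X) {
        X <- as_points(X, length(center))
        dx <- sweep(X, 2, center)
        r <- sqrt(rowSums(dx^2))
        dfdr <- (shell_a * cos(shell_a * r) - shell_b * sin(shell_a * r)) *
          exp(-shell_b * r)
        dx * ifelse(r > 0, dfdr / r, 0)
      }
      list(value = val, gradient = grad,
           topology = list(extended = TRUE,
                           lobe_count = function(r_max)
                             length(abs_lobes(shell_a, r_max))))
    },
    ring_current = {
      if (is.null(center)) center <- c(0, 0, 0)
      center <- as.numeric(center)
      comp <- list(
        jx = function(X) { X <- as_points(X, 3); dx <- sweep(X, 2, center)
          -dx[, 2] * amplitude * exp(-rowSums(dx^2)) },
        jy = function(X) { X <- as_points(X, 3); dx <- sweep(X, 2, center)
          dx[, 1] * amplitude * exp(-rowSums(dx^2)) },
        jz = function(X) { X <- as_points(X, 3); numeric(nrow(X)) })
      val <- function(X) {
        X <- as_points(X, 3); dx <- sweep(X, 2, center)
        rc <- sqrt(dx[, 1]^2 + dx[, 2]^2)
        amplitude * rc * exp(-rowSums(dx^2))
      }
      grad <- function(X) {
        X <- as_points(X, 3); dx <- sweep(X, 2, center)
        rc <- sqrt(dx[, 1]^2 + dx[, 2]^2)
        e <- amplitude * exp(-rowSums(dx^2))
        gx <- ifelse(rc > 0, dx[, 1] / rc, 0) * e - 2 * dx[, 1] * rc * e
        gy <- ifelse(rc > 0, dx[, 2] / rc, 0) * e - 2 * dx[, 2] * rc * e
        gz <- -2 * dx[, 3] * rc * e
        cbind(gx, gy, gz)
      }
      list(value = val, gradient = grad, components = comp,
           topology = list(zero_set = "z-axis", extended = TRUE))
    })
  structure(c(out, list(model = model)), class = "model_field")
}

# lobes of |sin(a r)| within [0, r_max]: intervals between consecutive zeros
abs_lobes <- function(a, r_max) {
  zeros <- seq(0, r_max, by = pi / a)
  seq_len(max(0L, length(zeros) - 1L))
}

as_points <- function(X, d) {
  if (is.null(dim(X))) X <- matrix(X, ncol = d)
  as.matrix(X)
}

#' @export
print.model_field <- function(x, ...) {
  cat("<model_field> ", x$model, "\n", sep = "")
  invisible(x)
}

#' Evaluate a model field on a grid
#' @param model a [make_field()] object.
#' @param grid a [topo_grid()].
#' @return a [scalar_field()] named after the model.
#' @export
eval_field <- function(model, grid) {
  stopifnot(inherits(model, "model_field"), inherits(grid, "topo_grid"))
  scalar_field(model$value(grid$points), name = model$model)
}
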