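#' Point grids
#'
#' A `topo_grid` is a set of distinct points in 1-, 2- or 3-dimensional
#' space (coordinates in bohr), optionally carrying per-point integration
#' weights (bohr^d). It is the carrier for every scalar field analysed by
#' the package: all topology is computed from function values at these
#' points, with no further function evaluations.
#'
#' Duplicate points (within `dedup_tol`) are merged and their weights
#' summed; triangulation engines fail on exact duplicates, so deduplication
#' is not optional.
#'
#' @param points numeric matrix (n x d) or vector (treated as 1D), in bohr.
#' @param weights optional numeric vector of nonnegative integration
#'   weights, one per point (bohr^d).
#' @param dedup_tol points closer than this (Euclidean, bohr) are merged.
#' @return An object of class `topo_grid` with fields `points`, `weights`,
#'   `dim`, `n`.
#' @examples
#' g <- topo_grid(cbind(runif(10), runif(10)))
#' g$n
#' @export
topo_grid <- function(points, weights = NULL, dedup_tol = 1e-12) {
  if (is.null(dim(points))) points <- matrix(as.numeric(points), ncol = 1)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  d <- ncol(points)
  if (!d %in% 1:3)
    stop("grid dimension must be 1, 2 or 3, got ", d)
  if (anyNA(points) || any(!is.finite(points)))
    stop("grid points must be finite")
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != nrow(points))
      stop("need one weight per point: ", length(weights), " weights for ",
           nrow(points), " points")
    if (any(weights < 0)) stop("integration weights must be nonnegative")
  }
  dd <- dedup_points(points, weights, dedup_tol)
  if (dd$ndropped > 0)
    warning(dd$ndropped, " duplicate point(s) merged (weights summed)")
  structure(list(points = dd$points, weights = dd$weights,
                 dim = d, n = nrow(dd$points)),
            class = "topo_grid")
}

# Merge points that coincide within tol; weights of merged points are summed.
dedup_points <- function(points, weights, tol) {
  n <- nrow(points)
  if (n > 1) {
    nn <- RANN::nn2(points, points, k = 2)
    if (any(nn$nn.dists[, 2] <= tol)) {
      # Union-find over coincident pairs, keep lowest index as representative
      rep_of <- seq_len(n)
      find <- function(i) { while (rep_of[i] != i) i <- rep_of[i] <- rep_of[rep_of[i]]; i }
      dup <- which(nn$nn.dists[, 2] <= tol)
      for (i in dup) {
        j <- nn$nn.idx[i, 2]
        ri <- find(i); rj <- find(j)
        if (ri != rj) rep_of[max(ri, rj)] <- min(ri, rj)
      }
      reps <- vapply(seq_len(n), find, integer(1))
      keep <- sort(unique(reps))
      if (!is.null(weights))
        weights <- as.numeric(tapply(weights, factor(reps, levels = keep), sum))
      points <- points[keep, , drop = FALSE]
      return(list(points = points, weights = weights, ndropped = n - length(keep)))
    }
  }
  list(points = points, weights = weights, ndropped = 0L)
}

#' @export
print.topo_grid <- function(x, ...) {
  cat("<topo_grid> ", x$n, " points in ", x$dim, "D",
      if (is.null(x$weights)) ", no weights" else ", with weights", "\n", sep = "")
  invisible(x)
}

# Affine rank of the point set (number of independent directions spanned).
affine_rank <- function(points) {
  if (nrow(points) < 2) return(0L)
  centered <- sweep(points, 2, colMeans(points))
  qr(centered, tol = 1e-10)$rank
}

#' Monte-Carlo Voronoi cell volumes, clipped to the convex hull
#'
#' Estimates the volume of each point's Voronoi cell restricted to the
#' convex hull of the grid, by sampling `nsamples` uniform points in the
#' hull's bounding box, keeping those inside the hull, and assigning each to
#' its nearest grid point. Used as the integration-weight fallback when a
#' grid carries no quadrature weights. Stochastic but seeded; relative cell
#' errors scale as 1/sqrt(samples per cell).
#'
#' @param grid a [topo_grid()].
#' @param nsamples total Monte-Carlo samples (default `200 * n`).
#' @param seed integer seed for the sampler.
#' @return numeric vector of nonnegative weights summing to the hull volume.
#' @export
voronoi_weights <- function(grid, nsamples = NULL, seed = 1L) {
  stopifnot(inherits(grid, "topo_grid"))
  n <- grid$n; d <- grid$dim
  if (is.null(nsamples)) nsamples <- min(200L * n, 5e6)
  pts <- grid$points
  if (d == 1) {
    # exact in 1D: midpoints between sorted neighbors
    o <- order(pts[, 1])
    x <- pts[o, 1]
    mids <- (x[-1] + x[-length(x)]) / 2
    lo <- c(x[1], mids); hi <- c(mids, x[length(x)])
    w <- numeric(n); w[o] <- hi - lo
    return(w)
  }
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  box_vol <- prod(hi - lo)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  samples <- matrix(runif(nsamples * d), ncol = d)
  samples <- sweep(sweep(samples, 2, hi - lo, "*"), 2, lo, "+")
  inside <- qhull()$in_hull_mask(pts, samples)
  samples <- samples[inside, , drop = FALSE]
  idx <- RANN::nn2(pts, samples, k = 1)$nn.idx[, 1]
  counts <- tabulate(idx, nbins = n)
  hull_vol <- qhull()$hull_volume(pts)
  counts / sum(counts) * hull_vol
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}
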