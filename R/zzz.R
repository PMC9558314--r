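#' @useDynLib gridtopo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif median density setNames
#' @importFrom utils head read.table write.table
NULL

# Cached python module handle (filled lazily; reticulate initializes python
# on first use, not at package load).
.gridtopo_env <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  # Point reticulate at the python interpreter on PATH unless the user has
  # already pinned one. scipy ships in the same environment as R here; the
  # Qhull kernels (Delaunay, convex hull, Voronoi) are reached through it.
  if (Sys.getenv("RETICULATE_PYTHON") == "" &&
      is.null(getOption("reticulate.python"))) {
    py <- Sys.which("python3")
    if (py == "") py <- Sys.which("python")
    if (py != "") Sys.setenv(RETICULATE_PYTHON = py)
  }
  invisible()
}

# Import the bundled scipy/Qhull helper module, caching the handle.
qhull <- function() {
  if (is.null(.gridtopo_env$qhull)) {
    path <- system.file("python", package = "gridtopo")
    .gridtopo_env$qhull <- reticulate::import_from_path(
      "qhull_helpers", path = path, delay_load = FALSE)
  }
  .gridtopo_env$qhull
}
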