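#' Scalar fields on a grid
#'
#' A `scalar_field` holds one finite real value per grid node plus light
#' metadata (name, provenance tag). Values are in whatever atomic units fit
#' the quantity: electron density in e/bohr^3, its Laplacian in e/bohr^5,
#' current-density magnitude in a.u.
#'
#' @param values numeric vector, one finite value per grid node.
#' @param name short descriptive name.
#' @param source provenance tag, one of `"input"`, `"negated"`, `"abs"`,
#'   `"isosurface_aux"`, `"magnitude"`.
#' @param n expected length (usually `grid$n`); checked if given.
#' @return object of class `scalar_field`.
#' @export
scalar_field <- function(values, name = "f", source = "input", n = NULL) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("scalar field values must be finite")
  if (!is.null(n) && length(values) != n)
    stop("field has ", length(values), " values but grid has ", n, " points")
  structure(list(values = values, name = name, source = source),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat("<scalar_field> '", x$name, "' (", x$source, "), ", length(x$values),
      " values, range [", format(min(x$values)), ", ",
      format(max(x$values)), "]\n", sep = "")
  invisible(x)
}

as_field <- function(x, n = NULL) {
  if (inherits(x, "scalar_field")) {
    if (!is.null(n) && length(x$values) != n)
      stop("field/grid length mismatch: ", length(x$values), " vs ", n)
    x
  } else scalar_field(x, n = n)
}

#' Field transforms
#'
#' Pointwise transforms that let one basin/critical-network engine serve
#' minima, isosurfaces, shell structure and stagnation graphs:
#'
#' * `negate()` - maxima of the output are minima of the input; the critical
#'   network of `-|J|` is the stagnation graph of a current density `J`, and
#'   that of a negated density Laplacian spans charge concentrations.
#' * `abs_field()` - e.g. `|Laplacian|`, whose maxima families are the
#'   alternating shells of charge concentration and depletion.
#' * `isosurface_aux()` - `exp(-|f - f_iso|)`, in (0, 1], equal to 1 exactly
#'   on the isosurface `f = f_iso`; its maxima families are the connected
#'   components of the isosurface.
#' * `vector_magnitude()` - Euclidean norm of three same-grid components,
#'   e.g. `|J|` from `(J_x, J_y, J_z)`.
#'
#' All transforms materialize a new `scalar_field` on the same grid.
#'
#' @param field,fx,fy,fz `scalar_field` objects (or bare numeric vectors).
#' @param f_iso target isosurface value.
#' @name field_transforms
NULL

#' @rdname field_transforms
#' @export
negate <- function(field) {
  field <- as_field(field)
  scalar_field(-field$values, name = paste0("-", field$name), source = "negated")
}

#' @rdname field_transforms
#' @export
abs_field <- function(field) {
  field <- as_field(field)
  scalar_field(abs(field$values), name = paste0("|", field$name, "|"),
               source = "abs")
}

#' @rdname field_transforms
#' @export
isosurface_aux <- function(field, f_iso) {
  field <- as_field(field)
  stopifnot(is.numeric(f_iso), length(f_iso) == 1, is.finite(f_iso))
  scalar_field(exp(-abs(field$values - f_iso)),
               name = sprintf("iso(%s, %g)", field$name, f_iso),
               source = "isosurface_aux")
}

#' @rdname field_transforms
#' @export
vector_magnitude <- function(fx, fy, fz) {
  fx <- as_field(fx); fy <- as_field(fy); fz <- as_field(fz)
  nl <- lengths(list(fx$values, fy$values, fz$values))
  if (length(unique(nl)) != 1)
    stop("component fields live on different grids (lengths ",
         paste(nl, collapse = ", "), ")")
  scalar_field(sqrt(fx$values^2 + fy$values^2 + fz$values^2),
               name = sprintf("|(%s,%s,%s)|", fx$name, fy$name, fz$name),
               source = "magnitude")
}
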