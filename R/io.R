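#' Read a Gaussian cube file
#'
#' Parses the standard cube layout: two comment lines; a line with the atom
#' count and grid origin; three axis lines (voxel count and step vector
#' each); the atom records; then the volumetric data in z-fastest order.
#' Coordinates are in bohr per the cube convention; a negative voxel count
#' on an axis signals Angstrom units and is converted on read, so
#' everything downstream is in bohr. A negative atom count (orbital cubes)
#' is tolerated: the extra dataset-id line is skipped.
#'
#' @param path file path.
#' @return list with `grid` (a [topo_grid()] with voxel-volume weights),
#'   `field` (a [scalar_field()]), `atoms` (data.frame Z, charge, x, y, z),
#'   `origin`, `axes` (3 x 3, rows are axis steps), `nvox` (3 voxel counts),
#'   `comment`.
#' @export
read_cube <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fail <- function(lineno, msg) stop("cube '", path, "' line ", lineno, ": ", msg)
  if (length(lines) < 7) fail(length(lines), "truncated header")
  comment <- lines[1:2]
  nums <- function(i, k) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (anyNA(v) || length(v) < k) fail(i, "expected at least ", k, " numbers")
    v
  }
  h <- nums(3, 4)
  natoms <- as.integer(h[1]); origin <- h[2:4]
  nvox <- integer(3); axes <- matrix(0, 3, 3)
  ang2bohr <- 1 / 0.52917721092
  for (k in 1:3) {
    v <- nums(3 + k, 4)
    nvox[k] <- as.integer(v[1]); axes[k, ] <- v[2:4]
    if (nvox[k] < 0) {            # negative count: this axis is in Angstrom
      nvox[k] <- -nvox[k]
      axes[k, ] <- axes[k, ] * ang2bohr
      if (k == 1) origin <- origin * ang2bohr
    }
    if (nvox[k] == 0) fail(3 + k, "zero voxel count")
  }
  na <- abs(natoms)
  atom_lines <- lines[seq_len(na) + 6]
  atoms <- do.call(rbind, lapply(seq_len(na), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(atom_lines[i]), "\\s+")[[1]]))
    if (anyNA(v) || length(v) != 5) fail(6 + i, "malformed atom record")
    data.frame(Z = as.integer(v[1]), charge = v[2], x = v[3], y = v[4], z = v[5])
  }))
  data_start <- 7 + na + if (natoms < 0) 1L else 0L
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[data_start:length(lines)]), "\\s+"))))
  if (anyNA(vals)) fail(data_start, "non-numeric volumetric data")
  nexp <- prod(nvox)
  if (length(vals) < nexp)
    fail(length(lines), sprintf("expected %d values, found %d", nexp, length(vals)))
  vals <- vals[seq_len(nexp)]
  # point (i,j,k) = origin + i*a1 + j*a2 + k*a3 with k (z) fastest
  idx <- expand.grid(k = seq_len(nvox[3]) - 1, j = seq_len(nvox[2]) - 1,
                     i = seq_len(nvox[1]) - 1)
  pts <- cbind(idx$i, idx$j, idx$k) %*% axes
  pts <- sweep(pts, 2, origin, "+")
  vol <- abs(det(axes))
  grid <- topo_grid(pts, weights = rep(vol, nrow(pts)))
  list(grid = grid, field = scalar_field(vals, name = basename(path)),
       atoms = atoms, origin = origin, axes = axes, nvox = nvox,
       comment = comment)
}

#' Write a Gaussian cube file
#'
#' Inverse of [read_cube()]: takes the lattice description explicitly
#' (origin, axes, voxel counts) plus values in z-fastest order. Always
#' writes bohr (positive voxel counts).
#'
#' @param path output path.
#' @param origin numeric length 3.
#' @param axes 3 x 3 matrix, rows are the axis step vectors (bohr).
#' @param nvox integer voxel counts per axis.
#' @param values numeric vector, z-fastest order, length `prod(nvox)`.
#' @param atoms data.frame with columns Z, charge, x, y, z (bohr); may be
#'   empty.
#' @param comment two comment lines.
#' @export
write_cube <- function(path, origin, axes, nvox, values, atoms = NULL,
                       comment = c("gridtopo cube", "")) {
  stopifnot(length(values) == prod(nvox))
  if (is.null(atoms))
    atoms <- data.frame(Z = integer(0), charge = numeric(0),
                        x = numeric(0), y = numeric(0), z = numeric(0))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(comment[1:2], con)
  fmt <- function(n, v) sprintf("%5d %19.12e %19.12e %19.12e", n, v[1], v[2], v[3])
  writeLines(fmt(nrow(atoms), origin), con)
  for (k in 1:3) writeLines(fmt(nvox[k], axes[k, ]), con)
  for (i in seq_len(nrow(atoms)))
    writeLines(sprintf("%5d %19.12e %19.12e %19.12e %19.12e", atoms$Z[i],
                       atoms$charge[i], atoms$x[i], atoms$y[i], atoms$z[i]), con)
  chunks <- split(values, ceiling(seq_along(values) / 6))
  writeLines(vapply(chunks, function(v)
    paste(sprintf("%19.12e", v), collapse = " "), character(1)), con)
  invisible(path)
}

#' Read a tabular point/value file
#'
#' Whitespace- or comma-delimited text with a header naming the columns:
#' coordinates (`x`, or `x y`, or `x y z`, in bohr), a `value` column, and
#' optionally a `weight` column (bohr^d). Comment lines starting with `#`
#' are skipped. Duplicate points are merged with summed weights (with a
#' warning), matching the grid constructor's policy.
#'
#' @param path file path.
#' @return list with `grid` (a [topo_grid()]) and `field`
#'   (a [scalar_field()]).
#' @export
read_points <- function(path) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  if (length(lineno) < 2) stop("points file '", path, "': no data rows")
  txt <- gsub(",", " ", raw[keep])
  header <- tolower(strsplit(trimws(txt[1]), "\\s+")[[1]])
  coord_cols <- intersect(c("x", "y", "z"), header)
  if (!"value" %in% header || length(coord_cols) == 0)
    stop("points file '", path, "': header must name coordinate columns and 'value'")
  rows <- strsplit(trimws(txt[-1]), "\\s+")
  ncol_exp <- length(header)
  bad <- which(lengths(rows) != ncol_exp)
  if (length(bad) > 0)
    stop("points file '", path, "' row ", lineno[bad[1] + 1],
         ": expected ", ncol_exp, " fields, found ", lengths(rows)[bad[1]])
  m <- matrix(suppressWarnings(as.numeric(unlist(rows))), ncol = ncol_exp,
              byrow = TRUE)
  if (anyNA(m)) {
    bad_row <- which(apply(m, 1, anyNA))[1]
    stop("points file '", path, "' row ", lineno[bad_row + 1],
         ": non-numeric entry")
  }
  colnames(m) <- header
  pts <- m[, coord_cols, drop = FALSE]
  dimnames(pts) <- NULL
  w <- if ("weight" %in% header) m[, "weight"] else NULL
  # deduplicate coordinates together with values: merged rows must agree
  grid <- topo_grid(pts, weights = w)
  vals <- m[, "value"]
  if (grid$n != nrow(pts)) {
    # re-associate values with surviving points via nearest lookup
    idx <- nearest_grid_point(grid, pts)
    vals <- vapply(seq_len(grid$n), function(i) mean(vals[idx == i]), numeric(1))
  }
  list(grid = grid, field = scalar_field(vals, name = basename(path)))
}

#' Write a tabular point/value file
#'
#' @param path output path.
#' @param grid a [topo_grid()].
#' @param field a [scalar_field()] (or numeric vector) on the grid.
#' @export
write_points <- function(path, grid, field) {
  stopifnot(inherits(grid, "topo_grid"))
  field <- as_field(field, grid$n)
  cn <- c("x", "y", "z")[seq_len(grid$dim)]
  header <- c(cn, "value", if (!is.null(grid$weights)) "weight")
  m <- cbind(grid$points, field$values, grid$weights)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(header, collapse = " "), con)
  writeLines(apply(m, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}

# Provenance block: everything needed to re-run a result bit-identically
# (deterministic stages) or statistically identically (seeded stages).
make_provenance <- function(parameters) {
  list(software = "gridtopo",
       version = as.character(utils::packageVersion("gridtopo")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       parameters = parameters)
}

write_provenance <- function(path, parameters) {
  jsonlite::write_json(make_provenance(parameters), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Check a provenance block against the shipped schema
#'
#' Light structural validation: the required fields of the JSON schema in
#' `inst/schema/provenance.schema.json` must be present and typed.
#'
#' @param prov list as produced when writing results (or a path to a JSON
#'   file).
#' @return `TRUE` (invisibly) or an error.
#' @export
validate_provenance <- function(prov) {
  if (is.character(prov)) prov <- jsonlite::read_json(prov)
  schema <- jsonlite::read_json(system.file("schema", "provenance.schema.json",
                                            package = "gridtopo"))
  req <- unlist(schema$required)
  missing <- setdiff(req, names(prov))
  if (length(missing) > 0)
    stop("provenance block missing required field(s): ",
         paste(missing, collapse = ", "))
  if (!is.list(prov$parameters)) stop("provenance 'parameters' must be an object")
  invisible(TRUE)
}
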