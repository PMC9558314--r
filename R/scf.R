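#' Restricted Hartree-Fock adapter for benchmark densities
#'
#' A compact closed-shell Hartree-Fock engine (McMurchie-Davidson Gaussian
#' integrals, in-core screened two-electron integrals, DIIS) used to
#' generate real molecular electron densities for the topology pipeline,
#' e.g. the benzene bond-critical-point benchmark. It is deliberately
#' minimal: spherical-harmonic basis functions up to d, closed-shell
#' molecules, energies and densities only (no gradients, no post-HF).
#'
#' `rhf()` solves the SCF problem; `scf_density()` evaluates the resulting
#' electron density at arbitrary points (in chunks, so million-point grids
#' are fine).
#'
#' @param atoms data.frame with columns `Z`, `x`, `y`, `z` (bohr).
#' @param basis basis-set name; `"cc-pVDZ"` (H and C are tabulated).
#' @param max_iter,conv_e SCF iteration cap and energy convergence (hartree).
#' @param cartesian_d represent d shells by the six normalized cartesian
#'   components instead of the five spherical harmonics (adds one s-like
#'   degree of freedom per d shell).
#' @return `rhf()`: object of class `scf_result` with `energy` (hartree),
#'   `converged`, density matrix `P`, MO coefficients/energies, `shells`,
#'   `atoms`, `nelec`.
#' @export
rhf <- function(atoms, basis = "cc-pVDZ", max_iter = 100L, conv_e = 1e-9,
                cartesian_d = FALSE) {
  shells <- build_shells(atoms, basis)
  nelec <- sum(atoms$Z)
  zmat <- cbind(atoms$Z, atoms$x, atoms$y, atoms$z)
  res <- cpp_rhf(shells, zmat, as.integer(nelec), as.integer(max_iter), conv_e,
                 1e-6, cartesian_d)
  if (!res$converged)
    warning("SCF did not converge in ", max_iter, " iterations")
  structure(list(energy = res$energy, enuc = res$enuc,
                 converged = res$converged, P = res$P, C = res$C,
                 eps = as.numeric(res$eps), S = res$S, nbf = res$nbf,
                 shells = shells, atoms = atoms, nelec = nelec,
                 basis = basis, cartesian_d = cartesian_d),
            class = "scf_result")
}

#' @export
print.scf_result <- function(x, ...) {
  cat("<scf_result> E =", format(x$energy, digits = 12), "hartree,",
      x$nbf, "basis functions,", x$nelec, "electrons,",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' @rdname rhf
#' @param scf an `scf_result`.
#' @param points matrix of evaluation points (n x 3, bohr).
#' @param chunk evaluation chunk size (memory control).
#' @return `scf_density()`: numeric vector of densities (e/bohr^3).
#' @export
scf_density <- function(scf, points, chunk = 100000L) {
  stopifnot(inherits(scf, "scf_result"))
  points <- as_points(points, 3)
  n <- nrow(points)
  out <- numeric(n)
  for (start in seq(1, n, by = chunk)) {
    end <- min(n, start + chunk - 1)
    out[start:end] <- cpp_density(scf$shells, scf$P,
                                  points[start:end, , drop = FALSE],
                                  isTRUE(scf$cartesian_d))
  }
  out
}

# Tabulated cc-pVDZ sets (exponents in 1/bohr^2, unnormalized contraction
# coefficients); H: (4s,1p)->[2s,1p], C: (9s,4p,1d)->[3s,2p,1d].
ccpvdz_data <- function() {
  c_s_exps <- c(6665.0, 1000.0, 228.0, 64.71, 21.06, 7.495, 2.797, 0.5215,
                0.1596)
  list(
    H = list(
      list(l = 0L, exps = c(13.010, 1.962, 0.4446, 0.1220),
           coefs = c(0.0196850, 0.1379770, 0.4781480, 0.5012400)),
      list(l = 0L, exps = 0.1220, coefs = 1),
      list(l = 1L, exps = 0.7270, coefs = 1)),
    C = list(
      list(l = 0L, exps = c_s_exps,
           coefs = c(0.0006920, 0.0053290, 0.0270770, 0.1017180, 0.2747400,
                     0.4485640, 0.2850740, 0.0152040, -0.0031910)),
      list(l = 0L, exps = c_s_exps,
           coefs = c(-0.0001460, -0.0011540, -0.0057250, -0.0233120,
                     -0.0639550, -0.1499810, -0.1272620, 0.5445290,
                     0.5804960)),
      list(l = 0L, exps = 0.1596, coefs = 1),
      list(l = 1L, exps = c(9.439, 2.002, 0.5456, 0.1517),
           coefs = c(0.0381090, 0.2094800, 0.5085570, 0.4688420)),
      list(l = 1L, exps = 0.1517, coefs = 1),
      list(l = 2L, exps = 0.5500, coefs = 1)))
}

element_symbol <- function(Z) c("H", "He", "Li", "Be", "B", "C", "N", "O")[Z]

build_shells <- function(atoms, basis) {
  if (!identical(toupper(basis), "CC-PVDZ"))
    stop("only cc-pVDZ is tabulated")
  data <- ccpvdz_data()
  shells <- list()
  for (i in seq_len(nrow(atoms))) {
    sym <- element_symbol(atoms$Z[i])
    if (is.na(sym) || is.null(data[[sym]]))
      stop("no cc-pVDZ data tabulated for Z = ", atoms$Z[i])
    for (sh in data[[sym]]) {
      sh$center <- c(atoms$x[i], atoms$y[i], atoms$z[i])
      shells[[length(shells) + 1]] <- sh
    }
  }
  shells
}

#' Benzene geometry and its Hartree-Fock optimization
#'
#' `benzene_atoms()` builds a D6h benzene from its two degrees of freedom:
#' the C-C bond length (equal to the carbon ring circumradius) and the C-H
#' bond length, carbons in the xy-plane. `optimize_benzene()` minimizes the
#' RHF/cc-pVDZ energy over these two parameters by Newton steps on
#' finite-difference gradients (the full 2 x 2 Hessian is measured on the
#' first iteration and reused), which converges in one or two steps from a
#' standard aromatic starting geometry.
#'
#' @param r_cc,r_ch bond lengths in bohr.
#' @return `benzene_atoms()`: data.frame of 12 atoms (Z, x, y, z).
#' @export
benzene_atoms <- function(r_cc, r_ch) {
  th <- pi / 3 * (0:5)
  data.frame(
    Z = rep(c(6L, 1L), each = 6),
    x = c(r_cc * cos(th), (r_cc + r_ch) * cos(th)),
    y = c(r_cc * sin(th), (r_cc + r_ch) * sin(th)),
    z = rep(0, 12))
}

#' @rdname benzene_atoms
#' @param start numeric length 2, starting `(r_cc, r_ch)` in bohr.
#' @param h finite-difference step (bohr).
#' @param tol convergence threshold on the Newton step (bohr).
#' @param max_newton maximum Newton iterations.
#' @param verbose print per-iteration energies.
#' @return `optimize_benzene()`: list with optimized `r_cc`, `r_ch` (bohr),
#'   `energy` (hartree), and the final `scf_result`.
#' @export
optimize_benzene <- function(start = c(2.62, 2.04), h = 0.01, tol = 2e-4,
                             max_newton = 3L, verbose = FALSE) {
  x <- start
  ene <- function(p) rhf(benzene_atoms(p[1], p[2]))$energy
  H2 <- NULL
  for (it in seq_len(max_newton)) {
    e0 <- ene(x)
    ep <- c(ene(x + c(h, 0)), ene(x + c(0, h)))
    em <- c(ene(x - c(h, 0)), ene(x - c(0, h)))
    g <- (ep - em) / (2 * h)
    if (is.null(H2)) {
      hd <- (ep - 2 * e0 + em) / h^2
      epp <- ene(x + c(h, h))
      hx <- (epp - ep[1] - ep[2] + e0) / h^2
      H2 <- matrix(c(hd[1], hx, hx, hd[2]), 2, 2)
    }
    step <- solve(H2, -g)
    # trust region: bond lengths move at most 0.1 bohr per iteration
    step <- step * min(1, 0.1 / max(abs(step)))
    x <- x + step
    if (verbose)
      message(sprintf("newton %d: E = %.8f, |g| = %.2e, step = (%.5f, %.5f)",
                      it, e0, sqrt(sum(g^2)), step[1], step[2]))
    if (max(abs(step)) < tol) break
  }
  final <- rhf(benzene_atoms(x[1], x[2]))
  list(r_cc = x[1], r_ch = x[2], energy = final$energy, scf = final)
}
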