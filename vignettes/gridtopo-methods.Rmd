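---
title: "Graph-based topology of scalar fields on arbitrary grids: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based topology of scalar fields on arbitrary grids: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Quantum-chemical topology asks topographical questions of molecular scalar
fields: where are the maxima of the electron density $\rho$ (atoms), which
pairs of maxima are joined through first-order saddles (bonds), how much
charge lives in each basin of attraction (Bader charges), where does the
Laplacian $\nabla^2\rho$ concentrate charge (shells, lone pairs), where does
a magnetically induced current density vanish (stagnation graphs)?
Conventional tools answer them by evaluating the field and its derivatives
at arbitrary points. **gridtopo** instead answers them *strictly by
post-processing*: the only input is the set of values $F = \{f(x_i)\}$ on an
arbitrary point set $G$ — a uniform lattice, a random cloud, or the radially
graded atom-centered quadrature grid a DFT code already has — with no
further function evaluations. Everything becomes a graph problem.

## Neighborhood graphs

All topography needs a notion of "neighboring point". We encode it as an
undirected graph $N$ over $G$ and require, for bulk (non-convex-hull)
nodes:

1. *connected*, 2. *undirected*, 3. *basis-preserving* — the displacement
vectors $\{y - x\}$ to the neighbors of $x$ span all $d$ dimensions, so a
least-squares gradient exists — and 4. *move-preserving* — every direction
has a neighbor with positive projection, so the gradient can also be
*followed*. `validate_graph()` reports all four; the move-preserving test is
implemented as "the origin lies strictly inside the convex hull of the unit
displacement vectors", which is equivalent and robust.

$k$-nearest-neighbor graphs (`build_knn()`) fail requirements 1 and 4 in
general, which manifests as fictitious local maxima; they are provided to
demonstrate exactly that. The production construction is the Delaunay
triangulation (`build_delaunay()`, Qhull, reached through scipy via
reticulate — no installed R package triangulates in 3D): any triangulation
satisfies 1–4, and the Delaunay one additionally matches the adjacency of
Voronoi cells and avoids oversized neighborhoods.

**Degeneracy policy.** Uniform lattices and concentric shells are
cocircular/cospherical — degenerate for the empty-circumcircle criterion. We
apply a deterministic jitter of `1e-9` times the bounding-box diagonal
(seeded; the seed is part of the graph provenance) to the coordinates used
for triangulation only. Highly replicated structures can still exceed
Qhull's facet-merging tolerance, in which case the build retries with
Qhull's own deterministic joggle (`QJ`). The atom-centered grid generator
additionally staggers every shell (golden-angle rotation per shell and per
center), which removes most of the degeneracy at the source and costs the
quadrature nothing.

## Gradients

At each node the gradient is the least-squares solution of the first-order
Taylor expansion over the neighborhood: $M g = b$ with
$M = \sum_y (y-x)(y-x)^T$, $b = \sum_y (y-x)(f(y)-f(x))$. The residual norm
is unweighted (a distance-weighted variant exists behind a flag but is off
by default). Exact for affine fields; on rank-deficient neighborhoods
(possible on the hull) the minimum-norm restricted solution is returned and
the node flagged, never an error — a bad hull node must not abort a
million-point analysis. The *nearest-neighbor gradient field*
$g_{NN}(x) = g(x \to G)$ extends node gradients piecewise-constantly over
Voronoi cells via a kd-tree lookup; it is what the off-graph ascent
integrates.

## Basins, families, charges

Graph local maxima are nodes strictly above all neighbors; a constant field
has none. On-graph ascent repeatedly moves to the neighbor maximizing the
slope $(f(y)-f(x))/|y-x|$, with two determinism rules the continuum does
not need: slope ties break to the lower node index, and plateau steps
(slope exactly zero) are taken only toward lower indices, which guarantees
termination. Paths adopt the attractor of the first already-assigned node
they touch; an oracle mode (`shortcut = FALSE`) re-traces every path and is
used in tests to show shortcutting never changes the result.

Extended maxima (rings, shells, isosurfaces) appear on a graph as many
near-equal local maxima. They are clustered into *maxima families* by flood
fills under the deviation measure
$d(x, y) = \frac{f(x) - f(y)}{f(x) - f_{\min}} \in [0, 1]$,
with $f_{\min}$ the global minimum value: scale- and shift-free, and
automatically tighter around lower maxima. The exact algebraic form is our
choice among those with these properties; the default tolerance $t = 0.25$
separates well-isolated peaks while fusing ring- and shell-like structures,
and $t = 1$ merges everything reachable. Overlapping fills merge
transitively.

Basin integrals $Q_M = \sum_{A(x) \in M} w(x) \rho(x)$ use the grid's own
quadrature weights; grids without weights fall back to Monte-Carlo Voronoi
cell volumes clipped to the convex hull (seeded; exact constructions are
used in 1D and, via deldir, in 2D boxes). Because basins partition the
grid, family totals conserve $\sum w\rho$ to machine precision — a test,
not an aspiration.

**Grid bias and the off-graph ascent.** Constraining ascent to graph edges
biases basin boundaries systematically, and the bias *persists at infinite
grid density* (a path that should climb at 5° to a lattice axis will climb
along the axis). The correction integrates $g_{NN}$ freely in space with a
step of half the median incident edge length at the current nearest node —
the step must adapt to local density because quadrature grids are radially
graded — until the trajectory enters the Voronoi cell of a maximum or of an
assigned node. A cap of $10 N^{1/d}$ steps guards degenerate flat regions;
capped trajectories fall back to on-graph ascent with a warning. On the
tilted two-Gaussian lattice benchmark the on-graph misassigned-area
fraction is ~3% *and does not shrink with density*, while the off-graph
fraction is several-fold smaller at every density tested.

## Critical networks

With edge weights $(f(i)+f(j))/2$, the path between two maxima that
maximizes its minimum value — the discrete bond path — is the unique path
on the *maximum spanning tree* (widest-path property; verified against
brute-force enumeration over all simple paths on 100 seeded random graphs).
Kruskal's algorithm with ties broken by lexicographic edge order makes the
tree deterministic even on symmetric fields, where ties are exact by
construction. Pruning non-maximum leaves yields the critical tree; the
minimum-value node on each maxima-pair path is its critical point (bond
critical point for $\rho$).

**Gap-filling.** A spanning tree is acyclic, so of the two nearly degenerate
routes around an aromatic ring, exactly one bond is always missing. For
every maxima pair not already linked (path within two basins, *or* — our
addition, needed when a few misassigned nodes paint a third basin label
onto a genuine direct path — an interior-maximum-free path already exists),
whose basins are adjacent, the maximum spanning tree of the two-basin
subgraph proposes a path; it is accepted iff it avoids the subgraph
boundary, the signature that distinguishes a true interface saddle from a
rim artifact. Gap-filling only ever adds edges.

**Cleaving.** To isolate subtrees of nearly constant value (stagnation
lines of $-|J|$), each path is scored by the deviation $1 - \min_z s(z)$,
$s(z) = (f(z)-f_{\min})/(f_{\mathrm{scale}}-f_{\min})$ with
$f_{\mathrm{scale}}$ the larger endpoint (a mean-based statistic is
available behind a flag); paths at or above `t_flat` are removed.
`t_flat = "auto"` takes the first local minimum of a Gaussian kernel
density estimate (Scott bandwidth) of the deviation distribution, falling
back to 0.1 when unimodal. Flat fields have deviation 0 by definition.

## Field transforms

`negate()`, `abs_field()`, `isosurface_aux()` (`exp(-|f - f_iso|)`, maximal
exactly on the isosurface) and `vector_magnitude()` materialize derived
fields so that the one basin/network engine also finds minima, isosurface
components, $|\nabla^2\rho|$ shells and stagnation graphs. Transforms are
eager rather than lazy: provenance stays simple and memory is not a
constraint at these sizes.

## Synthetic models and grids

Every algorithm is testable without any electronic-structure input through
closed-form models with known topology and analytic gradients (checked
against central finite differences at random points): two-Gaussian fields,
the ring $-(|x|-1)^2$ (one extended family), Gaussian mixtures,
promolecules $\sum_k N_k (\alpha_k^3/\pi) e^{-2\alpha_k |x-R_k|}$ (each
term integrates to exactly $N_k$ electrons, giving analytic basin
populations), radial shell profiles, and an azimuthal ring-current field
whose magnitude vanishes on its axis. Grid generators cover uniform
lattices (cell-volume weights), seeded random clouds (Voronoi-volume
weights) and simplified atom-centered grids: geometric radial shells
(log-space quadrature rule) times staggered Fibonacci-spiral spheres, with
Becke partition-of-unity weights so overlapping per-center grids never
double count. The spiral layout stands in for tabulated angular rules:
only positivity and reasonable quadrature matter here, and the two-center
promolecule integrates to its analytic electron count within 0.5% at
modest sizes. What these models do *not* emulate: nuclear cusps of real
densities are only approximated by the exponential promolecule, field
noise is absent, and no synthetic model has the near-degenerate ring-bond
competition of a real aromatic density — which is why the package also
carries a real benchmark (below).

## The Hartree-Fock adapter and the benzene benchmark

Topological analysis of a real molecular density needs a density. The
package ships a compact closed-shell restricted Hartree-Fock engine
(McMurchie-Davidson integrals over contracted Gaussians up to d, spherical
harmonics, Schwarz-screened in-core two-electron integrals, DIIS) with the
cc-pVDZ basis tabulated for H and C. It reproduces standard reference
energies (H$_2$ at 1.4 bohr: $-1.128709$; CH$_4$: $-40.19869$; benzene:
$-230.72235$ hartree) and its H s-contraction is re-derived in tests from
the atomic eigenproblem it was originally defined by. The engine is
validated against an independently coded closed-form s-orbital HF oracle
and quadrature cross-checks of its integral matrices.

The benchmark (`benzene_bcp_densities()`): optimize the two D6h parameters
of benzene at RHF/cc-pVDZ (Newton on finite-difference gradients; two
iterations from a standard aromatic start, landing at $r_{CC} = 1.3886$ Å,
$r_{CH} = 1.0823$ Å), evaluate $\rho$ on an atom-centered grid, build the
Delaunay graph, basins, and the gap-filled critical network, and read the
density at the six C-C and six C-H bond critical points. The ring closure
is restored by gap-filling every time — the acyclic tree must drop exactly
one ring bond. Tree paths between non-bonded maxima (meta carbons) also
exist on the discrete tree; bond values are therefore selected by nucleus
identity (ring-adjacent C-C, bonded C-H). Grid resolution matters
asymmetrically: the bond saddle sits on the *radial* axis of both
neighboring atom grids, so the radial spacing near 1.3 bohr controls
convergence of C-C values; the default (80 radial shells × 420 angular
points per atom, ~4 × 10⁵ points in total) puts the discretization
error near $10^{-3}$ e/bohr³ or below.

Against the external converged references (0.31673 and 0.29443 e/bohr³),
our C-C value agrees to well under $10^{-3}$ both on-grid and at the
analytic saddle of our density (0.31726). Our C-H value converges to the
analytic saddle of our density, 0.28722, about 2.4% below the external
reference. We examined this gap exhaustively — the H contraction re-derived
exactly, cartesian-d and diffuse-augmented variants shift the value by
under $10^{-3}$, and no Hartree-Fock-plausible geometry moves C-H by
+0.007 while leaving C-C in place — and report the computed value as is;
the residual is attributed to an unstated detail of the reference setup.

## Numerical choices and limitations

* Deduplication tolerance $10^{-12}$ bohr, weights summed; triangulators
  fail on exact duplicates.
* Atom-centered grids start at $r_{\mathrm{inner}} = 0.01$ bohr: shells
  below that radius contribute $\sim 10^{-4}$ electron to any integral and
  nothing to the topology, while their $10^{-6}$-bohr point spacings push
  Qhull's absolute merge tolerances into wide-facet failures and destroy
  the $O(N \log N)$ triangulation cost.
* Tie-breaking everywhere by (value, then lower node index); all stages are
  deterministic given the recorded seeds.
* All randomness (jitter, random grids, Monte-Carlo weights) sits behind
  explicit seeds recorded in provenance; a result can be re-run
  bit-identically.
* Dimensions restricted to $d \in \{1,2,3\}$ (1D "triangulation" is the
  sorted chain); no periodic boundaries; no anisotropic triangulations.
* Basin boundaries are node partitions: no fractional assignment of
  boundary points, so integrals converge with some noise at coarse grids.
* Critical values are node values: no sub-grid interpolation or
  derivative-based refinement of critical-point positions.
* The RHF adapter is closed-shell, s/p/d, energies and densities only; it
  exists to feed the topology pipeline, not to compete with quantum
  chemistry packages.

## Problem sizes used in the shipped checks

Unit tests run on $10^2$–$10^3$-point grids; the end-to-end checks use 500
(gradient quality), 2000 × 10 seeds (ring families), 4000 (hexagonal
gap-fill), ~10⁵ (promolecule populations), ~4 × 10⁵ (benzene) and 10³–10⁶ (scaling
law, fitted log-log slope ≤ 1.3, consistent with the $O(N \log N)$ cost
of the triangulation). The acceptance script runs the same benzene
benchmark end to end.
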