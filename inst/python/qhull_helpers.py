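"""Qhull-backed geometry kernels used by gridtopo through reticulate.

All heavy lifting (Delaunay triangulation, convex hulls, Voronoi diagrams)
is delegated to scipy.spatial, i.e. to Qhull.  Only small glue lives here:
edge extraction from simplices and batched point-in-hull tests, done in
numpy so that million-point grids never round-trip through interpreted R
loops.
"""

import numpy as np
from scipy.spatial import Delaunay, ConvexHull, Voronoi, cKDTree


def delaunay_edges(points, qhull_options=None):
    """Delaunay triangulation of an (n, d) array, d in {2, 3}.

    Returns (edges, hull_idx, nsimplex): edges is an (m, 2) int array of
    0-based unique undirected edges with edges[:,0] < edges[:,1]; hull_idx
    are indices of convex-hull vertices; nsimplex the simplex count.
    qhull_options overrides scipy's defaults (e.g. "QJ" to joggle heavily
    degenerate inputs; qhull's joggle is deterministic for a given input).
    """
    pts = np.ascontiguousarray(points, dtype=np.float64)
    if qhull_options is not None:
        qhull_options = "Qbb Qc Qz " + qhull_options
    tri = Delaunay(pts, qhull_options=qhull_options)
    d = pts.shape[1]
    simp = tri.simplices
    pairs = []
    for i in range(d + 1):
        for j in range(i + 1, d + 1):
            pairs.append(simp[:, [i, j]])
    edges = np.vstack(pairs)
    edges.sort(axis=1)
    # dedupe via scalar codes: unique on a 1-D int64 array is far cheaper
    # than row-wise unique
    n = pts.shape[0]
    codes = np.unique(edges[:, 0].astype(np.int64) * n + edges[:, 1])
    edges = np.column_stack((codes // n, codes % n)).astype(np.int32)
    hull_idx = np.unique(tri.convex_hull.ravel())
    return edges, hull_idx, int(simp.shape[0])


def delaunay_simplices(points):
    """Simplices of the Delaunay triangulation (for empty-circumsphere checks)."""
    pts = np.ascontiguousarray(points, dtype=np.float64)
    return Delaunay(pts).simplices


def voronoi_adjacency(points):
    """Pairs of input points whose Voronoi cells share a facet (ridge)."""
    vor = Voronoi(np.ascontiguousarray(points, dtype=np.float64))
    rp = np.asarray(vor.ridge_points)
    rp.sort(axis=1)
    return np.unique(rp, axis=0)


def origin_strictly_inside(vectors, eps=1e-10):
    """True if 0 lies strictly inside the convex hull of the row vectors.

    Used for the move-preserving test: every direction must have a neighbor
    with positive projection, which holds iff the origin is interior to the
    hull of the unit displacement vectors.  Rank deficiency or an origin on
    the hull boundary both fail.
    """
    u = np.asarray(vectors, dtype=np.float64)
    d = u.shape[1]
    if u.shape[0] < d + 1:
        return False
    if np.linalg.matrix_rank(u, tol=1e-12) < d:
        return False
    try:
        hull = ConvexHull(u)
    except Exception:
        return False
    # facet equations n.x + c <= 0 inside; origin interior iff all c < -eps
    return bool(np.all(hull.equations[:, -1] < -eps))


def move_preserving_mask(points, adj_ptr, adj_idx, node_idx, eps=1e-10):
    """Batched move-preserving test for the 0-based nodes in node_idx.

    adj_ptr/adj_idx is a CSR adjacency (0-based).  Returns a boolean array.
    """
    pts = np.asarray(points, dtype=np.float64)
    adj_ptr = np.atleast_1d(np.asarray(adj_ptr, dtype=np.int64))
    adj_idx = np.atleast_1d(np.asarray(adj_idx, dtype=np.int64))
    node_idx = np.atleast_1d(np.asarray(node_idx, dtype=np.int64))
    out = np.zeros(len(node_idx), dtype=bool)
    for k, i in enumerate(node_idx):
        nb = adj_idx[adj_ptr[i]:adj_ptr[i + 1]]
        u = pts[nb] - pts[i]
        nrm = np.linalg.norm(u, axis=1)
        u = u[nrm > 0] / nrm[nrm > 0, None]
        out[k] = origin_strictly_inside(u, eps)
    return out


def hull_vertices(points):
    """Indices of the points that are vertices of the convex hull."""
    return np.unique(ConvexHull(np.asarray(points, dtype=np.float64)).vertices)


def hull_volume(points):
    """Volume (area in 2D) of the convex hull of the points."""
    return float(ConvexHull(np.asarray(points, dtype=np.float64)).volume)


def in_hull_mask(points, queries):
    """Boolean mask of which query points lie inside the convex hull of points."""
    tri = Delaunay(np.ascontiguousarray(points, dtype=np.float64))
    return tri.find_simplex(np.ascontiguousarray(queries, dtype=np.float64)) >= 0
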