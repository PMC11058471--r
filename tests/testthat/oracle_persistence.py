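#!/usr/bin/env python
"""Independent persistent-homology oracle used by the test suite.

Reads a 3D point cloud (CSV, columns x,y,z), builds either a Vietoris-Rips
filtration (diameter convention, dims <= 3) by direct enumeration or an
alpha complex from scipy's Qhull Delaunay triangulation with filtration
values computed from the definition (squared radius of the smallest empty
circumscribing ball, minimised over cofaces), reduces the boundary matrix
over GF(2) using big-integer XOR columns, and writes the barcode (dims 0-2)
as CSV: dim,birth,death (death = inf for essential classes).

Usage: python oracle_persistence.py points.csv {vr|ac} {threshold|auto} out.csv
"""
import sys
import itertools
import numpy as np
from scipy.spatial import Delaunay


def circumball(pts):
    """Center and squared radius of the smallest ball with all pts on its
    boundary (affinely independent point set, 1-4 points)."""
    p0 = pts[0]
    if len(pts) == 1:
        return p0, 0.0
    # center = p0 + U^T y constrained to the affine hull of the simplex;
    # equidistance gives 2 U U^T y = |p_i - p0|^2 row-wise.
    U = pts[1:] - p0
    G = 2.0 * (U @ U.T)
    rhs = np.sum(U ** 2, axis=1)
    y = np.linalg.solve(G, rhs)
    x = U.T @ y
    return p0 + x, float(np.sum(x ** 2))


def vr_complex(P, maxdim, threshold):
    n = len(P)
    D = np.sqrt(np.sum((P[:, None, :] - P[None, :, :]) ** 2, axis=2))
    simplices = [((i,), 0.0) for i in range(n)]
    for d in range(1, maxdim + 1):
        for comb in itertools.combinations(range(n), d + 1):
            v = max(D[i][j] for i, j in itertools.combinations(comb, 2))
            if v <= threshold:
                simplices.append((comb, float(v)))
    return simplices


def alpha_complex(P):
    tri = Delaunay(P)
    tets = set()
    for s in tri.simplices:
        tets.add(tuple(sorted(int(v) for v in s)))
    complex_ = set()
    for t in tets:
        for d in range(1, 5):
            for face in itertools.combinations(t, d):
                complex_.add(face)
    # cofaces of each simplex
    cof = {s: set() for s in complex_}
    for t in tets:
        subs = [f for d in range(1, 5) for f in itertools.combinations(t, d)]
        for a in subs:
            sa = set(a)
            for b in subs:
                if sa.issubset(b):
                    cof[a].add(b)
    values = {}
    for s in complex_:
        if len(s) == 1:
            values[s] = 0.0
            continue
        best = np.inf
        for sigma in cof[s]:
            c, r2 = circumball(P[list(sigma)])
            # empty: no point strictly inside (tolerant strictness)
            d2 = np.sum((P - c) ** 2, axis=1)
            inside = d2 < r2 * (1.0 - 1e-10) - 1e-12
            if not np.any(inside):
                best = min(best, r2)
        values[s] = float(best)
    return sorted(values.items(), key=lambda kv: kv[0])


def reduce_persistence(simplices):
    """simplices: list of (vertex tuple, value). Returns (dim,birth,death).

    Standard column reduction over GF(2) with big-integer XOR columns and
    the twist (clearing) optimisation: dimensions are processed in
    decreasing order and pivot rows are never themselves reduced."""
    order = sorted(range(len(simplices)),
                   key=lambda i: (simplices[i][1], len(simplices[i][0]),
                                  simplices[i][0]))
    index = {simplices[order[r]][0]: r for r in range(len(order))}
    maxdim = max(len(s[0]) for s in simplices) - 1
    cols = {}
    pivot = {}
    pairs = []
    cleared = set()
    for d in range(maxdim, 0, -1):
        for r in range(len(order)):
            verts, _ = simplices[order[r]]
            if len(verts) - 1 != d or r in cleared:
                continue
            col = 0
            for f in range(len(verts)):
                face = verts[:f] + verts[f + 1:]
                col ^= 1 << index[face]
            while col:
                low = col.bit_length() - 1
                if low not in pivot:
                    pivot[low] = r
                    cols[r] = col
                    pairs.append((low, r))
                    cleared.add(low)
                    break
                col ^= cols[pivot[low]]
    paired = set(pivot.keys()) | set(pivot.values())
    out = []
    for lo, hi in pairs:
        vb, birth = simplices[order[lo]]
        _, death = simplices[order[hi]]
        if death != birth and len(vb) - 1 <= 2:
            out.append((len(vb) - 1, birth, death))
    for r in range(len(order)):
        if r not in paired:
            verts, birth = simplices[order[r]]
            if len(verts) - 1 <= 2:
                out.append((len(verts) - 1, birth, float("inf")))
    return out


def main():
    pts_csv, mode, threshold, out_csv = sys.argv[1:5]
    P = np.loadtxt(pts_csv, delimiter=",", ndmin=2)
    if mode == "vr":
        D = np.sqrt(np.sum((P[:, None, :] - P[None, :, :]) ** 2, axis=2))
        # auto = full filtration: pad the diameter by a relative epsilon so
        # last-ulp differences with the caller's distance computation cannot
        # drop the diameter simplex itself
        thr = (float(D.max()) * (1 + 1e-9) if threshold == "auto"
               else float(threshold))
        simplices = vr_complex(P, 3, thr)
    elif mode == "ac":
        simplices = alpha_complex(P)
    else:
        raise SystemExit("mode must be vr or ac")
    bars = reduce_persistence(simplices)
    with open(out_csv, "w") as fh:
        fh.write("dim,birth,death\n")
        for d, b, dd in sorted(bars):
            fh.write("%d,%.17g,%s\n" % (d, b,
                     "inf" if dd == float("inf") else "%.17g" % dd))


if __name__ == "__main__":
    main()
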