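"""MILP backend for the maximum quasi-clique formulation.

Reads {n, edges (0-based, may be empty), gamma_num, gamma_den} from the
JSON file given as argv[1], solves the linearized model with
scipy.optimize.milp (HiGHS), and writes {status, objective, x} to
argv[2].  Variables: x_0..x_{n-1} binary, then w for each pair i<j in
row-major order.  Constraints per pair: w - x_i <= 0, w - x_j <= 0,
x_i + x_j - w <= 1; density row: sum_E (b-a) w - sum_nonE a w >= 0.
"""
import json
import sys

import numpy as np
from scipy.optimize import Bounds, LinearConstraint, milp
from scipy.sparse import csr_matrix


def main(fin, fout):
    with open(fin) as fh:
        prob = json.load(fh)
    n = int(prob["n"])
    a = float(prob["gamma_num"])
    b = float(prob["gamma_den"])
    edges = prob.get("edges") or []
    eset = set()
    for e in edges:
        i, j = int(e[0]), int(e[1])
        eset.add((min(i, j), max(i, j)))

    pairs = [(i, j) for i in range(n) for j in range(i + 1, n)]
    npairs = len(pairs)
    nv = n + npairs

    rows, cols, vals, lo, hi = [], [], [], [], []
    r = 0
    for q, (i, j) in enumerate(pairs):
        wq = n + q
        for xi in (i, j):                      # w - x <= 0
            rows += [r, r]
            cols += [wq, xi]
            vals += [1.0, -1.0]
            lo.append(-np.inf)
            hi.append(0.0)
            r += 1
        rows += [r, r, r]                      # x_i + x_j - w <= 1
        cols += [i, j, wq]
        vals += [1.0, 1.0, -1.0]
        lo.append(-np.inf)
        hi.append(1.0)
        r += 1
    for q, (i, j) in enumerate(pairs):         # density row
        coef = (b - a) if (i, j) in eset else -a
        rows.append(r)
        cols.append(n + q)
        vals.append(coef)
    lo.append(0.0)
    hi.append(np.inf)
    r += 1

    A = csr_matrix((vals, (rows, cols)), shape=(r, nv))
    c = np.concatenate([-np.ones(n), np.zeros(npairs)])  # maximize sum x
    integrality = np.concatenate([np.ones(n), np.zeros(npairs)])
    res = milp(c=c, constraints=LinearConstraint(A, lo, hi),
               integrality=integrality, bounds=Bounds(0.0, 1.0))
    out = {
        "status": int(res.status),
        "objective": float(-res.fun) if res.fun is not None else None,
        "x": [float(v) for v in res.x[:n]] if res.x is not None else None,
    }
    with open(fout, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
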