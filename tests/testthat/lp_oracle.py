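"""Linear-programming feasibility oracle for convex-hull membership.

Reads JSON from stdin: a list of cases, each {"hull": [[...]], "queries": [[...]]}.
A query point q is inside the hull of points H iff the LP
    find lambda >= 0,  sum(lambda) = 1,  H^T lambda = q
is feasible. Writes a JSON list (one list of 0/1 per case) to stdout.
Used by the test suite as an independent oracle for in_hull/constrain_pool.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def inside(hull, q):
    k = hull.shape[0]
    A_eq = np.vstack([hull.T, np.ones((1, k))])
    b_eq = np.concatenate([q, [1.0]])
    res = linprog(np.zeros(k), A_eq=A_eq, b_eq=b_eq,
                  bounds=[(0, None)] * k, method="highs")
    return int(res.status == 0)


def main():
    cases = json.load(sys.stdin)
    out = []
    for case in cases:
        hull = np.asarray(case["hull"], dtype=float)
        queries = np.asarray(case["queries"], dtype=float)
        if queries.ndim == 1:
            queries = queries[None, :]
        out.append([inside(hull, q) for q in queries])
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
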