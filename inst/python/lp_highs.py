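"""Solve one LP with scipy's HiGHS interface.

Reads a problem written by sonoplan's R side as a small JSON header plus
flat little-endian double/int32 binary arrays, solves

    min c'x   s.t.  A x (<=|>=|==) b,   lo <= x <= hi,

and writes the solution back as JSON + binary. Called as
    python lp_highs.py <indir> <outdir>
"""
import json
import os
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import linprog


def rdbl(d, name, n):
    return np.fromfile(os.path.join(d, name + ".bin"), dtype="<f8", count=n)


def rint(d, name, n):
    return np.fromfile(os.path.join(d, name + ".bin"), dtype="<i4", count=n)


def main(indir, outdir):
    hdr = json.load(open(os.path.join(indir, "header.json")))
    m, n, nnz = hdr["m"], hdr["n"], hdr["nnz"]
    ai = rint(indir, "ai", nnz) - 1
    aj = rint(indir, "aj", nnz) - 1
    ax = rdbl(indir, "ax", nnz)
    b = rdbl(indir, "b", m)
    sense = rint(indir, "sense", m)
    c = rdbl(indir, "c", n)
    lo = rdbl(indir, "lo", n)
    hi = rdbl(indir, "hi", n)
    hi = np.where(hi >= 1e29, np.inf, hi)
    lo = np.where(lo <= -1e29, -np.inf, lo)

    sgn = np.where(sense > 0, -1.0, 1.0)  # >= rows are negated into <=
    ub = sense != 0
    A = sparse.csr_matrix((ax * sgn[ai], (ai, aj)), shape=(m, n))
    r = linprog(
        c,
        A_ub=A[ub] if ub.any() else None,
        b_ub=(b * sgn)[ub] if ub.any() else None,
        A_eq=A[~ub] if (~ub).any() else None,
        b_eq=b[~ub] if (~ub).any() else None,
        bounds=np.column_stack([lo, hi]),
        method=hdr.get("method", "highs"),
    )
    status = {0: "optimal", 1: "iteration_limit", 2: "infeasible",
              3: "unbounded"}.get(r.status, "error")
    x = r.x if r.x is not None else np.zeros(n)
    x.astype("<f8").tofile(os.path.join(outdir, "x.bin"))
    json.dump(
        {"status": status, "objective": float(r.fun) if r.fun is not None
         else float("nan")},
        open(os.path.join(outdir, "result.json"), "w"))


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
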