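"""Solve max c'x s.t. A x = b, x >= 0 with the HiGHS solver.

Reads A.mtx (MatrixMarket), c.txt and beq.txt (one number per line) from the
directory given as the single argument and writes solution.json there with
the maximized objective, the primal solution and the equality-constraint
duals.
"""
import json
import sys

import numpy as np
import scipy.io
import scipy.optimize
import scipy.sparse


def main(workdir):
    A = scipy.io.mmread(f"{workdir}/A.mtx").tocsr()
    c = np.loadtxt(f"{workdir}/c.txt")
    b = np.loadtxt(f"{workdir}/beq.txt")
    res = scipy.optimize.linprog(
        -c, A_eq=A, b_eq=b, bounds=(0, None), method="highs")
    out = {
        "status": int(res.status),
        "message": str(res.message),
        "objective": float(-res.fun) if res.status == 0 else None,
        "x": res.x.tolist() if res.x is not None else None,
        "duals": (-res.eqlin.marginals).tolist() if res.status == 0 else None,
    }
    with open(f"{workdir}/solution.json", "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1])
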