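"""Reference LP solutions for the test suite (scipy HiGHS).

Usage: python lp_oracle.py problems.json results.json
Each problem: {c, Aeq, beq, lb, ub, maximize}; result: {status, value}.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def solve(p):
    c = np.asarray(p["c"], dtype=float)
    sign = -1.0 if p["maximize"] else 1.0
    res = linprog(
        sign * c,
        A_eq=np.asarray(p["Aeq"], dtype=float),
        b_eq=np.asarray(p["beq"], dtype=float),
        bounds=list(zip(p["lb"], p["ub"])),
        method="highs",
    )
    if res.status == 0:
        return {"status": "optimal", "value": float(sign * res.fun)}
    return {"status": "infeasible" if res.status == 2 else "failed",
            "value": None}


def main():
    with open(sys.argv[1]) as fh:
        problems = json.load(fh)
    results = [solve(p) for p in problems]
    with open(sys.argv[2], "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main()
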