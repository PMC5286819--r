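"""Independent LP oracle for the test suite.

Reads a JSON list of LPs   {A, rhs, sense, obj, lb, ub}   (row-major A),
solves each with scipy.optimize.linprog (HiGHS) and writes a JSON list of
{status, objective}.  Status: "optimal", "infeasible", "unbounded".
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def solve(p):
    A = np.atleast_1d(np.array(p["A"], dtype=float)).reshape(p["m"], p["n"])
    rhs = np.atleast_1d(np.array(p["rhs"], dtype=float))
    sense = p["sense"] if isinstance(p["sense"], list) else [p["sense"]]
    obj = np.atleast_1d(np.array(p["obj"], dtype=float))
    lb = [None if v is None else v for v in p["lb"]]
    ub = [None if v is None else v for v in p["ub"]]
    bounds = list(zip(lb, ub))
    A_ub, b_ub, A_eq, b_eq = [], [], [], []
    for i, s in enumerate(sense):
        if s == "<=":
            A_ub.append(A[i]); b_ub.append(rhs[i])
        elif s == ">=":
            A_ub.append(-A[i]); b_ub.append(-rhs[i])
        else:
            A_eq.append(A[i]); b_eq.append(rhs[i])
    res = linprog(obj,
                  A_ub=np.array(A_ub) if A_ub else None,
                  b_ub=np.array(b_ub) if b_ub else None,
                  A_eq=np.array(A_eq) if A_eq else None,
                  b_eq=np.array(b_eq) if b_eq else None,
                  bounds=bounds, method="highs")
    if res.status == 0:
        return {"status": "optimal", "objective": float(res.fun)}
    if res.status == 2:
        return {"status": "infeasible", "objective": None}
    if res.status == 3:
        return {"status": "unbounded", "objective": None}
    return {"status": "error", "objective": None}


def main():
    with open(sys.argv[1]) as fh:
        problems = json.load(fh)
    out = [solve(p) for p in problems]
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
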