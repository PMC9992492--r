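"""Thin MILP driver: reads a token stream of assembled models, solves each
with scipy's HiGHS branch-and-bound, writes a JSON list of solutions.

Usage: milp_solve.py <infile> <outfile> <time_limit_seconds>

Problem kinds (models are fully assembled by the caller):
  0  minimum-input: binary x_e per link, matching rows <= 1 per node copy,
     closed in-neighborhood of every node must hold an unmatched node.
  1  minimum dominating set: binary y_v per node, every closed
     in-neighborhood must hold a selected node.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp


def closed_nbhd(n, gf, gt):
    # C[v, k] = 1 iff k == v or (k -> v) is an accessibility link
    rows = np.concatenate([gt, np.arange(n)])
    cols = np.concatenate([gf, np.arange(n)])
    data = np.ones(len(rows))
    return sparse.csr_matrix((data, (rows, cols)), shape=(n, n))


def pack(res, n_var):
    out = {"status": int(res.status), "objective": None, "x": None}
    if res.x is not None:
        x = np.rint(res.x).astype(int)
        out["x"] = x.tolist()
        out["objective"] = float(res.fun) if res.fun is not None else None
    return out


def solve_min_input(n, bf, bt, gf, gt, tl):
    m = len(bf)
    ones = np.ones(m)
    a_out = sparse.csr_matrix((ones, (bf, np.arange(m))), shape=(n, m))
    a_in = sparse.csr_matrix((ones, (bt, np.arange(m))), shape=(n, m))
    c_nb = closed_nbhd(n, gf, gt)
    a_dom = c_nb @ a_in  # counts matched in-links inside each neighborhood
    nb_size = np.asarray(c_nb.sum(axis=1)).ravel()
    cons = [
        LinearConstraint(a_out, -np.inf, 1),
        LinearConstraint(a_in, -np.inf, 1),
        LinearConstraint(a_dom, -np.inf, nb_size - 1),
    ]
    # valid inequality: the input set is a dominating set of G_l, so the
    # number of matched links is at most n - N_DS; the set-cover bound is
    # cheap to certify and lifts the weak LP relaxation considerably
    mds = milp(c=np.ones(n), constraints=[LinearConstraint(c_nb, 1, np.inf)],
               integrality=np.ones(n), bounds=Bounds(0, 1),
               options={"time_limit": max(tl / 4, 5), "mip_rel_gap": 0.0})
    if mds.status == 0:
        n_ds = float(np.round(mds.fun))
        cons.append(LinearConstraint(np.ones((1, m)), -np.inf, n - n_ds))
    res = milp(c=-np.ones(m), constraints=cons, integrality=np.ones(m),
               bounds=Bounds(0, 1),
               options={"time_limit": tl, "mip_rel_gap": 0.0})
    return pack(res, m)


def solve_mds(n, gf, gt, tl):
    c_nb = closed_nbhd(n, gf, gt)
    cons = [LinearConstraint(c_nb, 1, np.inf)]
    res = milp(c=np.ones(n), constraints=cons, integrality=np.ones(n),
               bounds=Bounds(0, 1),
               options={"time_limit": tl, "mip_rel_gap": 0.0})
    return pack(res, n)


def main():
    infile, outfile, tl = sys.argv[1], sys.argv[2], float(sys.argv[3])
    toks = open(infile).read().split()
    pos = 0

    def take(k):
        nonlocal pos
        v = np.array(toks[pos:pos + k], dtype=np.int64)
        pos += k
        return v

    n_prob = int(toks[pos]); pos += 1
    out = []
    for _ in range(n_prob):
        kind, n, m_b, m_g = (int(t) for t in toks[pos:pos + 4])
        pos += 4
        bf, bt = take(m_b) - 1, take(m_b) - 1
        gf, gt = take(m_g) - 1, take(m_g) - 1
        if kind == 0:
            out.append(solve_min_input(n, bf, bt, gf, gt, tl))
        else:
            out.append(solve_mds(n, gf, gt, tl))
    with open(outfile, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
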