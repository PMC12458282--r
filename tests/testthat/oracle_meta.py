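"""Independent reference implementation for the meta-analysis oracle test.

Reads a JSON file with per-case group summary statistics, recomputes the
standardized effect sizes (bias-corrected SMD with its standard error),
the DerSimonian-Laird between-study variance and the random-effects pooled
estimate/SE in numpy, cross-checks tau2/pooling against
statsmodels.stats.meta_analysis where its (unclipped) moment estimate is
non-negative, and writes the results as JSON.

Usage: python oracle_meta.py input.json output.json
"""
import json
import sys

import numpy as np
from statsmodels.stats.meta_analysis import combine_effects


def effect_size(m1, s1, n1, m2, s2, n2):
    s_pooled = np.sqrt(((n1 - 1) * s1**2 + (n2 - 1) * s2**2)
                       / (n1 + n2 - 2))
    smd = (m1 - m2) / s_pooled
    n = n1 + n2
    g = smd * (1 - 3.0 / (4 * n - 9))
    se = np.sqrt(n / (n1 * n2) + g**2 / (2 * n))
    return g, se


def dl_pool(g, se):
    w = 1.0 / se**2
    gbar = np.sum(w * g) / np.sum(w)
    q = np.sum(w * (g - gbar) ** 2)
    denom = np.sum(w) - np.sum(w**2) / np.sum(w)
    tau2 = max(0.0, (q - (len(g) - 1)) / denom)
    wr = 1.0 / (se**2 + tau2)
    est = np.sum(wr * g) / np.sum(wr)
    pooled_se = np.sqrt(1.0 / np.sum(wr))
    return tau2, est, pooled_se


def main(path_in, path_out):
    cases = json.load(open(path_in))
    out = []
    for case in cases:
        m1 = np.asarray(case["mean1"], dtype=float)
        s1 = np.asarray(case["sd1"], dtype=float)
        n1 = np.asarray(case["n1"], dtype=float)
        m2 = np.asarray(case["mean2"], dtype=float)
        s2 = np.asarray(case["sd2"], dtype=float)
        n2 = np.asarray(case["n2"], dtype=float)
        g, se = effect_size(m1, s1, n1, m2, s2, n2)
        tau2, est, pooled_se = dl_pool(g, se)
        res = {"g": g.tolist(), "se": se.tolist(), "tau2": tau2,
               "estimate": est, "pooled_se": pooled_se,
               "sm_checked": False}
        # statsmodels cross-check where its unclipped DL tau2 is >= 0
        cr = combine_effects(g, se**2, method_re="dl")
        if cr.tau2 >= 0:
            res["sm_checked"] = True
            res["sm_tau2"] = float(cr.tau2)
            res["sm_estimate"] = float(cr.mean_effect_re)
            res["sm_pooled_se"] = float(cr.sd_eff_w_re)
        out.append(res)
    json.dump(out, open(path_out, "w"))


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
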