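#!/usr/bin/env python
"""Independent Mondrian ICP p-value oracle (numpy).

Reads a CSV with columns: role (calib|test), label (0/1 for calib rows,
ignored for test rows), s0, s1 (class probabilities). Computes, for each test
row and each class c, the unsmoothed class-conditional conformal p-value

    p_c = (#{alpha_i >= alpha_test} + 1) / (n_c + 1),   alpha = 1 - s_c,

over the calibration rows with true label c, and writes CSV (p0, p1) to the
output path. Deliberately vectorised with outer comparisons rather than any
sorting/searching scheme, so it shares no mechanism with the implementation
it checks.
"""
import sys

import numpy as np
import pandas as pd


def main(inp, out):
    df = pd.read_csv(inp)
    calib = df[df.role == "calib"]
    test = df[df.role == "test"]
    cols = {}
    for cls, score_col in ((0, "s0"), (1, "s1")):
        cal_alpha = 1.0 - calib.loc[calib.label == cls, score_col].to_numpy()
        test_alpha = 1.0 - test[score_col].to_numpy()
        ge = (cal_alpha[None, :] >= test_alpha[:, None]).sum(axis=1)
        cols[f"p{cls}"] = (ge + 1.0) / (len(cal_alpha) + 1.0)
    pd.DataFrame(cols).to_csv(out, index=False)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
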