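"""Bridge: dump a supplementary-style .mat archive to JSON.

Expected layout (synthetic stand-in, documented in the package; the mapping
table inst/extdata/mat_mapping.csv may be revised per real archive): a single
top-level struct `D` with scalar fields `protocol` (char) and `fs`, and a
struct array `trials` whose per-trial fields are listed in the mapping table.
Anything else exits non-zero after listing the variables found, so the caller
can raise an informative import error.
"""
import json
import sys

import numpy as np
from scipy.io import loadmat


def to_plain(v):
    if isinstance(v, np.ndarray):
        if v.dtype.kind in "US":
            return str(v.item()) if v.size == 1 else [str(x) for x in v.ravel()]
        return [float(x) for x in np.atleast_1d(v).ravel()]
    if isinstance(v, (np.floating, np.integer)):
        return float(v)
    if isinstance(v, bytes):
        return v.decode()
    return v


def main(mat_path, out_path):
    m = loadmat(mat_path, squeeze_me=True, struct_as_record=False)
    user_vars = [k for k in m if not k.startswith("__")]
    if "D" not in user_vars:
        json.dump({"variables": user_vars}, open(out_path, "w"))
        return 0
    d = m["D"]
    fields = getattr(d, "_fieldnames", [])
    if "trials" not in fields:
        json.dump({"variables": user_vars + fields}, open(out_path, "w"))
        return 0
    trials = np.atleast_1d(d.trials)
    out = {
        "protocol": to_plain(getattr(d, "protocol", "")),
        "fs": to_plain(getattr(d, "fs", 100.0)),
        "trials": [
            {f: to_plain(getattr(t, f)) for f in getattr(t, "_fieldnames", [])}
            for t in trials
        ],
    }
    json.dump(out, open(out_path, "w"))
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv[1], sys.argv[2]))
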