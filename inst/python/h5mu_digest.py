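#!/usr/bin/env python
"""Independent decoder for .h5mu files, used to verify that the dialect is
readable outside R. Reads a file with h5py only (no anndata/mudata) and
prints a JSON digest: modality order, shapes, axis names, annotation
columns with full values (missing encoded as null), matrix checksums and
axis maps. Values are rounded to 10 decimals so the digest is a stable
cross-language fingerprint."""
import json
import sys

import h5py
import numpy as np


def rnd(x):
    return round(float(x), 10)


def decode_strings(arr):
    return [s.decode() if isinstance(s, bytes) else str(s) for s in arr]


def read_column(node):
    if isinstance(node, h5py.Group):  # categorical
        codes = node["codes"][:].astype(int)
        cats = decode_strings(node["categories"][:])
        return {"kind": "categorical", "categories": cats,
                "values": [None if c < 0 else cats[c] for c in codes]}
    enc = node.attrs.get("encoding-type")
    enc = enc.decode() if isinstance(enc, bytes) else enc
    v = node[:]
    if enc == "boolean":
        return {"kind": "boolean",
                "values": [None if x < 0 else bool(x) for x in v.astype(int)]}
    if enc == "integer":
        return {"kind": "integer",
                "values": [None if np.isnan(x) else int(x) for x in v]}
    if v.dtype.kind in "OSU":
        return {"kind": "string", "values": decode_strings(v)}
    if v.dtype.kind in "iu":
        return {"kind": "integer", "values": [int(x) for x in v]}
    return {"kind": "float",
            "values": [None if np.isnan(x) else rnd(x) for x in v]}


def read_dataframe(g):
    idx_name = g.attrs.get("_index", "_index")
    if isinstance(idx_name, bytes):
        idx_name = idx_name.decode()
    order = [c for c in decode_strings(np.atleast_1d(g.attrs.get("column-order", [])))
             if c]
    return {"index": decode_strings(g[idx_name][:]),
            "columns": {c: read_column(g[c]) for c in order},
            "column_order": order}


def matrix_digest(node):
    if isinstance(node, h5py.Group):  # CSR
        data = node["data"][:]
        return {"kind": "csr", "shape": [int(x) for x in node.attrs["shape"]],
                "nnz": int(data.size), "sum": rnd(data.sum()),
                "indices_sum": int(node["indices"][:].sum()),
                "indptr_last": int(node["indptr"][-1])}
    v = node[:]
    return {"kind": "dense", "shape": [int(s) for s in v.shape],
            "sum": rnd(np.nansum(v)),
            "first_row": [rnd(x) for x in np.ravel(v)[: min(10, v.size)]]}


def main(path):
    out = {}
    with h5py.File(path, "r") as f:
        out["encoding_type"] = f.attrs["encoding-type"]
        if isinstance(out["encoding_type"], bytes):
            out["encoding_type"] = out["encoding_type"].decode()
        mods = decode_strings(f["mod"].attrs["mod-order"])
        out["mod_order"] = mods
        out["obs"] = read_dataframe(f["obs"])
        out["var"] = read_dataframe(f["var"])
        out["obsmap"] = {m: [int(x) for x in f["obsmap"][m][:]] for m in mods}
        out["varmap"] = {m: [int(x) for x in f["varmap"][m][:]] for m in mods}
        out["mod"] = {}
        for m in mods:
            g = f["mod"][m]
            out["mod"][m] = {"X": matrix_digest(g["X"]),
                             "obs": read_dataframe(g["obs"]),
                             "var": read_dataframe(g["var"]),
                             "layers": {k: matrix_digest(g["layers"][k])
                                        for k in sorted(g["layers"])}}
    json.dump(out, sys.stdout, sort_keys=True)


if __name__ == "__main__":
    main(sys.argv[1])
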