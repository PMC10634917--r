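"""CSV <-> HDF5 bridge for localization tables.

Layout: one group per target, one dataset per column (x, y, frame, photons,
sigma, precision), acquisition metadata as group attributes. Invoked by the
R package; the CSV intermediate carries doubles at %.17g so values survive
the round trip bitwise.

Usage: h5_bridge.py w <h5> <csv> [target]   # csv (+ .yaml sidecar) -> h5
       h5_bridge.py r <h5> <csv> [target]   # h5 -> csv (+ .yaml sidecar)
"""
import sys

import h5py
import numpy as np
import yaml

COLS = ["x", "y", "frame", "photons", "sigma", "precision"]


def read_csv(path):
    with open(path) as fh:
        header = fh.readline().strip().split(",")
        rows = [line.strip().split(",") for line in fh if line.strip()]
    data = {}
    for k, name in enumerate(header):
        vals = [r[k] for r in rows]
        if name == "frame":
            data[name] = np.array([int(v) for v in vals], dtype=np.int64)
        else:
            data[name] = np.array(
                [np.nan if v in ("NA", "") else float(v) for v in vals],
                dtype=np.float64)
    return data


def main():
    mode, h5_path, csv_path = sys.argv[1:4]
    target = sys.argv[4] if len(sys.argv) > 4 else None
    if mode == "w":
        with open(csv_path + ".yaml") as fh:
            meta = yaml.safe_load(fh)
        data = read_csv(csv_path)
        target = target or meta.get("target_id", "target")
        with h5py.File(h5_path, "a") as f:
            if target in f:
                del f[target]
            g = f.create_group(target)
            for c in COLS:
                if c in data:
                    g.create_dataset(c, data=data[c])
            g.attrs["pixel_size_nm"] = float(meta["pixel_size_nm"])
            g.attrs["n_frames"] = int(meta["n_frames"])
            g.attrs["target_id"] = target
            g.attrs["units"] = meta.get("units", "nm")
    elif mode == "r":
        with h5py.File(h5_path, "r") as f:
            target = target or sorted(f.keys())[0]
            g = f[target]
            cols = [c for c in COLS if c in g]
            arrs = {c: g[c][...] for c in cols}
            meta = {
                "units": str(g.attrs.get("units", "nm")),
                "pixel_size_nm": float(g.attrs["pixel_size_nm"]),
                "n_frames": int(g.attrs["n_frames"]),
                "target_id": str(g.attrs.get("target_id", target)),
            }
        n = len(arrs[cols[0]]) if cols else 0
        with open(csv_path, "w") as fh:
            fh.write(",".join(cols) + "\n")
            for i in range(n):
                cells = []
                for c in cols:
                    v = arrs[c][i]
                    if c == "frame":
                        cells.append(str(int(v)))
                    else:
                        cells.append("NA" if np.isnan(v) else "%.17g" % v)
                fh.write(",".join(cells) + "\n")
        with open(csv_path + ".yaml", "w") as fh:
            yaml.safe_dump(meta, fh)
    else:
        raise SystemExit("unknown mode: " + mode)


if __name__ == "__main__":
    main()
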