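"""Batch UMAP embedding over a parameter grid.

Usage: python umap_grid.py X.csv grid.csv outdir metric seed

X.csv: dense 0/1 matrix, no header. grid.csv: rows "n_neighbors,min_dist".
Writes outdir/emb_<i>.csv per successful grid row. One process for the whole
grid so the numba JIT cost is paid once.
"""
import sys

import numpy as np


def main() -> int:
    xpath, gpath, outdir, metric, seed = sys.argv[1:6]
    X = np.loadtxt(xpath, delimiter=",", dtype=np.float32)
    if X.ndim == 1:
        X = X.reshape(1, -1)
    grid = np.loadtxt(gpath, delimiter=",", dtype=np.float64)
    if grid.ndim == 1:
        grid = grid.reshape(1, -1)
    import umap  # deferred: heavy import

    for i, (nn, md) in enumerate(grid):
        try:
            emb = umap.UMAP(
                n_neighbors=int(nn),
                min_dist=float(md),
                n_components=2,
                metric=metric,
                random_state=int(seed),
            ).fit_transform(X)
            np.savetxt(f"{outdir}/emb_{i}.csv", emb, delimiter=",")
        except Exception as exc:  # failed cell: no output file
            print(f"cell {i} failed: {exc}", file=sys.stderr)
    return 0


if __name__ == "__main__":
    sys.exit(main())
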