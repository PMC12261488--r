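"""2-D UMAP layout of PCA scores; called as a subprocess by latent_map()."""
import sys

import numpy as np
import umap

inp, out, seed, n_neighbors, min_dist, spread, metric = sys.argv[1:8]
x = np.loadtxt(inp, delimiter=",", ndmin=2)
emb = umap.UMAP(
    n_neighbors=int(n_neighbors),
    min_dist=float(min_dist),
    spread=float(spread),
    metric=metric,
    n_components=2,
    random_state=int(seed),
).fit_transform(x)
np.savetxt(out, emb, delimiter=",")
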