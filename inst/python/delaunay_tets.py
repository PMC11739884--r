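"""Delaunay kernel for the seg2fem volume mesher.

Reads float64 points (n x 3, row-major) from argv[1], writes the int32
simplex array (m x 4, row-major, 0-based) to argv[2].
"""
import sys

import numpy as np
from scipy.spatial import Delaunay


def main():
    pts = np.fromfile(sys.argv[1], dtype=np.float64).reshape(-1, 3)
    tri = Delaunay(pts)
    tri.simplices.astype(np.int32).tofile(sys.argv[2])


if __name__ == "__main__":
    main()
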