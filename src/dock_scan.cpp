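#include <Rcpp.h>
using namespace Rcpp;

// Score a rotated ligand at every candidate translation of its centre
// of mass on the grid lattice. Translations coincide with grid nodes
// shifted into a window [lo, hi] (0-based, may extend beyond the grid:
// out-of-grid reads contribute zero, matching the convention that
// atoms beyond the box are outside the 5 A interaction shell).
//
// grids:   list of numeric 3-d arrays (one per atom type), x fastest
// dims:    grid dimensions (nx, ny, nz)
// atomType: 0-based grid index per ligand atom
// rel:     ligand atom coordinates relative to the ligand COM, already
//          rotated, in grid units (Angstrom / spacing)
// lo, hi:  inclusive 0-based node-index window for the COM translation
// trilinear: interpolate ligand atom positions (8 corners) instead of
//          nearest-node lookup
//
// Returns the score for every window node in x-fastest order.
// [[Rcpp::export]]
NumericVector dockScanCpp(List grids, IntegerVector dims,
                          IntegerVector atomType, NumericMatrix rel,
                          IntegerVector lo, IntegerVector hi,
                          bool trilinear) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int wx = hi[0] - lo[0] + 1;
  const int wy = hi[1] - lo[1] + 1;
  const int wz = hi[2] - lo[2] + 1;
  const int natom = rel.nrow();
  NumericVector out((R_xlen_t)wx * wy * wz);
  double *S = REAL(out);

  std::vector<double *> G(grids.size());
  for (int g = 0; g < grids.size(); ++g)
    G[g] = REAL((SEXP)grids[g]);

  for (int a = 0; a < natom; ++a) {
    double *grid = G[atomType[a]];
    // corner offsets and weights for this atom's fractional position
    int ncorner = trilinear ? 8 : 1;
    int offx[8], offy[8], offz[8];
    double wgt[8];
    if (trilinear) {
      double fx = rel(a, 0), fy = rel(a, 1), fz = rel(a, 2);
      int bx = (int)std::floor(fx), by = (int)std::floor(fy),
          bz = (int)std::floor(fz);
      double gx = fx - bx, gy = fy - by, gz = fz - bz;
      int c = 0;
      for (int cz = 0; cz <= 1; ++cz)
        for (int cy = 0; cy <= 1; ++cy)
          for (int cx = 0; cx <= 1; ++cx) {
            offx[c] = bx + cx; offy[c] = by + cy; offz[c] = bz + cz;
            wgt[c] = (cx ? gx : 1 - gx) * (cy ? gy : 1 - gy) *
                     (cz ? gz : 1 - gz);
            ++c;
          }
    } else {
      offx[0] = (int)std::lround(rel(a, 0));
      offy[0] = (int)std::lround(rel(a, 1));
      offz[0] = (int)std::lround(rel(a, 2));
      wgt[0] = 1.0;
    }
    for (int c = 0; c < ncorner; ++c) {
      if (wgt[c] <= 0) continue;
      const double w = wgt[c];
      // window node (i,j,k) reads grid node (i+ox, j+oy, k+oz)
      const int ox = lo[0] + offx[c];
      const int oy = lo[1] + offy[c];
      const int oz = lo[2] + offz[c];
      // valid window k-range so grid z index stays in [0, nz)
      int k0 = std::max(0, -oz), k1 = std::min(wz - 1, nz - 1 - oz);
      int j0 = std::max(0, -oy), j1 = std::min(wy - 1, ny - 1 - oy);
      int i0 = std::max(0, -ox), i1 = std::min(wx - 1, nx - 1 - ox);
      if (k0 > k1 || j0 > j1 || i0 > i1) continue;
      for (int k = k0; k <= k1; ++k) {
        const R_xlen_t gzoff = (R_xlen_t)(k + oz) * nx * ny;
        const R_xlen_t szoff = (R_xlen_t)k * wx * wy;
        for (int j = j0; j <= j1; ++j) {
          const double *gp = grid + gzoff + (R_xlen_t)(j + oy) * nx + ox;
          double *sp = S + szoff + (R_xlen_t)j * wx;
          for (int i = i0; i <= i1; ++i)
            sp[i] += w * gp[i];
        }
      }
    }
  }
  return out;
}
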