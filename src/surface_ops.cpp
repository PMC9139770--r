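// Surface extraction, connected components and surface-set distances.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>
using namespace Rcpp;

// Region voxels with at least one 6-connected neighbour outside the region.
// Neighbours are only taken along axes with extent > 1 (a singleton axis is
// a 2D slab, not a one-voxel-thick 3D object); voxels on the grid boundary
// along a non-singleton axis count as surface.
// [[Rcpp::export]]
IntegerVector surface_indices_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int stride[3] = {1, nx, nx * ny};
  const int dim[3] = {nx, ny, nz};
  std::vector<int> out;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int p = x + nx * (y + ny * z);
        if (!mask[p]) continue;
        int xc[3] = {x, y, z};
        bool boundary = false;
        for (int ax = 0; ax < 3 && !boundary; ++ax) {
          if (dim[ax] < 2) continue;
          if (xc[ax] == 0 || xc[ax] == dim[ax] - 1) { boundary = true; break; }
          if (!mask[p - stride[ax]] || !mask[p + stride[ax]]) boundary = true;
        }
        if (boundary) out.push_back(p + 1);
      }
  return wrap(out);
}

// Hausdorff and average symmetric surface distance between two point sets
// (rows = points, columns = physical coordinates in mm). Exhaustive
// min-distance scans in both directions.
// [[Rcpp::export]]
List set_distances_cpp(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow(), d = A.ncol();
  double hmax = 0.0, ssum = 0.0;
  for (int pass = 0; pass < 2; ++pass) {
    const NumericMatrix& P = pass == 0 ? A : B;
    const NumericMatrix& Q = pass == 0 ? B : A;
    const int np = P.nrow(), nq = Q.nrow();
    for (int i = 0; i < np; ++i) {
      double best = R_PosInf;
      for (int j = 0; j < nq; ++j) {
        double s = 0.0;
        for (int k = 0; k < d; ++k) {
          const double t = P(i, k) - Q(j, k);
          s += t * t;
        }
        if (s < best) best = s;
      }
      best = std::sqrt(best);
      ssum += best;
      if (best > hmax) hmax = best;
    }
  }
  return List::create(_["hausdorff"] = hmax,
                      _["assd"] = ssum / (double)(na + nb));
}

// Largest connected component of a mask (26- or 6-connectivity over
// non-singleton axes); returns the mask restricted to that component.
// [[Rcpp::export]]
LogicalVector largest_component_cpp(LogicalVector mask, IntegerVector dims,
                                    int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const int dim[3] = {nx, ny, nz};
  std::vector<int> comp(n, 0);
  int ncomp = 0, best_comp = 0, best_size = 0;
  std::queue<int> q;
  for (int start = 0; start < n; ++start) {
    if (!mask[start] || comp[start]) continue;
    ++ncomp;
    int size = 0;
    comp[start] = ncomp;
    q.push(start);
    while (!q.empty()) {
      const int p = q.front(); q.pop();
      ++size;
      const int x = p % nx, y = (p / nx) % ny, z = p / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
              continue;
            const int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= dim[0] || yy < 0 || yy >= dim[1] ||
                zz < 0 || zz >= dim[2]) continue;
            const int pq = xx + nx * (yy + ny * zz);
            if (mask[pq] && !comp[pq]) {
              comp[pq] = ncomp;
              q.push(pq);
            }
          }
    }
    if (size > best_size) { best_size = size; best_comp = ncomp; }
  }
  LogicalVector out(n);
  for (int v = 0; v < n; ++v) out[v] = comp[v] == best_comp && best_comp > 0;
  return out;
}
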