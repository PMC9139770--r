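// Conservative flux-form forward-Euler stepper for the anisotropic
// Fisher-KPP model dc/dt = div(D grad c) + rho c (1 - c) on a voxel grid.
//
// Fluxes are computed once per interior face shared by two in-domain voxels
// and applied antisymmetrically to both cells, so with rho = 0 the total
// mass is conserved to round-off by construction. Faces touching any voxel
// outside the brain domain carry zero flux (no-flux Neumann boundary).
// Tensor components are stored per voxel in the order
// (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz), units mm^2 per day here.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int comp_index(int i, int j) {
  // symmetric 3x3 component index into (xx, xy, xz, yy, yz, zz)
  if (i > j) std::swap(i, j);
  if (i == 0) return j;          // 0,1,2
  if (i == 1) return 2 + j;      // (1,1)->3, (1,2)->4
  return 5;                      // (2,2)
}

// [[Rcpp::export]]
List rd_simulate_cpp(NumericVector c0, NumericMatrix D6, IntegerVector inbrain,
                     IntegerVector dims, NumericVector spacing, double dt,
                     double rho_day, IntegerVector snapshot_steps,
                     bool clamp) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const int stride[3] = {1, nx, nx * ny};
  const int dim[3] = {nx, ny, nz};
  const double h[3] = {spacing[0], spacing[1], spacing[2]};

  std::vector<double> c(c0.begin(), c0.end());
  std::vector<double> delta(n, 0.0);

  const int nsnap = snapshot_steps.size();
  NumericMatrix snaps(n, nsnap);
  int next_snap = 0;
  int total_steps = nsnap > 0 ? snapshot_steps[nsnap - 1] : 0;
  double clipped_mass = 0.0;

  // gradient of c along axis j at voxel r, with out-of-domain neighbours
  // replaced by the value at r (zero-gradient extension)
  auto grad_at = [&](int r, int rx, int ry, int rz, int j) -> double {
    int rc[3] = {rx, ry, rz};
    double cp = c[r], cm = c[r];
    if (rc[j] + 1 < dim[j]) {
      int q = r + stride[j];
      if (inbrain[q]) cp = c[q];
    }
    if (rc[j] - 1 >= 0) {
      int q = r - stride[j];
      if (inbrain[q]) cm = c[q];
    }
    return (cp - cm) / (2.0 * h[j]);
  };

  auto record = [&](int step) {
    while (next_snap < nsnap && snapshot_steps[next_snap] == step) {
      for (int v = 0; v < n; ++v) snaps(v, next_snap) = c[v];
      ++next_snap;
    }
  };

  record(0);
  for (int step = 1; step <= total_steps; ++step) {
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int axis = 0; axis < 3; ++axis) {
      if (dim[axis] < 2) continue;
      const int ii = comp_index(axis, axis);
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            int xc[3] = {x, y, z};
            if (xc[axis] + 1 >= dim[axis]) continue;
            const int p = x + nx * (y + ny * z);
            const int q = p + stride[axis];
            if (!inbrain[p] || !inbrain[q]) continue;
            double F = 0.5 * (D6(p, ii) + D6(q, ii)) * (c[q] - c[p]) / h[axis];
            for (int j = 0; j < 3; ++j) {
              if (j == axis || dim[j] < 2) continue;
              const double Dij = 0.5 * (D6(p, comp_index(axis, j)) +
                                        D6(q, comp_index(axis, j)));
              if (Dij == 0.0) continue;
              int qc[3] = {x, y, z};
              qc[axis] += 1;
              const double gj = 0.5 * (grad_at(p, x, y, z, j) +
                                       grad_at(q, qc[0], qc[1], qc[2], j));
              F += Dij * gj;
            }
            delta[p] += F / h[axis];
            delta[q] -= F / h[axis];
          }
    }
    for (int v = 0; v < n; ++v) {
      if (!inbrain[v]) continue;
      double cv = c[v];
      cv += dt * (delta[v] + rho_day * cv * (1.0 - cv));
      if (clamp) {
        if (cv < 0.0) {
          clipped_mass -= cv;
          cv = 0.0;
        } else if (cv > 1.0) {
          clipped_mass += cv - 1.0;
          cv = 1.0;
        }
      }
      c[v] = cv;
    }
    if (step % 25 == 0 || (next_snap < nsnap && snapshot_steps[next_snap] == step)) {
      for (int v = 0; v < n; ++v)
        if (!std::isfinite(c[v]))
          stop("non-finite density at step %d (voxel %d); reduce dt", step, v + 1);
    }
    record(step);
  }

  return List::create(_["snapshots"] = snaps,
                      _["clipped_mass"] = clipped_mass);
}

// Maximum over voxels of sum_i Dii/h_i^2 + sum_{i != j} |Dij| / (h_i h_j);
// the explicit-Euler bound used is dt <= 1 / (2 * L_max). D6 in mm^2/day.
// [[Rcpp::export]]
double rd_stability_denominator_cpp(NumericMatrix D6, NumericVector spacing,
                                    IntegerVector dims) {
  const double h[3] = {spacing[0], spacing[1], spacing[2]};
  const int dim[3] = {dims[0], dims[1], dims[2]};
  double Lmax = 0.0;
  for (int v = 0; v < D6.nrow(); ++v) {
    double L = 0.0;
    for (int i = 0; i < 3; ++i) {
      if (dim[i] < 2) continue;
      L += D6(v, comp_index(i, i)) / (h[i] * h[i]);
      for (int j = 0; j < 3; ++j) {
        if (j == i || dim[j] < 2) continue;
        L += std::abs(D6(v, comp_index(i, j))) / (h[i] * h[j]);
      }
    }
    if (L > Lmax) Lmax = L;
  }
  return Lmax;
}
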