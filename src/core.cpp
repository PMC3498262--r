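// Numerical core: batch eigen-decomposition of voxelwise diffusion tensors and
// tensor-deflection streamline propagation on a regular grid.
//
// Tensor component order everywhere: xx, yy, zz, xy, xz, yz.
// Streamline propagation works in continuous 0-based voxel coordinates and
// assumes an axis-aligned voxel->world mapping (checked on the R side); step
// lengths are in mm and converted per-axis by the voxel size.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static inline arma::mat33 tensor_from6(const double* t) {
  arma::mat33 D;
  D(0, 0) = t[0]; D(1, 1) = t[1]; D(2, 2) = t[2];
  D(0, 1) = D(1, 0) = t[3];
  D(0, 2) = D(2, 0) = t[4];
  D(1, 2) = D(2, 1) = t[5];
  return D;
}

static inline double fa_from_eigs(const arma::vec3& ev) {
  // negative eigenvalues (noisy fits) clamped to zero, matching compute_fa()
  arma::vec3 l = ev;
  for (int i = 0; i < 3; ++i) if (l[i] < 0.0) l[i] = 0.0;
  double nrm2 = arma::dot(l, l);
  if (nrm2 <= 0.0) return 0.0;
  double m = (l[0] + l[1] + l[2]) / 3.0;
  double num = (l[0] - m) * (l[0] - m) + (l[1] - m) * (l[1] - m) +
               (l[2] - m) * (l[2] - m);
  return std::sqrt(1.5 * num / nrm2);
}

//' @noRd
// [[Rcpp::export(name = ".dti_eigen_batch")]]
List dti_eigen_batch(const arma::mat& tensors6) {
  if (tensors6.n_rows != 6) stop("tensors6 must be 6 x N");
  const arma::uword n = tensors6.n_cols;
  arma::mat evals(3, n), e1(3, n);
  arma::vec3 ev;
  arma::mat33 vecs;
  for (arma::uword i = 0; i < n; ++i) {
    arma::mat33 D = tensor_from6(tensors6.colptr(i));
    arma::vec ev_; arma::mat vecs_;
    arma::eig_sym(ev_, vecs_, D);          // ascending
    evals(0, i) = ev_[2]; evals(1, i) = ev_[1]; evals(2, i) = ev_[0];
    e1(0, i) = vecs_(0, 2); e1(1, i) = vecs_(1, 2); e1(2, i) = vecs_(2, 2);
  }
  return List::create(_["values"] = evals, _["e1"] = e1);
}

// Trilinear interpolation of the 6 tensor components at continuous voxel
// coordinate p (0-based). Coordinates outside the grid are invalid (caller
// checks); the 8-neighbour stencil is clamped at the faces.
struct TensorGrid {
  const double* data;  // nx*ny*nz*6, R column-major [i + nx*(j + ny*(k + nz*c))]
  int nx, ny, nz;
  void interp(const double* p, double* out6) const {
    double x = p[0], y = p[1], z = p[2];
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    double fx = x - x0, fy = y - y0, fz = z - z0;
    int x1 = x0 + 1, y1 = y0 + 1, z1 = z0 + 1;
    if (x0 < 0) { x0 = 0; x1 = 0; fx = 0; }
    if (y0 < 0) { y0 = 0; y1 = 0; fy = 0; }
    if (z0 < 0) { z0 = 0; z1 = 0; fz = 0; }
    if (x1 > nx - 1) { x1 = nx - 1; if (x0 > nx - 1) { x0 = nx - 1; fx = 0; } }
    if (y1 > ny - 1) { y1 = ny - 1; if (y0 > ny - 1) { y0 = ny - 1; fy = 0; } }
    if (z1 > nz - 1) { z1 = nz - 1; if (z0 > nz - 1) { z0 = nz - 1; fz = 0; } }
    const double w000 = (1 - fx) * (1 - fy) * (1 - fz);
    const double w100 = fx * (1 - fy) * (1 - fz);
    const double w010 = (1 - fx) * fy * (1 - fz);
    const double w110 = fx * fy * (1 - fz);
    const double w001 = (1 - fx) * (1 - fy) * fz;
    const double w101 = fx * (1 - fy) * fz;
    const double w011 = (1 - fx) * fy * fz;
    const double w111 = fx * fy * fz;
    const long nxy = (long)nx * ny, nvox = (long)nx * ny * nz;
    for (int c = 0; c < 6; ++c) {
      const double* d = data + (long)c * nvox;
      out6[c] =
        w000 * d[x0 + nx * y0 + nxy * z0] + w100 * d[x1 + nx * y0 + nxy * z0] +
        w010 * d[x0 + nx * y1 + nxy * z0] + w110 * d[x1 + nx * y1 + nxy * z0] +
        w001 * d[x0 + nx * y0 + nxy * z1] + w101 * d[x1 + nx * y0 + nxy * z1] +
        w011 * d[x0 + nx * y1 + nxy * z1] + w111 * d[x1 + nx * y1 + nxy * z1];
    }
  }
};

static inline bool eig_at(const TensorGrid& g, const double* p,
                          arma::vec3& ev_desc, arma::vec3& e1) {
  double t6[6];
  g.interp(p, t6);
  arma::mat33 D = tensor_from6(t6);
  arma::vec ev; arma::mat vecs;
  if (!arma::eig_sym(ev, vecs, D)) return false;
  ev_desc[0] = ev[2]; ev_desc[1] = ev[1]; ev_desc[2] = ev[0];
  e1[0] = vecs(0, 2); e1[1] = vecs(1, 2); e1[2] = vecs(2, 2);
  return true;
}

// One unidirectional march from `seed` with initial direction v0 (unit, world
// mm frame). Appends visited points (voxel coords) to `out`.
static void march(const TensorGrid& g, const arma::vec3& seed_vox,
                  const arma::vec3& v0, const arma::vec3& voxel_size,
                  double step_mm, double fa_thr, double cos_thr,
                  double weight_prev, int max_steps,
                  std::vector<double>& out) {
  arma::vec3 p = seed_vox, v = v0;
  for (int s = 0; s < max_steps; ++s) {
    arma::vec3 pn;
    for (int a = 0; a < 3; ++a) pn[a] = p[a] + step_mm * v[a] / voxel_size[a];
    if (pn[0] < 0 || pn[0] > g.nx - 1 || pn[1] < 0 || pn[1] > g.ny - 1 ||
        pn[2] < 0 || pn[2] > g.nz - 1)
      break;                                   // next position leaves the volume
    arma::vec3 ev, e1;
    if (!eig_at(g, pn.memptr(), ev, e1)) break;
    if (fa_from_eigs(ev) < fa_thr) break;      // local FA below threshold
    if (arma::dot(v, e1) < 0) e1 = -e1;        // eigenvector sign ambiguity
    arma::vec3 vn = weight_prev * v + (1.0 - weight_prev) * e1;
    double nrm = arma::norm(vn);
    if (nrm <= 0) break;
    vn /= nrm;
    if (arma::dot(v, vn) < cos_thr) break;     // turning angle exceeded
    out.push_back(pn[0]); out.push_back(pn[1]); out.push_back(pn[2]);
    p = pn; v = vn;
  }
}

//' @noRd
// [[Rcpp::export(name = ".track_streamlines_cpp")]]
List track_streamlines_cpp(const NumericVector& tensor_flat,
                           const IntegerVector& dims,
                           const NumericVector& voxel_size,
                           const NumericMatrix& seeds,
                           double fa_threshold, double angle_threshold_deg,
                           double step_mm, double weight_prev, int max_steps) {
  TensorGrid g;
  g.data = REAL(tensor_flat);
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  if ((long)tensor_flat.size() != (long)g.nx * g.ny * g.nz * 6)
    stop("tensor_flat has wrong length");
  arma::vec3 vs; vs[0] = voxel_size[0]; vs[1] = voxel_size[1]; vs[2] = voxel_size[2];
  const double cos_thr = std::cos(angle_threshold_deg * M_PI / 180.0);
  const int n_seeds = seeds.nrow();
  List res(n_seeds);
  for (int i = 0; i < n_seeds; ++i) {
    arma::vec3 seed;
    seed[0] = seeds(i, 0); seed[1] = seeds(i, 1); seed[2] = seeds(i, 2);
    arma::vec3 ev, e1;
    bool ok = seed[0] >= 0 && seed[0] <= g.nx - 1 && seed[1] >= 0 &&
              seed[1] <= g.ny - 1 && seed[2] >= 0 && seed[2] <= g.nz - 1 &&
              eig_at(g, seed.memptr(), ev, e1) &&
              fa_from_eigs(ev) >= fa_threshold;
    if (!ok) { res[i] = NumericMatrix(0, 3); continue; }
    std::vector<double> fwd, bwd;
    march(g, seed, e1, vs, step_mm, fa_threshold, cos_thr, weight_prev,
          max_steps, fwd);
    arma::vec3 e1n = -e1;
    march(g, seed, e1n, vs, step_mm, fa_threshold, cos_thr, weight_prev,
          max_steps, bwd);
    const int nb = (int)bwd.size() / 3, nf = (int)fwd.size() / 3;
    NumericMatrix pts(nb + 1 + nf, 3);
    for (int j = 0; j < nb; ++j) {           // backward half, reversed
      int src = nb - 1 - j;
      pts(j, 0) = bwd[3 * src]; pts(j, 1) = bwd[3 * src + 1];
      pts(j, 2) = bwd[3 * src + 2];
    }
    pts(nb, 0) = seed[0]; pts(nb, 1) = seed[1]; pts(nb, 2) = seed[2];
    for (int j = 0; j < nf; ++j) {
      pts(nb + 1 + j, 0) = fwd[3 * j]; pts(nb + 1 + j, 1) = fwd[3 * j + 1];
      pts(nb + 1 + j, 2) = fwd[3 * j + 2];
    }
    res[i] = pts;
  }
  return res;
}
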