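// Probabilistic streamline propagation through a per-voxel orientation
// mixture. Directions are sampled from a von Mises-Fisher distribution and
// folded to the previous step's hemisphere (axial symmetry); propagation is
// bidirectional from each seed point, as in standard probabilistic
// trackers. Uses R's RNG so results are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  int nx, ny, nz, kmax;
  const int *n_fib;
  const double *dirs;   // [3, kmax, nvox]
  const double *kappa;  // [kmax, nvox]
  const double *frac;   // [kmax, nvox]

  inline int vox(int x, int y, int z) const { return x + nx * (y + ny * z); }
};

inline void sample_vmf(const double *mu, double kappa, double *out) {
  double w;
  if (kappa < 1e-8) {
    w = 2.0 * unif_rand() - 1.0;
  } else {
    double u = unif_rand();
    // inverse-CDF of the vMF cosine: density prop. to exp(kappa * w)
    w = 1.0 + std::log(u + (1.0 - u) * std::exp(-2.0 * kappa)) / kappa;
    if (w > 1.0) w = 1.0;
    if (w < -1.0) w = -1.0;
  }
  // random tangent direction orthogonal to mu
  double r[3], v[3];
  double vn = 0.0;
  do {
    for (int i = 0; i < 3; ++i) r[i] = norm_rand();
    double dot = r[0] * mu[0] + r[1] * mu[1] + r[2] * mu[2];
    for (int i = 0; i < 3; ++i) v[i] = r[i] - dot * mu[i];
    vn = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  } while (vn < 1e-12);
  double st = std::sqrt(std::max(0.0, 1.0 - w * w));
  for (int i = 0; i < 3; ++i) out[i] = w * mu[i] + st * v[i] / vn;
}

// One directed pass. Returns true if the path entered a target voxel.
// If path != nullptr, appends visited positions.
bool track_pass(const Model &m, const int *target, double x, double y,
                double z, int init_sign, double step, int max_steps,
                double curv_thresh, double kappa_floor,
                std::vector<double> *path) {
  double prev[3] = {0, 0, 0};
  bool has_prev = false;
  for (int s = 0; s <= max_steps; ++s) {
    int ix = (int)std::floor(x), iy = (int)std::floor(y),
        iz = (int)std::floor(z);
    if (ix < 0 || iy < 0 || iz < 0 || ix >= m.nx || iy >= m.ny || iz >= m.nz)
      return false;
    if (path) {
      path->push_back(x); path->push_back(y); path->push_back(z);
    }
    int v = m.vox(ix, iy, iz);
    if (target && target[v]) return true;
    if (s == max_steps) return false;
    int k = m.n_fib[v];
    if (k == 0) return false;
    double kmaxv = 0.0, ftot = 0.0;
    for (int c = 0; c < k; ++c) {
      if (m.kappa[c + m.kmax * v] > kmaxv) kmaxv = m.kappa[c + m.kmax * v];
      ftot += m.frac[c + m.kmax * v];
    }
    if (kmaxv < kappa_floor || ftot <= 0.0) return false; // background stop
    // choose a mixture component by fraction
    double u = unif_rand() * ftot, acc = 0.0;
    int c = 0;
    for (; c < k - 1; ++c) {
      acc += m.frac[c + m.kmax * v];
      if (u <= acc) break;
    }
    const double *mu = m.dirs + 3 * (c + m.kmax * v);
    double d[3];
    sample_vmf(mu, m.kappa[c + m.kmax * v], d);
    if (has_prev) {
      double dot = d[0] * prev[0] + d[1] * prev[1] + d[2] * prev[2];
      if (dot < 0) { d[0] = -d[0]; d[1] = -d[1]; d[2] = -d[2]; dot = -dot; }
      if (dot < curv_thresh) return false; // curvature stop
    } else if (init_sign < 0) {
      d[0] = -d[0]; d[1] = -d[1]; d[2] = -d[2];
    }
    x += step * d[0]; y += step * d[1]; z += step * d[2];
    prev[0] = d[0]; prev[1] = d[1]; prev[2] = d[2];
    has_prev = true;
  }
  return false;
}

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_count_hits(NumericMatrix starts, IntegerVector dim,
                             IntegerVector n_fib, NumericVector dirs,
                             NumericVector kappa, NumericVector frac,
                             IntegerVector target, double step_size,
                             int max_steps, double curv_thresh,
                             double kappa_floor, bool bidirectional) {
  Model m{dim[0], dim[1], dim[2],
          (int)(kappa.size() / (dim[0] * dim[1] * dim[2])),
          n_fib.begin(), dirs.begin(), kappa.begin(), frac.begin()};
  RNGScope scope;
  int hits = 0;
  for (int i = 0; i < starts.nrow(); ++i) {
    bool hit = track_pass(m, target.begin(), starts(i, 0), starts(i, 1),
                          starts(i, 2), +1, step_size, max_steps,
                          curv_thresh, kappa_floor, nullptr);
    if (!hit && bidirectional)
      hit = track_pass(m, target.begin(), starts(i, 0), starts(i, 1),
                       starts(i, 2), -1, step_size, max_steps, curv_thresh,
                       kappa_floor, nullptr);
    if (hit) ++hits;
  }
  return IntegerVector::create(hits, starts.nrow());
}

// [[Rcpp::export]]
NumericMatrix cpp_track_path(NumericVector start, IntegerVector dim,
                             IntegerVector n_fib, NumericVector dirs,
                             NumericVector kappa, NumericVector frac,
                             double step_size, int max_steps,
                             double curv_thresh, double kappa_floor) {
  Model m{dim[0], dim[1], dim[2],
          (int)(kappa.size() / (dim[0] * dim[1] * dim[2])),
          n_fib.begin(), dirs.begin(), kappa.begin(), frac.begin()};
  RNGScope scope;
  std::vector<double> path;
  int init_sign = unif_rand() < 0.5 ? -1 : +1;
  track_pass(m, nullptr, start[0], start[1], start[2], init_sign, step_size,
             max_steps, curv_thresh, kappa_floor, &path);
  int n = path.size() / 3;
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = path[3 * i + j];
  return out;
}
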