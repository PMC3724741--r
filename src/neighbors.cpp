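#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// minimum-image component: wrap d into (-L/2, L/2]
static inline double min_image(double d, double L) {
  d -= L * std::round(d / L);
  // round() maps exactly -L/2 to -L/2; shift to +L/2 to keep half-open side
  if (d <= -0.5 * L) d += L;
  return d;
}

static inline double mi_dist2(const double* p, const double* q,
                              const double* box) {
  double s = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = min_image(q[k] - p[k], box[k]);
    s += d * d;
  }
  return s;
}

// All unordered bead pairs (i < j) with minimum-image distance <= cutoff.
// pos: n x 3 (nm), box: length-3 orthorhombic edges (nm).
// Uses a periodic cell list when every dimension holds >= 3 cells of edge
// >= cutoff, otherwise falls back to the O(n^2) scan (small boxes).
// [[Rcpp::export]]
List neighbor_pairs_cpp(NumericMatrix pos, NumericVector box, double cutoff) {
  const int n = pos.nrow();
  if (box.size() != 3) stop("box must have length 3");
  for (int k = 0; k < 3; ++k)
    if (box[k] <= 0) stop("box edges must be strictly positive");
  if (cutoff <= 0) stop("cutoff must be positive");
  const double c2 = cutoff * cutoff;

  std::vector<double> P(3 * (size_t)n);
  for (int i = 0; i < n; ++i) {
    P[3 * (size_t)i]     = pos(i, 0);
    P[3 * (size_t)i + 1] = pos(i, 1);
    P[3 * (size_t)i + 2] = pos(i, 2);
  }
  const double bx[3] = {box[0], box[1], box[2]};

  std::vector<int> vi, vj;
  std::vector<double> vd;

  int nc[3];
  bool cells_ok = true;
  for (int k = 0; k < 3; ++k) {
    nc[k] = (int)std::floor(bx[k] / cutoff);
    if (nc[k] < 3) cells_ok = false;
  }

  if (!cells_ok || n < 64) {
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        double d2 = mi_dist2(&P[3 * (size_t)i], &P[3 * (size_t)j], bx);
        if (d2 <= c2) {
          vi.push_back(i + 1); vj.push_back(j + 1);
          vd.push_back(std::sqrt(d2));
        }
      }
  } else {
    const int ncx = nc[0], ncy = nc[1], ncz = nc[2];
    const int ncells = ncx * ncy * ncz;
    std::vector<std::vector<int> > cell(ncells);
    std::vector<int> ci(n), cj_(n), ck(n);
    for (int i = 0; i < n; ++i) {
      double x = P[3 * (size_t)i], y = P[3 * (size_t)i + 1],
             z = P[3 * (size_t)i + 2];
      int a = (int)std::floor(x / bx[0] * ncx); a = ((a % ncx) + ncx) % ncx;
      int b = (int)std::floor(y / bx[1] * ncy); b = ((b % ncy) + ncy) % ncy;
      int c = (int)std::floor(z / bx[2] * ncz); c = ((c % ncz) + ncz) % ncz;
      ci[i] = a; cj_[i] = b; ck[i] = c;
      cell[(a * ncy + b) * ncz + c].push_back(i);
    }
    // half-shell of neighbor cell offsets (13) + self
    const int off[13][3] = {
      {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
      {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
    for (int a = 0; a < ncx; ++a)
      for (int b = 0; b < ncy; ++b)
        for (int c = 0; c < ncz; ++c) {
          const std::vector<int>& me = cell[(a * ncy + b) * ncz + c];
          if (me.empty()) continue;
          // within-cell pairs
          for (size_t u = 0; u + 1 < me.size(); ++u)
            for (size_t v = u + 1; v < me.size(); ++v) {
              int i = me[u], j = me[v];
              double d2 = mi_dist2(&P[3 * (size_t)i], &P[3 * (size_t)j], bx);
              if (d2 <= c2) {
                int lo = i < j ? i : j, hi = i < j ? j : i;
                vi.push_back(lo + 1); vj.push_back(hi + 1);
                vd.push_back(std::sqrt(d2));
              }
            }
          for (int o = 0; o < 13; ++o) {
            int a2 = ((a + off[o][0]) % ncx + ncx) % ncx;
            int b2 = ((b + off[o][1]) % ncy + ncy) % ncy;
            int c2i = ((c + off[o][2]) % ncz + ncz) % ncz;
            const std::vector<int>& other = cell[(a2 * ncy + b2) * ncz + c2i];
            for (size_t u = 0; u < me.size(); ++u)
              for (size_t v = 0; v < other.size(); ++v) {
                int i = me[u], j = other[v];
                double d2 = mi_dist2(&P[3 * (size_t)i], &P[3 * (size_t)j], bx);
                if (d2 <= c2) {
                  int lo = i < j ? i : j, hi = i < j ? j : i;
                  vi.push_back(lo + 1); vj.push_back(hi + 1);
                  vd.push_back(std::sqrt(d2));
                }
              }
          }
        }
  }

  return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj),
                      _["dist"] = wrap(vd));
}

// Shrake-Rupley SASA on coarse-grained beads.
// pos: n x 3 nm; radii: n bead radii nm; probe: probe radius nm;
// n_points: test points per sphere (deterministic Fibonacci spiral);
// compute: logical mask of beads whose area is requested;
// occluder: logical mask of beads that block solvent;
// periodic: apply minimum image in the given box.
// Returns per-bead accessible area (nm^2); 0 for beads not in `compute`.
// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix pos, NumericVector radii,
                       NumericVector box, double probe, int n_points,
                       LogicalVector compute, LogicalVector occluder,
                       bool periodic) {
  const int n = pos.nrow();
  if (radii.size() != n || compute.size() != n || occluder.size() != n)
    stop("length mismatch between positions, radii and masks");
  if (n_points < 64) stop("n_points must be >= 64");
  for (int i = 0; i < n; ++i)
    if (compute[i] && !(radii[i] > 0)) stop("bead radius must be > 0");

  // deterministic spiral lattice on the unit sphere
  std::vector<double> sx(n_points), sy(n_points), sz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * k;
    sx[k] = r * std::cos(phi); sy[k] = r * std::sin(phi); sz[k] = z;
  }

  const double bx[3] = {box[0], box[1], box[2]};
  std::vector<double> P(3 * (size_t)n);
  for (int i = 0; i < n; ++i) {
    P[3 * (size_t)i]     = pos(i, 0);
    P[3 * (size_t)i + 1] = pos(i, 1);
    P[3 * (size_t)i + 2] = pos(i, 2);
  }

  NumericVector out(n);
  std::vector<int> nb; nb.reserve(256);
  for (int i = 0; i < n; ++i) {
    if (!compute[i]) { out[i] = 0.0; continue; }
    const double Ri = radii[i] + probe;
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i || !occluder[j]) continue;
      double lim = Ri + radii[j] + probe;
      double d2;
      if (periodic) d2 = mi_dist2(&P[3 * (size_t)i], &P[3 * (size_t)j], bx);
      else {
        d2 = 0.0;
        for (int k = 0; k < 3; ++k) {
          double d = P[3 * (size_t)j + k] - P[3 * (size_t)i + k];
          d2 += d * d;
        }
      }
      if (d2 < lim * lim) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double px = P[3 * (size_t)i]     + Ri * sx[k];
      double py = P[3 * (size_t)i + 1] + Ri * sy[k];
      double pz = P[3 * (size_t)i + 2] + Ri * sz[k];
      bool free_pt = true;
      for (size_t u = 0; u < nb.size(); ++u) {
        int j = nb[u];
        double Rj = radii[j] + probe;
        double dx = px - P[3 * (size_t)j];
        double dy = py - P[3 * (size_t)j + 1];
        double dz = pz - P[3 * (size_t)j + 2];
        if (periodic) {
          dx = min_image(dx, bx[0]);
          dy = min_image(dy, bx[1]);
          dz = min_image(dz, bx[2]);
        }
        if (dx * dx + dy * dy + dz * dz < Rj * Rj) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    out[i] = 4.0 * M_PI * Ri * Ri * (double)acc / (double)n_points;
  }
  return out;
}
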