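// Interior billiard ray-trace over a triangulated molecular surface.
//
// Acceleration follows the classic uniform-grid scheme: each surface element
// is registered in the grid cube(s) containing its corners (1 to 3 cubes per
// triangle).  The ray walks cubes with a 3D DDA; because registration is by
// corners only, the walk tests the 27-cube neighbourhood of each visited
// cube, which is exhaustive whenever the cube spacing is at least the longest
// mesh edge (any point of a triangle then lies within one cube of a corner).
// Under that condition the grid walk returns exactly the brute-force nearest
// intersection; the R layer clamps the spacing accordingly.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
};
inline V3 operator-(const V3& a, const V3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline V3 operator+(const V3& a, const V3& b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline V3 operator*(double s, const V3& a) { return {s * a.x, s * a.y, s * a.z}; }
inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(const V3& a, const V3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }
inline V3 unit(const V3& a) {
  double n = norm(a);
  return {a.x / n, a.y / n, a.z / n};
}

// splitmix64: small, seedable, platform-stable
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed + 0x9e3779b97f4a7c15ULL) {}
  uint64_t next_u64() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double runif() { return (next_u64() >> 11) * (1.0 / 9007199254740992.0); }
};

struct Mesh {
  int nt;
  std::vector<V3> a, e1, e2, n;  // vertex0, edges, unit outward normal
  std::vector<double> mep0, mep1, mep2;
};

struct Grid {
  double ox, oy, oz, h;
  int nx, ny, nz;
  std::unordered_map<int64_t, std::vector<int>> cells;  // corner registration
  // per-cell union of the 27-neighbourhood's corner registrations, so the
  // traversal scans a single precomputed list per visited cube
  std::vector<std::vector<int>> fat;
  int64_t key(int i, int j, int k) const { return ((int64_t)k * ny + j) * nx + i; }
  bool in_range(int i, int j, int k) const {
    return i >= 0 && j >= 0 && k >= 0 && i < nx && j < ny && k < nz;
  }
  void cell_of(const V3& p, int& i, int& j, int& k) const {
    i = (int)std::floor((p.x - ox) / h);
    j = (int)std::floor((p.y - oy) / h);
    k = (int)std::floor((p.z - oz) / h);
  }
};

const double T_EPS = 1e-6;      // self-hit guard along the ray (Angstrom)
const double TIE_EPS = 1e-12;   // exact-tie window; lower element index wins

void build_mesh(const NumericMatrix& V, const IntegerMatrix& F, const NumericVector& mep, Mesh& m) {
  m.nt = F.nrow();
  m.a.resize(m.nt);
  m.e1.resize(m.nt);
  m.e2.resize(m.nt);
  m.n.resize(m.nt);
  m.mep0.resize(m.nt);
  m.mep1.resize(m.nt);
  m.mep2.resize(m.nt);
  bool has_mep = mep.size() == V.nrow();
  for (int t = 0; t < m.nt; ++t) {
    int i0 = F(t, 0) - 1, i1 = F(t, 1) - 1, i2 = F(t, 2) - 1;
    V3 p0{V(i0, 0), V(i0, 1), V(i0, 2)};
    V3 p1{V(i1, 0), V(i1, 1), V(i1, 2)};
    V3 p2{V(i2, 0), V(i2, 1), V(i2, 2)};
    m.a[t] = p0;
    m.e1[t] = p1 - p0;
    m.e2[t] = p2 - p0;
    V3 nn = cross(m.e1[t], m.e2[t]);
    double l = norm(nn);
    m.n[t] = (l > 0) ? (1.0 / l) * nn : V3{0, 0, 1};
    m.mep0[t] = has_mep ? mep[i0] : 0.0;
    m.mep1[t] = has_mep ? mep[i1] : 0.0;
    m.mep2[t] = has_mep ? mep[i2] : 0.0;
  }
}

void build_grid(const NumericMatrix& V, const IntegerMatrix& F, double h, Grid& g) {
  g.h = h;
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int v = 0; v < V.nrow(); ++v)
    for (int a = 0; a < 3; ++a) {
      lo[a] = std::min(lo[a], V(v, a));
      hi[a] = std::max(hi[a], V(v, a));
    }
  g.ox = lo[0] - h;
  g.oy = lo[1] - h;
  g.oz = lo[2] - h;
  g.nx = (int)std::ceil((hi[0] - g.ox) / h) + 2;
  g.ny = (int)std::ceil((hi[1] - g.oy) / h) + 2;
  g.nz = (int)std::ceil((hi[2] - g.oz) / h) + 2;
  for (int t = 0; t < F.nrow(); ++t) {
    int64_t seen[3];
    int nseen = 0;
    for (int s = 0; s < 3; ++s) {
      int v = F(t, s) - 1;
      V3 p{V(v, 0), V(v, 1), V(v, 2)};
      int i, j, k;
      g.cell_of(p, i, j, k);
      int64_t kk = g.key(i, j, k);
      bool dup = false;
      for (int q = 0; q < nseen; ++q)
        if (seen[q] == kk) dup = true;
      if (!dup) {
        seen[nseen++] = kk;
        g.cells[kk].push_back(t);
      }
    }
  }
  // precompute fat cells (27-neighbourhood unions)
  g.fat.assign((size_t)g.nx * g.ny * g.nz, {});
  for (auto& kv : g.cells) {
    int i = (int)(kv.first % g.nx);
    int64_t r = kv.first / g.nx;
    int j = (int)(r % g.ny);
    int k = (int)(r / g.ny);
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (!g.in_range(ii, jj, kk)) continue;
          auto& lst = g.fat[(size_t)g.key(ii, jj, kk)];
          lst.insert(lst.end(), kv.second.begin(), kv.second.end());
        }
  }
  for (auto& lst : g.fat) {
    std::sort(lst.begin(), lst.end());
    lst.erase(std::unique(lst.begin(), lst.end()), lst.end());
  }
}

// Moller-Trumbore; returns t > T_EPS or -1
inline double tri_intersect(const Mesh& m, int t, const V3& p, const V3& d, double& u, double& v) {
  V3 pvec = cross(d, m.e2[t]);
  double det = dot(m.e1[t], pvec);
  if (std::fabs(det) < 1e-12) return -1.0;
  double inv = 1.0 / det;
  V3 tvec = p - m.a[t];
  u = dot(tvec, pvec) * inv;
  if (u < -1e-9 || u > 1.0 + 1e-9) return -1.0;
  V3 qvec = cross(tvec, m.e1[t]);
  v = dot(d, qvec) * inv;
  if (v < -1e-9 || u + v > 1.0 + 1e-9) return -1.0;
  double tt = dot(m.e2[t], qvec) * inv;
  if (tt <= T_EPS) return -1.0;
  return tt;
}

// exhaustive nearest intersection (used when grid misses or for oracle mode)
int brute_nearest(const Mesh& m, const V3& p, const V3& d, int exclude, double& best_t, double& bu,
                  double& bv) {
  int best = -1;
  best_t = R_PosInf;
  for (int t = 0; t < m.nt; ++t) {
    if (t == exclude) continue;
    double u, v;
    double tt = tri_intersect(m, t, p, d, u, v);
    if (tt > 0 && (tt < best_t - TIE_EPS || (tt < best_t + TIE_EPS && (best < 0 || t < best)))) {
      best_t = tt;
      best = t;
      bu = u;
      bv = v;
    }
  }
  return best;
}

// grid-accelerated nearest intersection
int grid_nearest(const Mesh& m, const Grid& g, std::vector<int>& stamp, int ray_id, const V3& p,
                 const V3& d, int exclude, double& best_t, double& bu, double& bv) {
  int ci, cj, ck;
  g.cell_of(p, ci, cj, ck);
  double tmaxx, tmaxy, tmaxz, tdx, tdy, tdz;
  int sx = d.x > 0 ? 1 : -1, sy = d.y > 0 ? 1 : -1, sz = d.z > 0 ? 1 : -1;
  auto axis_init = [&](double pc, double o, int c, double dc, int s, double& tmax, double& tdel) {
    if (std::fabs(dc) < 1e-300) {
      tmax = R_PosInf;
      tdel = R_PosInf;
    } else {
      double boundary = o + (c + (s > 0 ? 1 : 0)) * g.h;
      tmax = (boundary - pc) / dc;
      tdel = g.h / std::fabs(dc);
    }
  };
  axis_init(p.x, g.ox, ci, d.x, sx, tmaxx, tdx);
  axis_init(p.y, g.oy, cj, d.y, sy, tmaxy, tdy);
  axis_init(p.z, g.oz, ck, d.z, sz, tmaxz, tdz);

  int best = -1;
  best_t = R_PosInf;
  int guard = 4 * (g.nx + g.ny + g.nz) + 16;
  for (int step = 0; step < guard; ++step) {
    // the fat list holds every element registered in the cube's
    // 27-neighbourhood, which is exhaustive for spacing >= longest edge
    if (g.in_range(ci, cj, ck)) {
      for (int t : g.fat[(size_t)g.key(ci, cj, ck)]) {
        if (t == exclude || stamp[t] == ray_id) continue;
        stamp[t] = ray_id;
        double u, v;
        double tt = tri_intersect(m, t, p, d, u, v);
        if (tt > 0 &&
            (tt < best_t - TIE_EPS || (tt < best_t + TIE_EPS && (best < 0 || t < best)))) {
          best_t = tt;
          best = t;
          bu = u;
          bv = v;
        }
      }
    }
    double t_exit = std::min(tmaxx, std::min(tmaxy, tmaxz));
    if (best >= 0 && best_t <= t_exit + TIE_EPS) return best;
    // advance DDA
    if (tmaxx <= tmaxy && tmaxx <= tmaxz) {
      ci += sx;
      tmaxx += tdx;
    } else if (tmaxy <= tmaxz) {
      cj += sy;
      tmaxy += tdy;
    } else {
      ck += sz;
      tmaxz += tdz;
    }
    if (ci < -1 || cj < -1 || ck < -1 || ci > g.nx || cj > g.ny || ck > g.nz) break;
  }
  return best;  // may be -1 (escaped) or a hit found beyond the walked cubes
}

V3 reflect_dir(const V3& d, const V3& n) { return d - (2.0 * dot(d, n)) * n; }

// uniform sample within a cone of half-angle alpha (radians) about axis
V3 cone_sample(const V3& axis, double alpha, Rng& rng) {
  if (alpha <= 0) return axis;
  double cosa = std::cos(alpha);
  double c = 1.0 - rng.runif() * (1.0 - cosa);  // uniform in [cos a, 1]
  double s = std::sqrt(std::max(0.0, 1.0 - c * c));
  double phi = 2.0 * M_PI * rng.runif();
  // orthonormal frame around axis
  V3 u = (std::fabs(axis.x) < 0.9) ? V3{1, 0, 0} : V3{0, 1, 0};
  V3 e1 = unit(cross(axis, u));
  V3 e2 = cross(axis, e1);
  return c * axis + (s * std::cos(phi)) * e1 + (s * std::sin(phi)) * e2;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_splitmix_runif")]]
NumericVector cpp_splitmix_runif(double seed, int n) {
  Rng rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.runif();
  return out;
}

// [[Rcpp::export(name = ".cpp_grid_assign")]]
List cpp_grid_assign(NumericMatrix V, IntegerMatrix F, double spacing) {
  Grid g;
  build_grid(V, F, spacing, g);
  // invert: per element, list of cube keys (as i,j,k triples)
  std::vector<std::vector<int64_t>> percell(F.nrow());
  for (auto& kv : g.cells)
    for (int t : kv.second) percell[t].push_back(kv.first);
  List out(F.nrow());
  for (int t = 0; t < F.nrow(); ++t) {
    IntegerMatrix cubes(percell[t].size(), 3);
    for (size_t q = 0; q < percell[t].size(); ++q) {
      int64_t kk = percell[t][q];
      int i = (int)(kk % g.nx);
      int64_t r = kk / g.nx;
      int j = (int)(r % g.ny);
      int k = (int)(r / g.ny);
      cubes(q, 0) = i;
      cubes(q, 1) = j;
      cubes(q, 2) = k;
    }
    out[t] = cubes;
  }
  return List::create(_["element_cubes"] = out,
                      _["origin"] = NumericVector::create(g.ox, g.oy, g.oz),
                      _["spacing"] = g.h,
                      _["dims"] = IntegerVector::create(g.nx, g.ny, g.nz));
}

// [[Rcpp::export(name = ".cpp_next_reflection")]]
List cpp_next_reflection(NumericMatrix V, IntegerMatrix F, NumericVector p0, NumericVector d0,
                         double spacing, int exclude, bool brute) {
  Mesh m;
  NumericVector no_mep(0);
  build_mesh(V, F, no_mep, m);
  V3 p{p0[0], p0[1], p0[2]};
  V3 d = unit(V3{d0[0], d0[1], d0[2]});
  double t, u, v;
  int hit;
  if (brute) {
    hit = brute_nearest(m, p, d, exclude - 1, t, u, v);
  } else {
    Grid g;
    build_grid(V, F, spacing, g);
    std::vector<int> stamp(m.nt, -1);
    hit = grid_nearest(m, g, stamp, 0, p, d, exclude - 1, t, u, v);
  }
  if (hit < 0)
    return List::create(_["element"] = NA_INTEGER);
  V3 q = p + t * d;
  return List::create(_["element"] = hit + 1, _["t"] = t,
                      _["position"] = NumericVector::create(q.x, q.y, q.z),
                      _["bary"] = NumericVector::create(1.0 - u - v, u, v));
}

// [[Rcpp::export(name = ".cpp_reflect")]]
NumericVector cpp_reflect(NumericVector d0, NumericVector n0, double cone_deg, double seed) {
  V3 d = unit(V3{d0[0], d0[1], d0[2]});
  V3 n = unit(V3{n0[0], n0[1], n0[2]});
  V3 r = reflect_dir(d, n);
  if (cone_deg > 0) {
    Rng rng((uint64_t)seed);
    r = cone_sample(r, cone_deg * M_PI / 180.0, rng);
  }
  return NumericVector::create(r.x, r.y, r.z);
}

// [[Rcpp::export(name = ".cpp_trace")]]
List cpp_trace(NumericMatrix V, IntegerMatrix F, NumericVector mepV, IntegerVector elem_frag,
               IntegerVector contact_elems, int n_segments, double cone_deg, double spacing,
               double seed, int max_consecutive_failures) {
  Mesh m;
  build_mesh(V, F, mepV, m);
  Grid g;
  build_grid(V, F, spacing, g);
  std::vector<int> stamp(m.nt, -1);
  Rng rng((uint64_t)seed);
  const double alpha = cone_deg * M_PI / 180.0;

  if (contact_elems.size() == 0) stop("no contact elements to start the ray-trace from");

  std::vector<double> rx, ry, rz, rmep;
  std::vector<int> relem, rrun;
  std::vector<double> slen;
  std::vector<int> sfrom, sto;  // fragment ids at segment ends
  int run = 0, nseg = 0, restarts = 0, consecutive_fail = 0, ray_id = 0;

  while (nseg < n_segments) {
    // start at a random contact element, antiparallel to the outward normal
    ++run;
    int e0 = contact_elems[(int)(rng.runif() * contact_elems.size())] - 1;
    V3 p = m.a[e0] + (1.0 / 3.0) * (m.e1[e0] + m.e2[e0]);  // element center
    V3 d = -1.0 * m.n[e0];
    int prev_elem = e0;
    int prev_frag = elem_frag[e0];
    rx.push_back(p.x);
    ry.push_back(p.y);
    rz.push_back(p.z);
    rmep.push_back((m.mep0[e0] + m.mep1[e0] + m.mep2[e0]) / 3.0);
    relem.push_back(e0 + 1);
    rrun.push_back(run);
    bool progressed = false;

    while (nseg < n_segments) {
      double t, u, v;
      ++ray_id;
      int hit = grid_nearest(m, g, stamp, ray_id, p, d, prev_elem, t, u, v);
      if (hit < 0) break;  // propagation failure: truncate and restart
      V3 q = p + t * d;
      double w0 = 1.0 - u - v;
      double mep = w0 * m.mep0[hit] + u * m.mep1[hit] + v * m.mep2[hit];
      int frag = elem_frag[hit];
      rx.push_back(q.x);
      ry.push_back(q.y);
      rz.push_back(q.z);
      rmep.push_back(mep);
      relem.push_back(hit + 1);
      rrun.push_back(run);
      slen.push_back(t);
      sfrom.push_back(prev_frag);
      sto.push_back(frag);
      ++nseg;
      progressed = true;
      // specular reflection with cone perturbation.  The uniform-cap draw is
      // used as a Metropolis proposal against the cosine-weighted (Liouville)
      // boundary measure: accept with probability min(1, cos'/cos), otherwise
      // keep the ideal reflection.  This de-biases the perturbation so the
      // segment lengths sample the interior chord-length distribution
      // (mean 4V/S) instead of drifting toward a uniform direction measure.
      V3 ideal = reflect_dir(d, m.n[hit]);
      V3 nd = ideal;
      if (alpha > 0) {
        V3 cand = cone_sample(ideal, alpha, rng);
        double c_new = -dot(cand, m.n[hit]);
        double c_cur = -dot(ideal, m.n[hit]);
        if (c_new > 1e-12 && c_cur > 0 &&
            rng.runif() < std::min(1.0, c_new / c_cur))
          nd = cand;
      }
      if (dot(nd, m.n[hit]) >= 0) break;  // grazing pathologies: restart
      p = q;
      d = unit(nd);
      prev_elem = hit;
      prev_frag = frag;
    }
    if (nseg >= n_segments) break;
    ++restarts;
    consecutive_fail = progressed ? 0 : consecutive_fail + 1;
    if (consecutive_fail > max_consecutive_failures)
      stop("ray-trace failed repeatedly from fresh starts; mesh quality is suspect");
  }

  int nr = (int)rx.size();
  NumericMatrix pos(nr, 3);
  for (int i = 0; i < nr; ++i) {
    pos(i, 0) = rx[i];
    pos(i, 1) = ry[i];
    pos(i, 2) = rz[i];
  }
  return List::create(
      _["position"] = pos, _["element"] = IntegerVector(relem.begin(), relem.end()),
      _["mep"] = NumericVector(rmep.begin(), rmep.end()),
      _["run"] = IntegerVector(rrun.begin(), rrun.end()),
      _["seg_length"] = NumericVector(slen.begin(), slen.end()),
      _["seg_from"] = IntegerVector(sfrom.begin(), sfrom.end()),
      _["seg_to"] = IntegerVector(sto.begin(), sto.end()), _["restarts"] = restarts);
}
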