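// Incremental (Bowyer-Watson) Delaunay tetrahedralization in 3-D.
//
// Points are rescaled to the unit box before triangulating so that the
// orientation/in-sphere predicates work at a uniform magnitude; the
// per-tetrahedron circumradii and volumes returned to R are rescaled back
// to the input units (metres).  Tolerance-based predicates with a small
// cavity-repair loop handle near-cospherical inputs (e.g. grid-like
// clouds); exact arithmetic is not used.

#include <Rcpp.h>
#include <array>
#include <vector>
#include <map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

inline double det3(double a, double b, double c,
                   double d, double e, double f,
                   double g, double h, double i) {
  return a * (e * i - f * h) - b * (d * i - f * g) + c * (d * h - e * g);
}

struct Triangulation {
  std::vector<std::array<double, 3>> P;  // scaled points, super vertices last
  std::vector<std::array<int, 4>> TV;    // tet vertices (positive orientation)
  std::vector<std::array<int, 4>> TA;    // neighbour opposite vertex i, -1 = none
  std::vector<char> alive;
  int last_tet = 0;
  double eps_orient = 1e-13;
  double eps_sphere = 1e-13;

  double orient(int a, int b, int c, int d) const {
    const std::array<double, 3> &A = P[a], &B = P[b], &C = P[c], &D = P[d];
    return det3(B[0] - A[0], B[1] - A[1], B[2] - A[2],
                C[0] - A[0], C[1] - A[1], C[2] - A[2],
                D[0] - A[0], D[1] - A[1], D[2] - A[2]);
  }

  // >0 iff e strictly inside the circumsphere of (positively oriented) tet t
  double insphere(int t, int e) const {
    double m[4][4];
    const std::array<double, 3> &E = P[e];
    for (int i = 0; i < 4; ++i) {
      const std::array<double, 3> &V = P[TV[t][i]];
      double dx = V[0] - E[0], dy = V[1] - E[1], dz = V[2] - E[2];
      m[i][0] = dx; m[i][1] = dy; m[i][2] = dz;
      m[i][3] = dx * dx + dy * dy + dz * dz;
    }
    double d = 0.0;
    for (int c = 0; c < 4; ++c) {
      double sub[3][3];
      for (int r = 1; r < 4; ++r) {
        int cc = 0;
        for (int c2 = 0; c2 < 4; ++c2)
          if (c2 != c) sub[r - 1][cc++] = m[r][c2];
      }
      double s = det3(sub[0][0], sub[0][1], sub[0][2],
                      sub[1][0], sub[1][1], sub[1][2],
                      sub[2][0], sub[2][1], sub[2][2]);
      d += ((c % 2) ? -1.0 : 1.0) * m[0][c] * s;
    }
    return -d;  // row layout gives inside < 0 for a positive tet; flip
  }

  // value of the orientation test replacing vertex slot i of tet t by p;
  // all four >= -eps means p is in (or on) tet t
  double side(int t, int i, int p) const {
    int v[4] = {TV[t][0], TV[t][1], TV[t][2], TV[t][3]};
    v[i] = p;
    return orient(v[0], v[1], v[2], v[3]);
  }

  int locate(int p) {
    int t = last_tet;
    if (!alive[(size_t)t]) {
      for (size_t i = 0; i < TV.size(); ++i)
        if (alive[i]) { t = (int)i; break; }
    }
    size_t max_steps = TV.size() + 64;
    for (size_t step = 0; step < max_steps; ++step) {
      double worst = -eps_orient;
      int worst_i = -1;
      for (int i = 0; i < 4; ++i) {
        double s = side(t, i, p);
        if (s < worst) { worst = s; worst_i = i; }
      }
      if (worst_i < 0) return t;
      int nb = TA[t][worst_i];
      if (nb < 0 || !alive[(size_t)nb]) break;  // fall through to scan
      t = nb;
    }
    // robust fallback: linear scan
    int best = -1;
    double best_min = -std::numeric_limits<double>::infinity();
    for (size_t i = 0; i < TV.size(); ++i) {
      if (!alive[i]) continue;
      double mn = std::numeric_limits<double>::infinity();
      for (int k = 0; k < 4; ++k) mn = std::min(mn, side((int)i, k, p));
      if (mn >= -eps_orient) return (int)i;
      if (mn > best_min) { best_min = mn; best = (int)i; }
    }
    return best;  // least-bad tet; cavity BFS still applies the in-sphere test
  }

  void insert(int p) {
    int t0 = locate(p);
    if (t0 < 0) stop("point location failed");

    // grow the cavity: tets whose circumsphere strictly contains p
    std::vector<int> cavity;
    std::vector<char> in_cavity(TV.size(), 0);
    std::vector<int> stack;
    cavity.push_back(t0); in_cavity[(size_t)t0] = 1; stack.push_back(t0);
    while (!stack.empty()) {
      int t = stack.back(); stack.pop_back();
      for (int i = 0; i < 4; ++i) {
        int nb = TA[t][i];
        if (nb < 0 || in_cavity[(size_t)nb] || !alive[(size_t)nb]) continue;
        if (insphere(nb, p) > eps_sphere) {
          in_cavity[(size_t)nb] = 1;
          cavity.push_back(nb);
          stack.push_back(nb);
        }
      }
    }

    // cavity repair: every boundary face must see p positively, otherwise
    // the outer neighbour is absorbed (handles cospherical ties)
    bool changed = true;
    int guard = 0;
    while (changed && ++guard < 1000) {
      changed = false;
      for (size_t ci = 0; ci < cavity.size() && !changed; ++ci) {
        int t = cavity[ci];
        for (int i = 0; i < 4 && !changed; ++i) {
          int nb = TA[t][i];
          if (nb >= 0 && in_cavity[(size_t)nb]) continue;
          if (side(t, i, p) <= eps_orient) {
            if (nb < 0) stop("degenerate insertion on hull of bounding tetrahedron");
            in_cavity[(size_t)nb] = 1;
            cavity.push_back(nb);
            changed = true;
          }
        }
      }
    }
    if (guard >= 1000) stop("cavity repair failed to converge");

    // boundary faces of the cavity -> new tets around p
    struct BFace { int verts[3]; int outer; };
    std::vector<BFace> bf;
    for (size_t ci = 0; ci < cavity.size(); ++ci) {
      int t = cavity[ci];
      for (int i = 0; i < 4; ++i) {
        int nb = TA[t][i];
        if (nb >= 0 && in_cavity[(size_t)nb]) continue;
        // face opposite vertex slot i, ordered so (f0,f1,f2,p) is positive
        static const int fo[4][3] = {{1, 2, 3}, {0, 3, 2}, {0, 1, 3}, {0, 2, 1}};
        BFace f;
        f.verts[0] = TV[t][fo[i][0]];
        f.verts[1] = TV[t][fo[i][1]];
        f.verts[2] = TV[t][fo[i][2]];
        f.outer = nb;
        if (orient(f.verts[0], f.verts[1], f.verts[2], p) < 0)
          std::swap(f.verts[1], f.verts[2]);
        bf.push_back(f);
      }
    }

    for (size_t ci = 0; ci < cavity.size(); ++ci) alive[(size_t)cavity[ci]] = 0;

    // create new tets and stitch adjacency
    std::map<std::pair<int, int>, std::pair<int, int>> half;  // edge -> (tet, slot)
    std::vector<int> created;
    for (size_t fi = 0; fi < bf.size(); ++fi) {
      std::array<int, 4> tv = {bf[fi].verts[0], bf[fi].verts[1], bf[fi].verts[2], p};
      std::array<int, 4> ta = {-1, -1, -1, bf[fi].outer};
      TV.push_back(tv); TA.push_back(ta); alive.push_back(1);
      in_cavity.push_back(0);
      int id = (int)TV.size() - 1;
      created.push_back(id);
      if (bf[fi].outer >= 0) {
        // find the slot of the outer tet whose opposite face matches
        int outer = bf[fi].outer;
        for (int k = 0; k < 4; ++k) {
          int nb = TA[(size_t)outer][k];
          if (nb >= 0 && (size_t)nb < in_cavity.size() && in_cavity[(size_t)nb] &&
              !alive[(size_t)nb]) {
            // candidate; confirm the shared face is this one
            static const int fo[4][3] = {{1, 2, 3}, {0, 3, 2}, {0, 1, 3}, {0, 2, 1}};
            int a = TV[(size_t)outer][fo[k][0]];
            int b = TV[(size_t)outer][fo[k][1]];
            int c = TV[(size_t)outer][fo[k][2]];
            int s1 = a + b + c, s2 = tv[0] + tv[1] + tv[2];
            long long p1 = (long long)a * b + (long long)b * c + (long long)a * c;
            long long p2 = (long long)tv[0] * tv[1] + (long long)tv[1] * tv[2] +
                           (long long)tv[0] * tv[2];
            if (s1 == s2 && p1 == p2) { TA[(size_t)outer][k] = id; break; }
          }
        }
      }
      // internal faces: slots 0,1,2 are faces containing p; key on the
      // opposite edge of the base triangle
      for (int s = 0; s < 3; ++s) {
        int e1 = tv[(s + 1) % 3], e2 = tv[(s + 2) % 3];
        std::pair<int, int> key(std::min(e1, e2), std::max(e1, e2));
        std::map<std::pair<int, int>, std::pair<int, int>>::iterator it = half.find(key);
        if (it == half.end()) {
          half[key] = std::make_pair(id, s);
        } else {
          TA[(size_t)id][s] = it->second.first;
          TA[(size_t)it->second.first][it->second.second] = id;
          half.erase(it);
        }
      }
    }
    if (!half.empty()) stop("cavity boundary is not a closed fan");
    last_tet = created.back();
  }
};

}  // namespace

// [[Rcpp::export(name = ".delaunay3d_cpp")]]
List delaunay3d_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");

  // rescale into the unit box
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      double v = pts(i, d);
      if (!R_finite(v)) stop("non-finite coordinate");
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  double extent = 0.0;
  for (int d = 0; d < 3; ++d) extent = std::max(extent, hi[d] - lo[d]);
  if (extent <= 0.0) stop("degenerate point set (zero extent)");
  double scale = 1.0 / extent;

  Triangulation T;
  T.P.resize((size_t)n + 4);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d)
      T.P[(size_t)i][d] = (pts(i, d) - lo[d]) * scale;

  // large bounding tetrahedron (scaled coords live in [0,1]^3)
  double R = 1e4;
  T.P[(size_t)n + 0] = {0.5, 0.5, 3.0 * R};
  T.P[(size_t)n + 1] = {0.5, 2.0 * R, -R};
  T.P[(size_t)n + 2] = {0.5 + 1.8 * R, -1.2 * R, -R};
  T.P[(size_t)n + 3] = {0.5 - 1.8 * R, -1.2 * R, -R};
  std::array<int, 4> tv = {n, n + 1, n + 2, n + 3};
  if (T.orient(tv[0], tv[1], tv[2], tv[3]) < 0) std::swap(tv[2], tv[3]);
  T.TV.push_back(tv);
  T.TA.push_back({-1, -1, -1, -1});
  T.alive.push_back(1);

  // deterministic pseudo-shuffled insertion order (fixed LCG)
  std::vector<int> order((size_t)n);
  for (int i = 0; i < n; ++i) order[(size_t)i] = i;
  uint64_t s = 88172645463325252ULL;
  for (int i = n - 1; i > 0; --i) {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    int j = (int)(s % (uint64_t)(i + 1));
    std::swap(order[(size_t)i], order[(size_t)j]);
  }
  for (int i = 0; i < n; ++i) T.insert(order[(size_t)i]);

  // harvest tets with only real vertices; compute circumradius and volume
  std::vector<std::array<int, 4>> keep;
  for (size_t t = 0; t < T.TV.size(); ++t) {
    if (!T.alive[t]) continue;
    bool real = true;
    for (int k = 0; k < 4; ++k)
      if (T.TV[t][k] >= n) { real = false; break; }
    if (real) keep.push_back(T.TV[t]);
  }
  int m = (int)keep.size();
  IntegerMatrix tets(m, 4);
  NumericVector circumradius(m), volume(m);
  for (int t = 0; t < m; ++t) {
    const std::array<double, 3> &A = T.P[(size_t)keep[(size_t)t][0]];
    const std::array<double, 3> &B = T.P[(size_t)keep[(size_t)t][1]];
    const std::array<double, 3> &C = T.P[(size_t)keep[(size_t)t][2]];
    const std::array<double, 3> &D = T.P[(size_t)keep[(size_t)t][3]];
    double ba[3], ca[3], da[3];
    for (int d = 0; d < 3; ++d) {
      ba[d] = B[d] - A[d]; ca[d] = C[d] - A[d]; da[d] = D[d] - A[d];
    }
    double det = det3(ba[0], ba[1], ba[2], ca[0], ca[1], ca[2],
                      da[0], da[1], da[2]);
    volume[t] = std::fabs(det) / 6.0 / (scale * scale * scale);
    double rhs[3] = {
      0.5 * (ba[0] * ba[0] + ba[1] * ba[1] + ba[2] * ba[2]),
      0.5 * (ca[0] * ca[0] + ca[1] * ca[1] + ca[2] * ca[2]),
      0.5 * (da[0] * da[0] + da[1] * da[1] + da[2] * da[2])};
    if (std::fabs(det) < 1e-300) {
      circumradius[t] = R_PosInf;
    } else {
      // Cramer solve of [ba; ca; da] x = rhs for circumcentre offset x
      double x0 = det3(rhs[0], ba[1], ba[2], rhs[1], ca[1], ca[2],
                       rhs[2], da[1], da[2]) / det;
      double x1 = det3(ba[0], rhs[0], ba[2], ca[0], rhs[1], ca[2],
                       da[0], rhs[2], da[2]) / det;
      double x2 = det3(ba[0], ba[1], rhs[0], ca[0], ca[1], rhs[1],
                       da[0], da[1], rhs[2]) / det;
      circumradius[t] = std::sqrt(x0 * x0 + x1 * x1 + x2 * x2) / scale;
    }
    for (int k = 0; k < 4; ++k) tets(t, k) = keep[(size_t)t][k] + 1;
  }
  return List::create(_["tets"] = tets,
                      _["circumradius"] = circumradius,
                      _["volume"] = volume);
}
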