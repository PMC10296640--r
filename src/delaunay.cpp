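// Incremental 3-D Delaunay tessellation (Bowyer-Watson) with ghost
// tetrahedra carrying a point-at-infinity, so no super-tetrahedron of
// finite far-away vertices is needed and hull handling stays exact-ish.
//
// Predicates are evaluated in long double. Callers are expected to pass
// points in general position (the R wrapper applies a deterministic
// perturbation); residual degeneracies surface as a non-zero status and
// the wrapper retries with a fresh perturbation.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>

using Rcpp::IntegerMatrix;
using Rcpp::List;
using Rcpp::NumericMatrix;

typedef long double ld;

static const int GHOST = -1;

struct Tet {
  int v[4];       // vertex ids; v[3] == GHOST for ghost tets
  bool alive;
  // cached circumsphere (finite tets only), double precision prefilter
  double cc[3];
  double r2;
  bool has_cc;
};

// det of rows (a-d, b-d, c-d); Shewchuk sign convention
static inline ld orient3d(const ld *a, const ld *b, const ld *c, const ld *d) {
  ld adx = a[0] - d[0], ady = a[1] - d[1], adz = a[2] - d[2];
  ld bdx = b[0] - d[0], bdy = b[1] - d[1], bdz = b[2] - d[2];
  ld cdx = c[0] - d[0], cdy = c[1] - d[1], cdz = c[2] - d[2];
  return adx * (bdy * cdz - bdz * cdy) - ady * (bdx * cdz - bdz * cdx) +
         adz * (bdx * cdy - bdy * cdx);
}

// > 0 iff e strictly inside circumsphere of positively oriented (a,b,c,d)
static inline ld insphere(const ld *a, const ld *b, const ld *c, const ld *d,
                          const ld *e) {
  ld aex = a[0] - e[0], aey = a[1] - e[1], aez = a[2] - e[2];
  ld bex = b[0] - e[0], bey = b[1] - e[1], bez = b[2] - e[2];
  ld cex = c[0] - e[0], cey = c[1] - e[1], cez = c[2] - e[2];
  ld dex = d[0] - e[0], dey = d[1] - e[1], dez = d[2] - e[2];

  ld ab = aex * bey - bex * aey;
  ld bc = bex * cey - cex * bey;
  ld cd = cex * dey - dex * cey;
  ld da = dex * aey - aex * dey;
  ld ac = aex * cey - cex * aey;
  ld bd = bex * dey - dex * bey;

  ld abc = aez * bc - bez * ac + cez * ab;
  ld bcd = bez * cd - cez * bd + dez * bc;
  ld cda = cez * da + dez * ac + aez * cd;
  ld dab = dez * ab + aez * bd + bez * da;

  ld alift = aex * aex + aey * aey + aez * aez;
  ld blift = bex * bex + bey * bey + bez * bez;
  ld clift = cex * cex + cey * cey + cez * cez;
  ld dlift = dex * dex + dey * dey + dez * dez;

  return dlift * abc - clift * dab + blift * cda - alift * bcd;
}

struct FaceKey {
  int a, b, c;  // sorted ascending (GHOST = -1 sorts first)
  bool operator==(const FaceKey &o) const {
    return a == o.a && b == o.b && c == o.c;
  }
};
struct FaceHash {
  size_t operator()(const FaceKey &f) const {
    uint64_t h = (uint64_t)(f.a + 2);
    h = h * 1000003u + (uint64_t)(f.b + 2);
    h = h * 1000003u + (uint64_t)(f.c + 2);
    return (size_t)h;
  }
};

static inline FaceKey make_face(int a, int b, int c) {
  int v[3] = {a, b, c};
  if (v[0] > v[1]) std::swap(v[0], v[1]);
  if (v[1] > v[2]) std::swap(v[1], v[2]);
  if (v[0] > v[1]) std::swap(v[0], v[1]);
  FaceKey f = {v[0], v[1], v[2]};
  return f;
}

class Mesh {
 public:
  std::vector<ld> P;  // 3n coordinates
  std::vector<Tet> tets;
  ld ref[3];  // interior reference point (centroid of seed tet)
  int status; // 0 ok, >0 degeneracy code

  const ld *pt(int i) const { return &P[3 * i]; }

  void add_finite(int a, int b, int c, int d) {
    if (orient3d(pt(a), pt(b), pt(c), pt(d)) < 0) std::swap(a, b);
    if (orient3d(pt(a), pt(b), pt(c), pt(d)) <= 0) { status = 2; return; }
    Tet t;
    t.v[0] = a; t.v[1] = b; t.v[2] = c; t.v[3] = d;
    t.alive = true;
    t.has_cc = circumsphere(t);
    tets.push_back(t);
  }

  // ghost over hull triangle (a,b,c); orient so that the interior
  // reference point lies strictly on the negative side
  void add_ghost(int a, int b, int c) {
    ld o = orient3d(pt(a), pt(b), pt(c), ref);
    if (o > 0) std::swap(a, b);
    else if (o == 0) { status = 3; return; }
    Tet t;
    t.v[0] = a; t.v[1] = b; t.v[2] = c; t.v[3] = GHOST;
    t.alive = true;
    t.has_cc = false;
    tets.push_back(t);
  }

  bool circumsphere(Tet &t) {
    // solve for circumcenter in double precision (prefilter cache only)
    const ld *a = pt(t.v[0]);
    double ax = (double)a[0], ay = (double)a[1], az = (double)a[2];
    double m[3][3], rhs[3];
    for (int k = 0; k < 3; ++k) {
      const ld *q = pt(t.v[k + 1]);
      m[k][0] = (double)q[0] - ax;
      m[k][1] = (double)q[1] - ay;
      m[k][2] = (double)q[2] - az;
      rhs[k] = 0.5 * (m[k][0] * m[k][0] + m[k][1] * m[k][1] + m[k][2] * m[k][2]);
    }
    double det = m[0][0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
                 m[0][1] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
                 m[0][2] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]);
    if (det == 0.0 || !std::isfinite(det)) return false;
    double ux = (rhs[0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
                 m[0][1] * (rhs[1] * m[2][2] - m[1][2] * rhs[2]) +
                 m[0][2] * (rhs[1] * m[2][1] - m[1][1] * rhs[2])) / det;
    double uy = (m[0][0] * (rhs[1] * m[2][2] - m[1][2] * rhs[2]) -
                 rhs[0] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
                 m[0][2] * (m[1][0] * rhs[2] - rhs[1] * m[2][0])) / det;
    double uz = (m[0][0] * (m[1][1] * rhs[2] - rhs[1] * m[2][1]) -
                 m[0][1] * (m[1][0] * rhs[2] - rhs[1] * m[2][0]) +
                 rhs[0] * (m[1][0] * m[2][1] - m[1][1] * m[2][0])) / det;
    t.cc[0] = ax + ux; t.cc[1] = ay + uy; t.cc[2] = az + uz;
    t.r2 = ux * ux + uy * uy + uz * uz;
    return true;
  }

  bool conflicts(const Tet &t, int p) {
    const ld *pp = pt(p);
    if (t.v[3] == GHOST)
      return orient3d(pt(t.v[0]), pt(t.v[1]), pt(t.v[2]), pp) > 0;
    if (t.has_cc) {
      double dx = (double)pp[0] - t.cc[0];
      double dy = (double)pp[1] - t.cc[1];
      double dz = (double)pp[2] - t.cc[2];
      double d2 = dx * dx + dy * dy + dz * dz;
      double margin = 1e-9 * (t.r2 + d2) + 1e-300;
      if (d2 > t.r2 + margin) return false;
      if (d2 < t.r2 - margin) return true;
    }
    return insphere(pt(t.v[0]), pt(t.v[1]), pt(t.v[2]), pt(t.v[3]), pp) > 0;
  }

  void insert(int p) {
    std::vector<int> bad;
    for (size_t i = 0; i < tets.size(); ++i)
      if (tets[i].alive && conflicts(tets[i], p)) bad.push_back((int)i);
    if (bad.empty()) { status = 4; return; }  // p coincides with a vertex or predicate failure

    std::unordered_map<FaceKey, int, FaceHash> count;
    count.reserve(bad.size() * 8);
    for (int bi : bad) {
      const Tet &t = tets[bi];
      const int f[4][3] = {{t.v[1], t.v[2], t.v[3]}, {t.v[0], t.v[2], t.v[3]},
                           {t.v[0], t.v[1], t.v[3]}, {t.v[0], t.v[1], t.v[2]}};
      for (int k = 0; k < 4; ++k)
        count[make_face(f[k][0], f[k][1], f[k][2])]++;
    }
    for (int bi : bad) tets[bi].alive = false;
    for (auto &kv : count) {
      if (kv.second != 1) {
        if (kv.second > 2) status = 5;
        continue;
      }
      const FaceKey &f = kv.first;
      if (f.a == GHOST) add_ghost(f.b, f.c, p);       // hull edge + infinity
      else add_finite(f.a, f.b, f.c, p);
      if (status != 0) return;
    }
  }
};

// [[Rcpp::export(name = ".delaunay3d_cpp")]]
List delaunay3d_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  Mesh M;
  M.status = 0;
  M.P.resize(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) M.P[3 * i + k] = (ld)pts(i, k);

  // seed: first 4 affinely independent points
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  for (int i = 1; i < n && i1 < 0; ++i) {
    ld dx = M.P[3 * i] - M.P[0], dy = M.P[3 * i + 1] - M.P[1],
       dz = M.P[3 * i + 2] - M.P[2];
    if (dx * dx + dy * dy + dz * dz > 0) i1 = i;
  }
  if (i1 >= 0) {
    for (int i = i1 + 1; i < n && i2 < 0; ++i) {
      const ld *a = M.pt(i0), *b = M.pt(i1), *c = M.pt(i);
      ld ux = b[0] - a[0], uy = b[1] - a[1], uz = b[2] - a[2];
      ld vx = c[0] - a[0], vy = c[1] - a[1], vz = c[2] - a[2];
      ld cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
      if (cx * cx + cy * cy + cz * cz > 0) i2 = i;
    }
  }
  if (i2 >= 0) {
    for (int i = i2 + 1; i < n && i3 < 0; ++i)
      if (orient3d(M.pt(i0), M.pt(i1), M.pt(i2), M.pt(i)) != 0) i3 = i;
  }
  if (i3 < 0) return List::create(Rcpp::Named("status") = 1);

  for (int k = 0; k < 3; ++k)
    M.ref[k] = (M.P[3 * i0 + k] + M.P[3 * i1 + k] + M.P[3 * i2 + k] +
                M.P[3 * i3 + k]) / 4.0L;
  M.add_finite(i0, i1, i2, i3);
  if (M.status == 0) {
    const Tet t0 = M.tets[0];
    M.add_ghost(t0.v[1], t0.v[2], t0.v[3]);
    if (M.status == 0) M.add_ghost(t0.v[0], t0.v[2], t0.v[3]);
    if (M.status == 0) M.add_ghost(t0.v[0], t0.v[1], t0.v[3]);
    if (M.status == 0) M.add_ghost(t0.v[0], t0.v[1], t0.v[2]);
  }

  for (int p = 0; p < n && M.status == 0; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    M.insert(p);
    // compact occasionally to keep scans linear in live tets
    if (M.tets.size() > 64 && M.tets.size() > 3 * (size_t)n * 8) {
      std::vector<Tet> keep;
      keep.reserve(M.tets.size() / 2);
      for (const Tet &t : M.tets)
        if (t.alive) keep.push_back(t);
      M.tets.swap(keep);
    }
  }

  if (M.status != 0) return List::create(Rcpp::Named("status") = M.status);

  int nt = 0;
  for (const Tet &t : M.tets)
    if (t.alive && t.v[3] != GHOST) ++nt;
  IntegerMatrix out(nt, 4);
  int r = 0;
  for (const Tet &t : M.tets) {
    if (!t.alive || t.v[3] == GHOST) continue;
    for (int k = 0; k < 4; ++k) out(r, k) = t.v[k] + 1;  // 1-based
    ++r;
  }
  return List::create(Rcpp::Named("status") = 0, Rcpp::Named("tets") = out);
}
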