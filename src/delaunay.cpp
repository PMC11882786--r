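// 3-D Delaunay tessellation by incremental Bowyer-Watson insertion.
//
// Points are rescaled to a unit box and wrapped in a large super-tetrahedron;
// each point is inserted by removing every tetrahedron whose circumsphere
// contains it and re-triangulating the cavity boundary. Circumspheres are
// cached per tetrahedron. Callers are expected to pre-jitter degenerate
// (cospherical/coplanar) inputs; a small relative tolerance guards the
// in-sphere test. Complexity is O(n * T) from the brute-force bad-tetrahedron
// scan, which is ample for protein-sized point sets.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <set>
#include <cmath>

using namespace Rcpp;

namespace {

struct Tet {
  int v[4];
  double cx, cy, cz, r2;  // circumsphere
  bool alive;
};

// Solve the 3x3 linear system for the circumcenter. Returns false when the
// four points are (numerically) coplanar.
bool circumsphere(const std::vector<double>& X, const std::vector<double>& Y,
                  const std::vector<double>& Z, const int v[4], Tet& t) {
  double ax = X[v[0]], ay = Y[v[0]], az = Z[v[0]];
  double A[3][3], b[3];
  for (int k = 0; k < 3; ++k) {
    double dx = X[v[k + 1]] - ax, dy = Y[v[k + 1]] - ay, dz = Z[v[k + 1]] - az;
    A[k][0] = dx; A[k][1] = dy; A[k][2] = dz;
    b[k] = 0.5 * (dx * dx + dy * dy + dz * dz);
  }
  double det =
      A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
      A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
      A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  if (std::fabs(det) < 1e-14) return false;
  double ux = (b[0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
               A[0][1] * (b[1] * A[2][2] - A[1][2] * b[2]) +
               A[0][2] * (b[1] * A[2][1] - A[1][1] * b[2])) / det;
  double uy = (A[0][0] * (b[1] * A[2][2] - A[1][2] * b[2]) -
               b[0] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
               A[0][2] * (A[1][0] * b[2] - b[1] * A[2][0])) / det;
  double uz = (A[0][0] * (A[1][1] * b[2] - b[1] * A[2][1]) -
               A[0][1] * (A[1][0] * b[2] - b[1] * A[2][0]) +
               b[0] * (A[1][0] * A[2][1] - A[1][1] * A[2][0])) / det;
  t.cx = ax + ux; t.cy = ay + uy; t.cz = az + uz;
  t.r2 = ux * ux + uy * uy + uz * uz;
  return true;
}

struct Face {
  int a, b, c;
  Face(int x, int y, int z) {
    int m[3] = {x, y, z};
    if (m[0] > m[1]) std::swap(m[0], m[1]);
    if (m[1] > m[2]) std::swap(m[1], m[2]);
    if (m[0] > m[1]) std::swap(m[0], m[1]);
    a = m[0]; b = m[1]; c = m[2];
  }
  bool operator<(const Face& o) const {
    if (a != o.a) return a < o.a;
    if (b != o.b) return b < o.b;
    return c < o.c;
  }
};

}  // namespace

// Returns a 2-column 1-based matrix of the unique Delaunay edges among the
// input points, or throws on degenerate input.
// [[Rcpp::export(name = ".delaunay_edges_cpp")]]
IntegerMatrix delaunay_edges_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("need at least 4 points for a 3-D tessellation");

  // rescale into [0,1]^3 to keep the super-tetrahedron well conditioned
  double mn[3], mx[3];
  for (int k = 0; k < 3; ++k) {
    mn[k] = R_PosInf; mx[k] = R_NegInf;
    for (int i = 0; i < n; ++i) {
      if (!R_finite(pts(i, k))) stop("non-finite coordinate");
      mn[k] = std::min(mn[k], pts(i, k));
      mx[k] = std::max(mx[k], pts(i, k));
    }
  }
  double span = 0.0;
  for (int k = 0; k < 3; ++k) span = std::max(span, mx[k] - mn[k]);
  if (span <= 0) stop("degenerate point set: zero spatial extent");

  std::vector<double> X(n + 4), Y(n + 4), Z(n + 4);
  for (int i = 0; i < n; ++i) {
    X[i] = (pts(i, 0) - mn[0]) / span;
    Y[i] = (pts(i, 1) - mn[1]) / span;
    Z[i] = (pts(i, 2) - mn[2]) / span;
  }
  // super-tetrahedron comfortably enclosing the unit box
  const double B = 60.0;
  X[n] = -B;        Y[n] = -B;        Z[n] = -B;
  X[n + 1] = 3 * B; Y[n + 1] = -B;    Z[n + 1] = -B;
  X[n + 2] = 0.5;   Y[n + 2] = 3 * B; Z[n + 2] = -B;
  X[n + 3] = 0.5;   Y[n + 3] = 0.5;   Z[n + 3] = 3 * B;

  std::vector<Tet> tets;
  {
    Tet t0;
    t0.v[0] = n; t0.v[1] = n + 1; t0.v[2] = n + 2; t0.v[3] = n + 3;
    t0.alive = true;
    if (!circumsphere(X, Y, Z, t0.v, t0)) stop("internal: bad super-tet");
    tets.push_back(t0);
  }

  const double eps = 1e-12;
  for (int p = 0; p < n; ++p) {
    std::map<Face, int> faceCount;
    bool any = false;
    for (size_t ti = 0; ti < tets.size(); ++ti) {
      Tet& t = tets[ti];
      if (!t.alive) continue;
      double dx = X[p] - t.cx, dy = Y[p] - t.cy, dz = Z[p] - t.cz;
      if (dx * dx + dy * dy + dz * dz < t.r2 * (1.0 + eps) + eps) {
        t.alive = false;
        any = true;
        static const int f[4][3] = {{0, 1, 2}, {0, 1, 3}, {0, 2, 3}, {1, 2, 3}};
        for (int k = 0; k < 4; ++k) {
          faceCount[Face(t.v[f[k][0]], t.v[f[k][1]], t.v[f[k][2]])]++;
        }
      }
    }
    if (!any) stop("degenerate input: point not located in any circumsphere");
    // boundary faces of the cavity appear exactly once
    for (std::map<Face, int>::const_iterator it = faceCount.begin();
         it != faceCount.end(); ++it) {
      if (it->second != 1) continue;
      Tet nt;
      nt.v[0] = it->first.a; nt.v[1] = it->first.b;
      nt.v[2] = it->first.c; nt.v[3] = p;
      nt.alive = true;
      if (!circumsphere(X, Y, Z, nt.v, nt)) {
        stop("degenerate input: coplanar points in tessellation (jitter needed)");
      }
      tets.push_back(nt);
    }
    // compact occasionally to bound memory
    if (tets.size() > 40000) {
      std::vector<Tet> keep;
      keep.reserve(tets.size());
      for (size_t ti = 0; ti < tets.size(); ++ti) {
        if (tets[ti].alive) keep.push_back(tets[ti]);
      }
      tets.swap(keep);
    }
  }

  std::set<std::pair<int, int> > edges;
  for (size_t ti = 0; ti < tets.size(); ++ti) {
    const Tet& t = tets[ti];
    if (!t.alive) continue;
    bool super = false;
    for (int k = 0; k < 4; ++k) {
      if (t.v[k] >= n) { super = true; break; }
    }
    if (super) continue;
    for (int a = 0; a < 4; ++a) {
      for (int b = a + 1; b < 4; ++b) {
        int u = t.v[a], v = t.v[b];
        if (u > v) std::swap(u, v);
        edges.insert(std::make_pair(u, v));
      }
    }
  }
  if (edges.empty()) stop("tessellation produced no interior tetrahedra");

  IntegerMatrix out(edges.size(), 2);
  int r = 0;
  for (std::set<std::pair<int, int> >::const_iterator it = edges.begin();
       it != edges.end(); ++it, ++r) {
    out(r, 0) = it->first + 1;
    out(r, 1) = it->second + 1;
  }
  return out;
}
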