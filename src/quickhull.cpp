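#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <queue>
#include <map>
#include <set>
#include <functional>
using namespace Rcpp;

// 3D convex hull (incremental quickhull-style) returning outward facet
// planes. Input point clouds here are scattered neurite samples (a few
// hundred points), so an O(n * F) insertion scan is adequate and keeps the
// code simple and robust.

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 vsub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double vdot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double vnorm(const Vec3 &a) { return std::sqrt(vdot(a, a)); }

struct Face {
  int a, b, c;     // vertex indices, wound consistently with outward normal
  Vec3 n;          // outward unit normal
  double off;      // n . v for any vertex v of the face
  bool alive;
};

// signed distance of p from face plane (positive = outside)
inline double fdist(const Face &f, const Vec3 &p) {
  return vdot(f.n, p) - f.off;
}

Face make_face(int a, int b, int c, const std::vector<Vec3> &P,
               const Vec3 &interior) {
  Face f;
  f.a = a; f.b = b; f.c = c;
  Vec3 n = vcross(vsub(P[b], P[a]), vsub(P[c], P[a]));
  double nn = vnorm(n);
  if (nn > 0) { n.x /= nn; n.y /= nn; n.z /= nn; }
  // orient outward, keep winding consistent with the normal
  if (vdot(n, vsub(P[a], interior)) < 0) {
    std::swap(f.b, f.c);
    n.x = -n.x; n.y = -n.y; n.z = -n.z;
  }
  f.n = n;
  f.off = vdot(n, P[f.a]);
  f.alive = true;
  return f;
}

} // namespace

// [[Rcpp::export(name = ".hull3d_cpp")]]
List hull3d_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");
  std::vector<Vec3> P(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    scale = std::max(scale, std::max(std::fabs(P[i].x),
                     std::max(std::fabs(P[i].y), std::fabs(P[i].z))));
  }
  const double eps = 1e-10 * std::max(1.0, scale);

  // initial simplex: two extreme points, then farthest from line, then
  // farthest from plane
  int i0 = 0, i1 = 0;
  for (int i = 1; i < n; ++i) {
    if (P[i].x < P[i0].x) i0 = i;
    if (P[i].x > P[i1].x) i1 = i;
  }
  if (i0 == i1) i1 = (i0 + 1) % n;
  double best = -1.0;
  int i2 = -1;
  Vec3 d01 = vsub(P[i1], P[i0]);
  for (int i = 0; i < n; ++i) {
    double dd = vnorm(vcross(d01, vsub(P[i], P[i0])));
    if (dd > best) { best = dd; i2 = i; }
  }
  if (best <= eps * std::max(1.0, vnorm(d01)))
    stop("degenerate hull: points are collinear");
  Vec3 nrm = vcross(d01, vsub(P[i2], P[i0]));
  double nn = vnorm(nrm);
  nrm.x /= nn; nrm.y /= nn; nrm.z /= nn;
  best = -1.0;
  int i3 = -1;
  for (int i = 0; i < n; ++i) {
    double dd = std::fabs(vdot(nrm, vsub(P[i], P[i0])));
    if (dd > best) { best = dd; i3 = i; }
  }
  if (best <= eps) stop("degenerate hull: points are coplanar");

  Vec3 interior = {
    (P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0,
    (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0,
    (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0};

  std::vector<Face> faces;
  faces.reserve(4 * n);
  faces.push_back(make_face(i0, i1, i2, P, interior));
  faces.push_back(make_face(i0, i1, i3, P, interior));
  faces.push_back(make_face(i0, i2, i3, P, interior));
  faces.push_back(make_face(i1, i2, i3, P, interior));

  std::vector<bool> used(n, false);
  used[i0] = used[i1] = used[i2] = used[i3] = true;

  for (int p = 0; p < n; ++p) {
    if (used[p]) continue;
    used[p] = true;
    // visible faces
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f)
      if (faces[f].alive && fdist(faces[f], P[p]) > eps)
        vis.push_back((int)f);
    if (vis.empty()) continue;  // interior point
    // horizon: directed edges of visible faces whose reverse is not visible
    std::set<std::pair<int, int>> edges;
    for (int f : vis) {
      const Face &F = faces[f];
      edges.insert({F.a, F.b});
      edges.insert({F.b, F.c});
      edges.insert({F.c, F.a});
    }
    std::vector<std::pair<int, int>> horizon;
    for (const auto &e : edges)
      if (!edges.count({e.second, e.first})) horizon.push_back(e);
    for (int f : vis) faces[f].alive = false;
    for (const auto &e : horizon)
      faces.push_back(make_face(e.first, e.second, p, P, interior));
  }

  // collect live faces
  std::vector<int> live;
  for (size_t f = 0; f < faces.size(); ++f)
    if (faces[f].alive) live.push_back((int)f);
  const int nf = (int)live.size();
  NumericMatrix A(nf, 3);
  NumericVector b(nf);
  IntegerMatrix tri(nf, 3);
  std::set<int> verts;
  for (int k = 0; k < nf; ++k) {
    const Face &F = faces[live[k]];
    A(k, 0) = F.n.x; A(k, 1) = F.n.y; A(k, 2) = F.n.z;
    b[k] = F.off;
    tri(k, 0) = F.a + 1; tri(k, 1) = F.b + 1; tri(k, 2) = F.c + 1;
    verts.insert(F.a); verts.insert(F.b); verts.insert(F.c);
  }
  IntegerVector vidx(verts.size());
  int k = 0;
  for (int v : verts) vidx[k++] = v + 1;
  return List::create(_["normals"] = A, _["offsets"] = b,
                      _["faces"] = tri, _["vertices"] = vidx,
                      _["interior"] = NumericVector::create(
                          interior.x, interior.y, interior.z));
}

// [[Rcpp::export(name = ".points_in_hull_cpp")]]
LogicalVector points_in_hull_cpp(NumericMatrix A, NumericVector b,
                                 NumericMatrix P, double tol) {
  const int nf = A.nrow(), np = P.nrow();
  LogicalVector out(np);
  for (int i = 0; i < np; ++i) {
    const double x = P(i, 0), y = P(i, 1), z = P(i, 2);
    bool inside = true;
    for (int f = 0; f < nf; ++f) {
      if (A(f, 0) * x + A(f, 1) * y + A(f, 2) * z - b[f] > tol) {
        inside = false;
        break;
      }
    }
    out[i] = inside;
  }
  return out;
}

// Candidate synaptic pairs: axis-aligned bounding-box prefilter (closed
// intervals, touching counts) followed by convex-hull inclusion of at least
// one dendritic point of the postsynaptic neuron in the axonal hull of the
// presynaptic neuron. Early exit on the first included point.
// [[Rcpp::export(name = ".candidate_pairs_cpp")]]
IntegerMatrix candidate_pairs_cpp(List axon_A, List axon_b,
                                  NumericMatrix axon_box, List dend_pts,
                                  NumericMatrix dend_box, double tol,
                                  bool prefilter) {
  const int n = axon_A.size();
  if (dend_pts.size() != n || axon_box.nrow() != n || dend_box.nrow() != n)
    stop("inconsistent morphology inputs");
  std::vector<int> pre, post;
  for (int i = 0; i < n; ++i) {
    NumericMatrix A = axon_A[i];
    NumericVector b = axon_b[i];
    const int nf = A.nrow();
    const double ax0 = axon_box(i, 0), ax1 = axon_box(i, 1);
    const double ay0 = axon_box(i, 2), ay1 = axon_box(i, 3);
    const double az0 = axon_box(i, 4), az1 = axon_box(i, 5);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (prefilter) {
        // overlap1D on each axis: max1 >= min2 & max2 >= min1
        if (!(ax1 >= dend_box(j, 0) && dend_box(j, 1) >= ax0)) continue;
        if (!(ay1 >= dend_box(j, 2) && dend_box(j, 3) >= ay0)) continue;
        if (!(az1 >= dend_box(j, 4) && dend_box(j, 5) >= az0)) continue;
      }
      NumericMatrix D = dend_pts[j];
      const int np = D.nrow();
      bool hit = false;
      for (int p = 0; p < np && !hit; ++p) {
        const double x = D(p, 0), y = D(p, 1), z = D(p, 2);
        // a point outside the (tolerance-expanded) axonal bounding box
        // cannot be inside the hull
        if (x < ax0 - tol || x > ax1 + tol || y < ay0 - tol ||
            y > ay1 + tol || z < az0 - tol || z > az1 + tol)
          continue;
        bool inside = true;
        for (int f = 0; f < nf; ++f) {
          if (A(f, 0) * x + A(f, 1) * y + A(f, 2) * z - b[f] > tol) {
            inside = false;
            break;
          }
        }
        if (inside) hit = true;
      }
      if (hit) {
        pre.push_back(i + 1);
        post.push_back(j + 1);
      }
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  IntegerMatrix out(pre.size(), 2);
  for (size_t k = 0; k < pre.size(); ++k) {
    out(k, 0) = pre[k];
    out(k, 1) = post[k];
  }
  colnames(out) = CharacterVector::create("pre", "post");
  return out;
}

// connected components of an undirected graph given as an edge list
// (1-based vertex indices); used by the surface side-splitting
// nearest-neighbour clustering
// [[Rcpp::export(name = ".graph_components_cpp")]]
IntegerVector graph_components_cpp(IntegerMatrix edges, int n) {
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  };
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = find(edges(e, 0) - 1), b = find(edges(e, 1) - 1);
    if (a != b) parent[a] = b;
  }
  std::map<int, int> relabel;
  IntegerVector lab(n);
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    auto it = relabel.find(r);
    if (it == relabel.end()) {
      int id = (int)relabel.size() + 1;
      relabel[r] = id;
      lab[i] = id;
    } else {
      lab[i] = it->second;
    }
  }
  return lab;
}

// 4-connected component labelling of a binary mask (row/col grid),
// equivalent to MATLAB bwconncomp for connectivity 4.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int>> q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      q.push({r, c});
      while (!q.empty()) {
        auto rc = q.front();
        q.pop();
        const int rr = rc.first, cc = rc.second;
        const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = next;
            q.push({r2, c2});
          }
        }
      }
    }
  }
  return lab;
}
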