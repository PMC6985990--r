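// Incremental 3D convex hull (quickhull-style conflict lists).
// Returns hull volume, facet area and the vertex indices actually used.
// Coordinates are expected in mm; tolerance scales with the bounding box.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 sub(const Vec3& a, const Vec3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct Face {
  int a, b, c;          // vertex indices, outward CCW
  Vec3 n;               // unit outward normal
  double off;           // plane offset: dot(n, p) = off on the face
  bool alive;
  std::vector<int> outside;
};

inline double face_dist(const Face& f, const Vec3& p) { return dot(f.n, p) - f.off; }

Face make_face(const std::vector<Vec3>& P, int a, int b, int c, const Vec3& interior) {
  Face f;
  f.a = a; f.b = b; f.c = c; f.alive = true;
  Vec3 n = cross(sub(P[b], P[a]), sub(P[c], P[a]));
  double ln = norm(n);
  if (ln > 0) { n.x /= ln; n.y /= ln; n.z /= ln; }
  f.n = n;
  f.off = dot(n, P[a]);
  if (face_dist(f, interior) > 0) {  // flip to point away from the interior
    std::swap(f.b, f.c);
    f.n.x = -f.n.x; f.n.y = -f.n.y; f.n.z = -f.n.z;
    f.off = -f.off;
  }
  return f;
}

}  // namespace

// [[Rcpp::export(name = ".hull3d_cpp")]]
List hull3d_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  std::vector<Vec3> P(n);
  for (int i = 0; i < n; ++i) P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};

  double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    const double c[3] = {P[i].x, P[i].y, P[i].z};
    for (int d = 0; d < 3; ++d) {
      if (c[d] < lo[d]) lo[d] = c[d];
      if (c[d] > hi[d]) hi[d] = c[d];
    }
  }
  double diag = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) + (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                          (hi[2] - lo[2]) * (hi[2] - lo[2]));
  double eps = 1e-9 + 1e-9 * diag;
  double tol = 1e-7 + 1e-7 * diag;  // visibility tolerance

  // Initial simplex: two extreme points, then max-distance-from-line, then from-plane.
  int i0 = 0, i1 = 0;
  double best = -1;
  for (int d = 0; d < 3; ++d) {
    int lo_i = 0, hi_i = 0;
    for (int i = 0; i < n; ++i) {
      const double c[3] = {P[i].x, P[i].y, P[i].z};
      const double cl[3] = {P[lo_i].x, P[lo_i].y, P[lo_i].z};
      const double ch[3] = {P[hi_i].x, P[hi_i].y, P[hi_i].z};
      if (c[d] < cl[d]) lo_i = i;
      if (c[d] > ch[d]) hi_i = i;
    }
    double sep = norm(sub(P[hi_i], P[lo_i]));
    if (sep > best) { best = sep; i0 = lo_i; i1 = hi_i; }
  }
  if (best <= eps) return List::create(_["status"] = "degenerate", _["rank"] = 0);

  Vec3 dir = sub(P[i1], P[i0]);
  double ld = norm(dir);
  int i2 = -1; best = tol;
  for (int i = 0; i < n; ++i) {
    double d = norm(cross(sub(P[i], P[i0]), dir)) / ld;
    if (d > best) { best = d; i2 = i; }
  }
  if (i2 < 0) return List::create(_["status"] = "degenerate", _["rank"] = 1);

  Vec3 nrm = cross(sub(P[i1], P[i0]), sub(P[i2], P[i0]));
  double ln = norm(nrm);
  int i3 = -1; best = tol;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(dot(nrm, sub(P[i], P[i0]))) / ln;
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) return List::create(_["status"] = "degenerate", _["rank"] = 2);

  Vec3 interior = {(P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0,
                   (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0,
                   (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0};

  std::vector<Face> faces;
  faces.push_back(make_face(P, i0, i1, i2, interior));
  faces.push_back(make_face(P, i0, i1, i3, interior));
  faces.push_back(make_face(P, i0, i2, i3, interior));
  faces.push_back(make_face(P, i1, i2, i3, interior));

  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (face_dist(faces[f], P[i]) > tol) { faces[f].outside.push_back(i); break; }
    }
  }

  // Main loop: expand any face that still sees points.
  for (;;) {
    int fi = -1;
    for (size_t f = 0; f < faces.size(); ++f)
      if (faces[f].alive && !faces[f].outside.empty()) { fi = (int)f; break; }
    if (fi < 0) break;

    // Furthest conflict point of that face.
    int pi = -1; double bd = -1;
    for (int idx : faces[fi].outside) {
      double d = face_dist(faces[fi], P[idx]);
      if (d > bd) { bd = d; pi = idx; }
    }
    const Vec3 p = P[pi];

    // Visible faces (global scan keeps the code simple; face counts stay small).
    std::vector<int> visible;
    for (size_t f = 0; f < faces.size(); ++f)
      if (faces[f].alive && face_dist(faces[f], p) > tol) visible.push_back((int)f);

    // Horizon: directed edges of visible faces whose reverse is not in a visible face.
    std::vector<std::pair<int, int> > edges;
    for (int f : visible) {
      int v[3] = {faces[f].a, faces[f].b, faces[f].c};
      for (int e = 0; e < 3; ++e) edges.push_back(std::make_pair(v[e], v[(e + 1) % 3]));
    }
    std::vector<std::pair<int, int> > horizon;
    for (size_t e = 0; e < edges.size(); ++e) {
      bool internal = false;
      for (size_t g = 0; g < edges.size(); ++g)
        if (edges[g].first == edges[e].second && edges[g].second == edges[e].first) {
          internal = true; break;
        }
      if (!internal) horizon.push_back(edges[e]);
    }

    std::vector<int> orphans;
    for (int f : visible) {
      faces[f].alive = false;
      orphans.insert(orphans.end(), faces[f].outside.begin(), faces[f].outside.end());
      faces[f].outside.clear();
    }

    std::vector<int> fresh;
    for (size_t e = 0; e < horizon.size(); ++e) {
      faces.push_back(make_face(P, horizon[e].first, horizon[e].second, pi, interior));
      fresh.push_back((int)faces.size() - 1);
    }
    for (int idx : orphans) {
      if (idx == pi) continue;
      for (int f : fresh) {
        if (face_dist(faces[f], P[idx]) > tol) { faces[f].outside.push_back(idx); break; }
      }
    }
  }

  double vol = 0, area = 0;
  std::vector<bool> used(n, false);
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    const Vec3 &a = P[faces[f].a], &b = P[faces[f].b], &c = P[faces[f].c];
    Vec3 cr = cross(sub(b, a), sub(c, a));
    area += 0.5 * norm(cr);
    // Signed volume of tetra (interior, a, b, c); outward orientation makes it positive.
    Vec3 ra = sub(a, interior), rb = sub(b, interior), rc = sub(c, interior);
    vol += dot(ra, cross(rb, rc)) / 6.0;
    used[faces[f].a] = used[faces[f].b] = used[faces[f].c] = true;
  }
  IntegerVector verts;
  for (int i = 0; i < n; ++i) if (used[i]) verts.push_back(i + 1);

  int nf = 0;
  for (size_t f = 0; f < faces.size(); ++f) if (faces[f].alive) ++nf;
  NumericMatrix planes(nf, 4);  // outward normal (x,y,z) and offset
  int r = 0;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    planes(r, 0) = faces[f].n.x; planes(r, 1) = faces[f].n.y;
    planes(r, 2) = faces[f].n.z; planes(r, 3) = faces[f].off;
    ++r;
  }

  return List::create(_["status"] = "ok", _["volume"] = vol, _["area"] = area,
                      _["vertices"] = verts, _["planes"] = planes);
}
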