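// Incremental Bowyer-Watson Delaunay triangulation of a 2-D point set.
// Used by build_mesh() to triangulate the disk phantom; callers pass points
// pre-scaled to O(1) coordinates (uniform scaling preserves the Delaunay
// property).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Tri {
  int v[3];
  bool alive;
};

inline double orient2d(const double *p, const double *q, const double *r) {
  return (q[0] - p[0]) * (r[1] - p[1]) - (q[1] - p[1]) * (r[0] - p[0]);
}

// > 0 iff d lies strictly inside the circumcircle of CCW triangle (a,b,c)
inline double incircle(const double *a, const double *b, const double *c,
                       const double *d) {
  const double adx = a[0] - d[0], ady = a[1] - d[1];
  const double bdx = b[0] - d[0], bdy = b[1] - d[1];
  const double cdx = c[0] - d[0], cdy = c[1] - d[1];
  const double ad = adx * adx + ady * ady;
  const double bd = bdx * bdx + bdy * bdy;
  const double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy) - ady * (bdx * cd - bd * cdx) +
         ad * (bdx * cdy - bdy * cdx);
}

inline int64_t edge_key(int a, int b) {
  if (a > b) std::swap(a, b);
  return (static_cast<int64_t>(a) << 32) | static_cast<uint32_t>(b);
}

} // namespace

// [[Rcpp::export(name = ".delaunay_cpp")]]
IntegerMatrix delaunay_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 3) stop("need at least 3 points");

  // coordinates, super-triangle vertices appended at indices n..n+2
  std::vector<double> xy(2 * (n + 3));
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    xy[2 * i] = pts(i, 0);
    xy[2 * i + 1] = pts(i, 1);
    xmin = std::min(xmin, pts(i, 0));
    xmax = std::max(xmax, pts(i, 0));
    ymin = std::min(ymin, pts(i, 1));
    ymax = std::max(ymax, pts(i, 1));
  }
  const double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
  const double span = std::max(xmax - xmin, ymax - ymin) + 1e-9;
  const double big = 50.0 * span;
  xy[2 * n] = cx - big;       xy[2 * n + 1] = cy - big;
  xy[2 * (n + 1)] = cx + big; xy[2 * (n + 1) + 1] = cy - big;
  xy[2 * (n + 2)] = cx;       xy[2 * (n + 2) + 1] = cy + big;

  std::vector<Tri> tris;
  tris.reserve(4 * n);
  tris.push_back({{n, n + 1, n + 2}, true});

  std::vector<int> cand;           // candidate bad triangles
  std::vector<char> in_cavity;
  std::vector<int> stack;

  for (int ip = 0; ip < n; ++ip) {
    const double *p = &xy[2 * ip];

    // compact the triangle list when mostly dead
    size_t alive_cnt = 0;
    for (const Tri &t : tris) alive_cnt += t.alive;
    if (tris.size() > 64 && alive_cnt * 3 < tris.size()) {
      std::vector<Tri> keep;
      keep.reserve(2 * alive_cnt);
      for (const Tri &t : tris)
        if (t.alive) keep.push_back(t);
      tris.swap(keep);
    }

    cand.clear();
    int containing = -1;
    for (size_t it = 0; it < tris.size(); ++it) {
      if (!tris[it].alive) continue;
      const double *a = &xy[2 * tris[it].v[0]];
      const double *b = &xy[2 * tris[it].v[1]];
      const double *c = &xy[2 * tris[it].v[2]];
      if (incircle(a, b, c, p) > 0.0) {
        if (containing < 0 && orient2d(a, b, p) >= -1e-12 &&
            orient2d(b, c, p) >= -1e-12 && orient2d(c, a, p) >= -1e-12)
          containing = static_cast<int>(cand.size());
        cand.push_back(static_cast<int>(it));
      }
    }
    if (cand.empty()) stop("point insertion failed (duplicate point?)");
    if (containing < 0) containing = 0; // roundoff fallback

    // keep only the candidates edge-connected to the containing triangle,
    // so the cavity stays a topological disk despite roundoff
    std::unordered_map<int64_t, std::pair<int, int>> emap;
    emap.reserve(cand.size() * 4);
    for (size_t k = 0; k < cand.size(); ++k) {
      const int *v = tris[cand[k]].v;
      for (int e = 0; e < 3; ++e) {
        int64_t key = edge_key(v[e], v[(e + 1) % 3]);
        auto it = emap.find(key);
        if (it == emap.end())
          emap[key] = {static_cast<int>(k), -1};
        else
          it->second.second = static_cast<int>(k);
      }
    }
    in_cavity.assign(cand.size(), 0);
    stack.clear();
    stack.push_back(containing);
    in_cavity[containing] = 1;
    while (!stack.empty()) {
      int k = stack.back();
      stack.pop_back();
      const int *v = tris[cand[k]].v;
      for (int e = 0; e < 3; ++e) {
        auto &pr = emap[edge_key(v[e], v[(e + 1) % 3])];
        int other = (pr.first == k) ? pr.second : pr.first;
        if (other >= 0 && !in_cavity[other]) {
          in_cavity[other] = 1;
          stack.push_back(other);
        }
      }
    }

    // boundary = directed edges of cavity triangles whose undirected edge is
    // not shared with another cavity triangle
    std::vector<std::pair<int, int>> boundary;
    for (size_t k = 0; k < cand.size(); ++k) {
      if (!in_cavity[k]) continue;
      const int *v = tris[cand[k]].v;
      for (int e = 0; e < 3; ++e) {
        int a = v[e], b = v[(e + 1) % 3];
        auto &pr = emap[edge_key(a, b)];
        int other = (pr.first == static_cast<int>(k)) ? pr.second : pr.first;
        bool shared = other >= 0 && in_cavity[other];
        if (!shared) boundary.push_back({a, b});
      }
    }

    // validate the fan; on failure retreat to the containing triangle alone
    bool ok = !boundary.empty();
    for (auto &e : boundary)
      if (orient2d(&xy[2 * e.first], &xy[2 * e.second], p) <= 0.0) {
        ok = false;
        break;
      }
    if (!ok) {
      for (size_t k = 0; k < cand.size(); ++k) in_cavity[k] = 0;
      in_cavity[containing] = 1;
      boundary.clear();
      const int *v = tris[cand[containing]].v;
      for (int e = 0; e < 3; ++e) boundary.push_back({v[e], v[(e + 1) % 3]});
    }

    for (size_t k = 0; k < cand.size(); ++k)
      if (in_cavity[k]) tris[cand[k]].alive = false;
    for (auto &e : boundary) tris.push_back({{e.first, e.second, ip}, true});
  }

  int m = 0;
  for (const Tri &t : tris)
    if (t.alive && t.v[0] < n && t.v[1] < n && t.v[2] < n) ++m;
  IntegerMatrix out(m, 3);
  int r = 0;
  for (const Tri &t : tris) {
    if (!(t.alive && t.v[0] < n && t.v[1] < n && t.v[2] < n)) continue;
    out(r, 0) = t.v[0] + 1;
    out(r, 1) = t.v[1] + 1;
    out(r, 2) = t.v[2] + 1;
    ++r;
  }
  return out;
}
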