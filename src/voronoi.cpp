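#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 2D Voronoi tessellation by per-cell half-plane clipping. Each cell starts
// as the bounding box and is clipped by the perpendicular bisector of every
// sufficiently close site (sites visited in order of increasing distance,
// stopping once half the site distance exceeds the cell's circumradius).
// Returns tile areas, tile adjacency (sites whose bisector contributes a
// surviving cell edge, i.e. Delaunay neighbours) and a flag for cells
// touching the bounding box (unbounded in the open-plane tessellation).

// [[Rcpp::export(rng = false)]]
List voronoi_cells_cpp(NumericMatrix pts, NumericVector bbox) {
  const int n = pts.nrow();
  const double xmin = bbox[0], xmax = bbox[1], ymin = bbox[2], ymax = bbox[3];

  NumericVector areas(n);
  LogicalVector boundary(n);
  List neighbors(n);

  // sites sorted once by x for a crude sweep-prune; per-cell we sort by
  // distance to the focal site
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  std::vector<double> vx, vy, nvx, nvy;
  std::vector<int> tag, ntag;  // tag of edge starting at vertex k (-1 = bbox)
  std::vector<std::pair<double, int> > byd(n);

  for (int i = 0; i < n; ++i) {
    const double px = pts(i, 0), py = pts(i, 1);
    vx.assign(4, 0.0); vy.assign(4, 0.0); tag.assign(4, -1);
    vx[0] = xmin; vy[0] = ymin; vx[1] = xmax; vy[1] = ymin;
    vx[2] = xmax; vy[2] = ymax; vx[3] = xmin; vy[3] = ymax;

    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = pts(j, 0) - px, dy = pts(j, 1) - py;
      const double d2 = dx * dx + dy * dy;
      if (d2 == 0.0) continue;  // coincident site: handled by the caller
      byd[m++] = std::make_pair(d2, j);
    }
    std::sort(byd.begin(), byd.begin() + m);

    double rad2 = 0.0;  // squared circumradius of current cell around site
    for (size_t k = 0; k < vx.size(); ++k) {
      const double q = (vx[k] - px) * (vx[k] - px) + (vy[k] - py) * (vy[k] - py);
      if (q > rad2) rad2 = q;
    }

    for (int jj = 0; jj < m; ++jj) {
      if (byd[jj].first > 4.0 * rad2) break;  // bisector cannot reach the cell
      const int j = byd[jj].second;
      const double ux = pts(j, 0) - px, uy = pts(j, 1) - py;
      const double mxx = 0.5 * (pts(j, 0) + px), myy = 0.5 * (pts(j, 1) + py);
      // keep side: dot(x - mid, u) <= 0
      const int nv = (int)vx.size();
      if (nv == 0) break;
      nvx.clear(); nvy.clear(); ntag.clear();
      std::vector<double> side(nv);
      for (int k = 0; k < nv; ++k)
        side[k] = (vx[k] - mxx) * ux + (vy[k] - myy) * uy;
      bool cut = false;
      for (int k = 0; k < nv; ++k) {
        const int k2 = (k + 1) % nv;
        const bool in1 = side[k] <= 0.0, in2 = side[k2] <= 0.0;
        if (in1) {
          nvx.push_back(vx[k]); nvy.push_back(vy[k]);
          ntag.push_back(in2 ? tag[k] : tag[k]);
        }
        if (in1 != in2) {
          const double t = side[k] / (side[k] - side[k2]);
          nvx.push_back(vx[k] + t * (vx[k2] - vx[k]));
          nvy.push_back(vy[k] + t * (vy[k2] - vy[k]));
          // leaving the half-plane: the new edge along the bisector starts
          // here; entering: the original edge continues
          ntag.push_back(in1 ? j : tag[k]);
          cut = true;
        }
      }
      if (cut) {
        vx = nvx; vy = nvy; tag = ntag;
        rad2 = 0.0;
        for (size_t k = 0; k < vx.size(); ++k) {
          const double q = (vx[k] - px) * (vx[k] - px) + (vy[k] - py) * (vy[k] - py);
          if (q > rad2) rad2 = q;
        }
      }
    }

    // shoelace area and surviving edge tags
    double a = 0.0;
    const int nv = (int)vx.size();
    bool onbox = false;
    std::vector<int> nbs;
    for (int k = 0; k < nv; ++k) {
      const int k2 = (k + 1) % nv;
      a += vx[k] * vy[k2] - vx[k2] * vy[k];
      if (tag[k] < 0) onbox = true;
      else nbs.push_back(tag[k] + 1);
    }
    std::sort(nbs.begin(), nbs.end());
    nbs.erase(std::unique(nbs.begin(), nbs.end()), nbs.end());
    areas[i] = 0.5 * std::fabs(a);
    boundary[i] = onbox;
    neighbors[i] = IntegerVector(nbs.begin(), nbs.end());
  }
  return List::create(_["area"] = areas, _["neighbors"] = neighbors,
                      _["boundary"] = boundary);
}

// Volume of the 3D convex hull by incremental construction (triangle soup
// with horizon re-facing). Coplanar inputs give volume 0.

namespace {
struct Face { int a, b, c; };
inline void cross3(const double* u, const double* v, double* out) {
  out[0] = u[1] * v[2] - u[2] * v[1];
  out[1] = u[2] * v[0] - u[0] * v[2];
  out[2] = u[0] * v[1] - u[1] * v[0];
}
}  // namespace

// [[Rcpp::export(rng = false)]]
double hull_volume_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) return 0.0;
  std::vector<double> P(3 * n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      P[3 * i + c] = pts(i, c);
      scale = std::max(scale, std::fabs(pts(i, c)));
    }
  const double eps = 1e-9 * std::max(scale, 1.0);

  // initial non-degenerate tetrahedron
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  for (int i = 1; i < n && i1 < 0; ++i) {
    double s = 0.0;
    for (int c = 0; c < 3; ++c) s += std::fabs(P[3 * i + c] - P[3 * i0 + c]);
    if (s > eps) i1 = i;
  }
  if (i1 < 0) return 0.0;
  double u[3], v[3], w[3], cr[3];
  for (int c = 0; c < 3; ++c) u[c] = P[3 * i1 + c] - P[3 * i0 + c];
  for (int i = 1; i < n && i2 < 0; ++i) {
    if (i == i1) continue;
    for (int c = 0; c < 3; ++c) v[c] = P[3 * i + c] - P[3 * i0 + c];
    cross3(u, v, cr);
    if (std::fabs(cr[0]) + std::fabs(cr[1]) + std::fabs(cr[2]) > eps * eps) i2 = i;
  }
  if (i2 < 0) return 0.0;
  for (int c = 0; c < 3; ++c) v[c] = P[3 * i2 + c] - P[3 * i0 + c];
  cross3(u, v, cr);
  double best = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int c = 0; c < 3; ++c) s += cr[c] * (P[3 * i + c] - P[3 * i0 + c]);
    if (std::fabs(s) > std::fabs(best)) { best = s; i3 = i; }
  }
  if (i3 < 0 || std::fabs(best) <= eps * eps * eps) return 0.0;

  double cen[3];
  for (int c = 0; c < 3; ++c)
    cen[c] = (P[3 * i0 + c] + P[3 * i1 + c] + P[3 * i2 + c] + P[3 * i3 + c]) / 4.0;

  std::vector<Face> faces;
  // orient each face so the interior centroid lies on the negative side
  int init[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
  for (int f = 0; f < 4; ++f) {
    Face fc; fc.a = init[f][0]; fc.b = init[f][1]; fc.c = init[f][2];
    for (int c = 0; c < 3; ++c) {
      u[c] = P[3 * fc.b + c] - P[3 * fc.a + c];
      v[c] = P[3 * fc.c + c] - P[3 * fc.a + c];
    }
    cross3(u, v, cr);
    double s = 0.0;
    for (int c = 0; c < 3; ++c) s += cr[c] * (cen[c] - P[3 * fc.a + c]);
    if (s > 0) std::swap(fc.b, fc.c);
    faces.push_back(fc);
  }

  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    std::vector<int> visible;
    for (size_t f = 0; f < faces.size(); ++f) {
      const Face& fc = faces[f];
      for (int c = 0; c < 3; ++c) {
        u[c] = P[3 * fc.b + c] - P[3 * fc.a + c];
        v[c] = P[3 * fc.c + c] - P[3 * fc.a + c];
        w[c] = P[3 * p + c] - P[3 * fc.a + c];
      }
      cross3(u, v, cr);
      if (cr[0] * w[0] + cr[1] * w[1] + cr[2] * w[2] > eps) visible.push_back((int)f);
    }
    if (visible.empty()) continue;
    // horizon: edges appearing exactly once among visible faces
    std::vector<std::pair<int, int> > edges;
    for (size_t kk = 0; kk < visible.size(); ++kk) {
      const Face& fc = faces[visible[kk]];
      int e[3][2] = {{fc.a, fc.b}, {fc.b, fc.c}, {fc.c, fc.a}};
      for (int q = 0; q < 3; ++q) {
        const std::pair<int, int> rev(e[q][1], e[q][0]);
        std::vector<std::pair<int, int> >::iterator it =
          std::find(edges.begin(), edges.end(), rev);
        if (it != edges.end()) edges.erase(it);
        else edges.push_back(std::make_pair(e[q][0], e[q][1]));
      }
    }
    std::vector<Face> kept;
    std::vector<bool> vis(faces.size(), false);
    for (size_t kk = 0; kk < visible.size(); ++kk) vis[visible[kk]] = true;
    for (size_t f = 0; f < faces.size(); ++f) if (!vis[f]) kept.push_back(faces[f]);
    for (size_t e = 0; e < edges.size(); ++e) {
      Face fc; fc.a = edges[e].first; fc.b = edges[e].second; fc.c = p;
      // keep outward orientation (interior centroid on the negative side)
      for (int c = 0; c < 3; ++c) {
        u[c] = P[3 * fc.b + c] - P[3 * fc.a + c];
        v[c] = P[3 * fc.c + c] - P[3 * fc.a + c];
      }
      cross3(u, v, cr);
      double s = 0.0;
      for (int c = 0; c < 3; ++c) s += cr[c] * (cen[c] - P[3 * fc.a + c]);
      if (s > 0) std::swap(fc.b, fc.c);
      kept.push_back(fc);
    }
    faces.swap(kept);
  }

  double vol = 0.0;
  for (size_t f = 0; f < faces.size(); ++f) {
    const Face& fc = faces[f];
    for (int c = 0; c < 3; ++c) {
      u[c] = P[3 * fc.a + c] - cen[c];
      v[c] = P[3 * fc.b + c] - cen[c];
      w[c] = P[3 * fc.c + c] - cen[c];
    }
    cross3(v, w, cr);
    vol += std::fabs(u[0] * cr[0] + u[1] * cr[1] + u[2] * cr[2]) / 6.0;
  }
  return vol;
}
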