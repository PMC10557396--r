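// Low-level geometry kernels: ray casting, closest point on a triangle mesh,
// convex hull of unit directions (spherical triangulation) and 2D Delaunay.
// Brute-force complexity is acceptable at the package's working scales
// (<= ~5k vertices / ~10k faces); no spatial index is built.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <limits>
#include <map>

using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void sub3(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// Moller-Trumbore; returns t >= tmin of the first (nearest) intersection or -1.
static double ray_tri(const double* orig, const double* dir,
                      const double* v0, const double* v1, const double* v2,
                      double tmin) {
  double e1[3], e2[3], p[3], q[3], s[3];
  sub3(v1, v0, e1);
  sub3(v2, v0, e2);
  cross3(dir, e2, p);
  double det = dot3(e1, p);
  if (std::fabs(det) < 1e-14) return -1.0;
  double inv = 1.0 / det;
  sub3(orig, v0, s);
  double u = dot3(s, p) * inv;
  if (u < -1e-9 || u > 1.0 + 1e-9) return -1.0;
  cross3(s, e1, q);
  double v = dot3(dir, q) * inv;
  if (v < -1e-9 || u + v > 1.0 + 1e-9) return -1.0;
  double t = dot3(e2, q) * inv;
  if (t < tmin) return -1.0;
  return t;
}

// [[Rcpp::export]]
NumericVector cf_ray_mesh_first_hit(NumericMatrix origins, NumericMatrix dirs,
                                    NumericMatrix V, IntegerMatrix F,
                                    double max_depth, double tmin) {
  int n = origins.nrow(), nf = F.nrow();
  NumericVector out(n, NA_REAL);
  std::vector<double> Vx(V.nrow()), Vy(V.nrow()), Vz(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) { Vx[i] = V(i,0); Vy[i] = V(i,1); Vz[i] = V(i,2); }
  for (int i = 0; i < n; ++i) {
    double o[3] = {origins(i,0), origins(i,1), origins(i,2)};
    double d[3] = {dirs(i,0), dirs(i,1), dirs(i,2)};
    double best = std::numeric_limits<double>::infinity();
    for (int f = 0; f < nf; ++f) {
      int a = F(f,0) - 1, b = F(f,1) - 1, c = F(f,2) - 1;
      double va[3] = {Vx[a], Vy[a], Vz[a]};
      double vb[3] = {Vx[b], Vy[b], Vz[b]};
      double vc[3] = {Vx[c], Vy[c], Vz[c]};
      double t = ray_tri(o, d, va, vb, vc, tmin);
      if (t >= 0 && t < best) best = t;
    }
    if (best <= max_depth) out[i] = best;
  }
  return out;
}

// closest point on triangle (Ericson, Real-Time Collision Detection)
static void closest_pt_tri(const double* p, const double* a, const double* b,
                           const double* c, double* out) {
  double ab[3], ac[3], ap[3];
  sub3(b, a, ab); sub3(c, a, ac); sub3(p, a, ap);
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0 && d2 <= 0) { out[0]=a[0]; out[1]=a[1]; out[2]=a[2]; return; }
  double bp[3]; sub3(p, b, bp);
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0 && d4 <= d3) { out[0]=b[0]; out[1]=b[1]; out[2]=b[2]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double t = d1 / (d1 - d3);
    for (int k=0;k<3;++k) out[k] = a[k] + t * ab[k];
    return;
  }
  double cp[3]; sub3(p, c, cp);
  double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0 && d5 <= d6) { out[0]=c[0]; out[1]=c[1]; out[2]=c[2]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double t = d2 / (d2 - d6);
    for (int k=0;k<3;++k) out[k] = a[k] + t * ac[k];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k=0;k<3;++k) out[k] = b[k] + t * (c[k] - b[k]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k=0;k<3;++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
}

// For each query point: nearest point on the mesh surface, its distance and
// the (1-based, lowest on ties) face index. Columns: x,y,z,dist,face.
// [[Rcpp::export]]
NumericMatrix cf_closest_points_mesh(NumericMatrix P, NumericMatrix V,
                                     IntegerMatrix F) {
  int n = P.nrow(), nf = F.nrow();
  NumericMatrix out(n, 5);
  // precompute triangle centroids + circumscribing radius for pruning
  std::vector<double> cx(nf), cy(nf), cz(nf), rad(nf);
  for (int f = 0; f < nf; ++f) {
    int a = F(f,0)-1, b = F(f,1)-1, c = F(f,2)-1;
    cx[f] = (V(a,0)+V(b,0)+V(c,0))/3.0;
    cy[f] = (V(a,1)+V(b,1)+V(c,1))/3.0;
    cz[f] = (V(a,2)+V(b,2)+V(c,2))/3.0;
    double r = 0;
    for (int k = 0; k < 3; ++k) {
      int vi = F(f,k)-1;
      double dx=V(vi,0)-cx[f], dy=V(vi,1)-cy[f], dz=V(vi,2)-cz[f];
      double d2 = dx*dx+dy*dy+dz*dz;
      if (d2 > r) r = d2;
    }
    rad[f] = std::sqrt(r);
  }
  for (int i = 0; i < n; ++i) {
    double p[3] = {P(i,0), P(i,1), P(i,2)};
    double best = std::numeric_limits<double>::infinity();
    int bestf = -1;
    double bestpt[3] = {0,0,0};
    for (int f = 0; f < nf; ++f) {
      double dx = p[0]-cx[f], dy = p[1]-cy[f], dz = p[2]-cz[f];
      double dc = std::sqrt(dx*dx+dy*dy+dz*dz) - rad[f];
      if (dc * dc >= best && dc > 0) continue;
      int a = F(f,0)-1, b = F(f,1)-1, c = F(f,2)-1;
      double va[3] = {V(a,0),V(a,1),V(a,2)};
      double vb[3] = {V(b,0),V(b,1),V(b,2)};
      double vc[3] = {V(c,0),V(c,1),V(c,2)};
      double q[3];
      closest_pt_tri(p, va, vb, vc, q);
      double d2 = (p[0]-q[0])*(p[0]-q[0]) + (p[1]-q[1])*(p[1]-q[1]) +
                  (p[2]-q[2])*(p[2]-q[2]);
      if (d2 < best - 1e-18 || (std::fabs(d2 - best) <= 1e-18 && f < bestf)) {
        best = d2; bestf = f;
        bestpt[0]=q[0]; bestpt[1]=q[1]; bestpt[2]=q[2];
      }
    }
    out(i,0)=bestpt[0]; out(i,1)=bestpt[1]; out(i,2)=bestpt[2];
    out(i,3)=std::sqrt(best); out(i,4)=bestf + 1;
  }
  return out;
}

// Convex hull triangulation of points assumed in near-general position on a
// sphere around their centroid (all points are hull vertices). Incremental
// algorithm; returns 1-based faces oriented outward.
// [[Rcpp::export]]
IntegerMatrix cf_convex_hull_faces(NumericMatrix P) {
  int n = P.nrow();
  if (n < 4) stop("convex hull needs >= 4 points");
  std::vector<std::array<double,3> > pts(n);
  double ctr[3] = {0,0,0};
  for (int i = 0; i < n; ++i) {
    pts[i] = { P(i,0), P(i,1), P(i,2) };
    for (int k=0;k<3;++k) ctr[k] += pts[i][k] / n;
  }
  double scale = 0;
  for (int i = 0; i < n; ++i) {
    double d[3]; sub3(pts[i].data(), ctr, d);
    scale = std::max(scale, std::sqrt(dot3(d, d)));
  }
  double eps = 1e-10 * scale * scale;
  // initial tetrahedron: first point, farthest from it, farthest from line,
  // farthest from plane
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  double bd = -1;
  for (int i = 1; i < n; ++i) {
    double d[3]; sub3(pts[i].data(), pts[i0].data(), d);
    double dd = dot3(d,d);
    if (dd > bd) { bd = dd; i1 = i; }
  }
  bd = -1;
  double e0[3]; sub3(pts[i1].data(), pts[i0].data(), e0);
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    double d[3], c[3];
    sub3(pts[i].data(), pts[i0].data(), d);
    cross3(e0, d, c);
    double dd = dot3(c,c);
    if (dd > bd) { bd = dd; i2 = i; }
  }
  if (i2 < 0 || bd < 1e-20) stop("degenerate point cloud (collinear)");
  double e1[3], nrm[3];
  sub3(pts[i2].data(), pts[i0].data(), e1);
  cross3(e0, e1, nrm);
  bd = -1;
  double bsigned = 0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2) continue;
    double d[3]; sub3(pts[i].data(), pts[i0].data(), d);
    double s = dot3(nrm, d);
    if (std::fabs(s) > bd) { bd = std::fabs(s); i3 = i; bsigned = s; }
  }
  if (i3 < 0 || bd < 1e-14 * scale * scale * scale)
    stop("degenerate point cloud (coplanar)");
  typedef std::array<int,3> Face;
  std::vector<Face> faces;
  if (bsigned > 0) faces = { {i0,i2,i1}, {i0,i1,i3}, {i1,i2,i3}, {i2,i0,i3} };
  else             faces = { {i0,i1,i2}, {i0,i3,i1}, {i1,i3,i2}, {i2,i3,i0} };
  std::vector<bool> used(n, false);
  used[i0]=used[i1]=used[i2]=used[i3]=true;
  for (int i = 0; i < n; ++i) {
    if (used[i]) continue;
    const double* p = pts[i].data();
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      const double* a = pts[faces[f][0]].data();
      double u[3], v[3], fn[3], d[3];
      sub3(pts[faces[f][1]].data(), a, u);
      sub3(pts[faces[f][2]].data(), a, v);
      cross3(u, v, fn);
      sub3(p, a, d);
      if (dot3(fn, d) > eps) vis.push_back((int)f);
    }
    if (vis.empty()) continue;  // interior point
    std::map<std::pair<int,int>, int> edgecnt;
    for (size_t k = 0; k < vis.size(); ++k) {
      const Face& fc = faces[vis[k]];
      for (int e = 0; e < 3; ++e) {
        int a = fc[e], b = fc[(e+1)%3];
        edgecnt[std::make_pair(a,b)]++;
      }
    }
    std::vector<std::pair<int,int> > horizon;
    for (std::map<std::pair<int,int>,int>::iterator it = edgecnt.begin();
         it != edgecnt.end(); ++it) {
      std::pair<int,int> rev(it->first.second, it->first.first);
      if (edgecnt.find(rev) == edgecnt.end()) horizon.push_back(it->first);
    }
    std::vector<bool> kill(faces.size(), false);
    for (size_t k = 0; k < vis.size(); ++k) kill[vis[k]] = true;
    std::vector<Face> next;
    next.reserve(faces.size() + horizon.size());
    for (size_t f = 0; f < faces.size(); ++f)
      if (!kill[f]) next.push_back(faces[f]);
    for (size_t h = 0; h < horizon.size(); ++h) {
      Face nf = { horizon[h].first, horizon[h].second, i };
      next.push_back(nf);
    }
    faces.swap(next);
  }
  IntegerMatrix out((int)faces.size(), 3);
  for (size_t f = 0; f < faces.size(); ++f)
    for (int k = 0; k < 3; ++k) out((int)f, k) = faces[f][k] + 1;
  return out;
}

// Greedy blue-noise thinning: visit candidate points in the given order and
// keep each one whose distance to every previously kept point is >= r.
// [[Rcpp::export]]
LogicalVector cf_poisson_thin(NumericMatrix P, double r) {
  int n = P.nrow();
  LogicalVector keep(n, false);
  if (r <= 0) { std::fill(keep.begin(), keep.end(), true); return keep; }
  double cell = r;
  std::map<std::array<long long,3>, std::vector<int> > grid;
  double r2 = r * r;
  for (int i = 0; i < n; ++i) {
    long long gx = (long long)std::floor(P(i,0) / cell);
    long long gy = (long long)std::floor(P(i,1) / cell);
    long long gz = (long long)std::floor(P(i,2) / cell);
    bool ok = true;
    for (long long dx = -1; dx <= 1 && ok; ++dx)
      for (long long dy = -1; dy <= 1 && ok; ++dy)
        for (long long dz = -1; dz <= 1 && ok; ++dz) {
          std::array<long long,3> key = {gx+dx, gy+dy, gz+dz};
          std::map<std::array<long long,3>, std::vector<int> >::iterator it =
            grid.find(key);
          if (it == grid.end()) continue;
          for (size_t k = 0; k < it->second.size(); ++k) {
            int j = it->second[k];
            double ddx = P(i,0)-P(j,0), ddy = P(i,1)-P(j,1),
                   ddz = P(i,2)-P(j,2);
            if (ddx*ddx + ddy*ddy + ddz*ddz < r2) { ok = false; break; }
          }
        }
    if (ok) {
      keep[i] = true;
      std::array<long long,3> key = {gx, gy, gz};
      grid[key].push_back(i);
    }
  }
  return keep;
}

// Bowyer-Watson Delaunay triangulation in 2D; returns 1-based ccw faces.
// [[Rcpp::export]]
IntegerMatrix cf_delaunay2d(NumericMatrix P) {
  int n = P.nrow();
  if (n < 3) stop("need >= 3 points");
  double minx = P(0,0), maxx = P(0,0), miny = P(0,1), maxy = P(0,1);
  for (int i = 1; i < n; ++i) {
    minx = std::min(minx, P(i,0)); maxx = std::max(maxx, P(i,0));
    miny = std::min(miny, P(i,1)); maxy = std::max(maxy, P(i,1));
  }
  double dmax = std::max(maxx - minx, maxy - miny);
  if (dmax <= 0) stop("degenerate point set");
  double midx = (minx + maxx) / 2, midy = (miny + maxy) / 2;
  std::vector<std::array<double,2> > pts(n + 3);
  for (int i = 0; i < n; ++i) pts[i] = { P(i,0), P(i,1) };
  pts[n]   = { midx - 20 * dmax, midy - dmax };
  pts[n+1] = { midx,             midy + 20 * dmax };
  pts[n+2] = { midx + 20 * dmax, midy - dmax };
  typedef std::array<int,3> Tri;
  std::vector<Tri> tris;
  tris.push_back({ n, n+1, n+2 });
  for (int i = 0; i < n; ++i) {
    double px = pts[i][0], py = pts[i][1];
    std::vector<int> bad;
    for (size_t t = 0; t < tris.size(); ++t) {
      double ax = pts[tris[t][0]][0] - px, ay = pts[tris[t][0]][1] - py;
      double bx = pts[tris[t][1]][0] - px, by = pts[tris[t][1]][1] - py;
      double cx2 = pts[tris[t][2]][0] - px, cy2 = pts[tris[t][2]][1] - py;
      double det = (ax*ax + ay*ay) * (bx*cy2 - cx2*by)
                 - (bx*bx + by*by) * (ax*cy2 - cx2*ay)
                 + (cx2*cx2 + cy2*cy2) * (ax*by - bx*ay);
      // orientation of triangle
      double ori = (pts[tris[t][1]][0]-pts[tris[t][0]][0]) *
                   (pts[tris[t][2]][1]-pts[tris[t][0]][1]) -
                   (pts[tris[t][2]][0]-pts[tris[t][0]][0]) *
                   (pts[tris[t][1]][1]-pts[tris[t][0]][1]);
      if ((ori > 0 && det > 0) || (ori < 0 && det < 0)) bad.push_back((int)t);
    }
    std::map<std::pair<int,int>, int> edgecnt;
    for (size_t k = 0; k < bad.size(); ++k) {
      const Tri& tt = tris[bad[k]];
      for (int e = 0; e < 3; ++e) {
        int a = tt[e], b = tt[(e+1)%3];
        std::pair<int,int> key(std::min(a,b), std::max(a,b));
        edgecnt[key]++;
      }
    }
    std::vector<bool> kill(tris.size(), false);
    for (size_t k = 0; k < bad.size(); ++k) kill[bad[k]] = true;
    std::vector<Tri> next;
    for (size_t t = 0; t < tris.size(); ++t)
      if (!kill[t]) next.push_back(tris[t]);
    for (std::map<std::pair<int,int>,int>::iterator it = edgecnt.begin();
         it != edgecnt.end(); ++it) {
      if (it->second != 1) continue;  // interior edge of the cavity
      int a = it->first.first, b = it->first.second;
      // orient ccw
      double ori = (pts[b][0]-pts[a][0]) * (pts[i][1]-pts[a][1]) -
                   (pts[i][0]-pts[a][0]) * (pts[b][1]-pts[a][1]);
      Tri nt = ori > 0 ? Tri{a, b, i} : Tri{b, a, i};
      next.push_back(nt);
    }
    tris.swap(next);
  }
  std::vector<Tri> keep;
  for (size_t t = 0; t < tris.size(); ++t)
    if (tris[t][0] < n && tris[t][1] < n && tris[t][2] < n)
      keep.push_back(tris[t]);
  IntegerMatrix out((int)keep.size(), 3);
  for (size_t t = 0; t < keep.size(); ++t)
    for (int k = 0; k < 3; ++k) out((int)t, k) = keep[t][k] + 1;
  return out;
}
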