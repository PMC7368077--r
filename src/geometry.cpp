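// Planar overlay engine on convex decompositions.
//
// A multipolygon is represented as a list of convex rings (n x 2 numeric
// matrices, CCW, interiors pairwise disjoint).  All boolean operations stay
// inside that closed family: intersection of two convex pieces is convex,
// difference of a convex piece and a convex piece is a fan of convex pieces,
// and arbitrary simple rings enter the family through ear-clipping
// triangulation.  Areas are therefore exact sums of shoelace areas, with no
// need for a general polygon-clipping library.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

struct Pt { double x, y; };
typedef std::vector<Pt> Poly;       // one convex ring, CCW, not closed
typedef std::vector<Poly> CG;       // convex decomposition

static const double AREA_DROP = 1e-9;  // m^2: degenerate-sliver floor

// ---------- basic primitives ----------

static inline double cross3(const Pt &a, const Pt &b, const Pt &c) {
  return (b.x - a.x) * (c.y - a.y) - (b.y - a.y) * (c.x - a.x);
}

static double ringArea(const Poly &p) {  // signed
  double s = 0.0;
  size_t n = p.size();
  for (size_t i = 0; i < n; ++i) {
    size_t j = (i + 1) % n;
    s += p[i].x * p[j].y - p[j].x * p[i].y;
  }
  return 0.5 * s;
}

struct BBox { double xmin, ymin, xmax, ymax; };

static BBox polyBBox(const Poly &p) {
  BBox b = {p[0].x, p[0].y, p[0].x, p[0].y};
  for (const Pt &q : p) {
    b.xmin = std::min(b.xmin, q.x); b.xmax = std::max(b.xmax, q.x);
    b.ymin = std::min(b.ymin, q.y); b.ymax = std::max(b.ymax, q.y);
  }
  return b;
}

static inline bool bboxOverlap(const BBox &a, const BBox &b) {
  return a.xmin <= b.xmax && b.xmin <= a.xmax &&
         a.ymin <= b.ymax && b.ymin <= a.ymax;
}

// drop consecutive (near-)duplicate vertices; they would otherwise create
// zero-length edges whose halfplane degenerates to the whole plane
static void dedupe(Poly &p) {
  if (p.size() < 2) return;
  Poly q;
  q.reserve(p.size());
  for (const Pt &v : p) {
    if (q.empty() || std::fabs(q.back().x - v.x) > 1e-9 ||
        std::fabs(q.back().y - v.y) > 1e-9)
      q.push_back(v);
  }
  while (q.size() > 1 && std::fabs(q.front().x - q.back().x) <= 1e-9 &&
         std::fabs(q.front().y - q.back().y) <= 1e-9)
    q.pop_back();
  p.swap(q);
}

// clip convex CCW polygon against halfplane a*x + b*y <= c
static Poly clipHalf(const Poly &p, double a, double b, double c) {
  Poly out;
  size_t n = p.size();
  if (n == 0) return out;
  out.reserve(n + 2);
  for (size_t i = 0; i < n; ++i) {
    const Pt &P = p[i];
    const Pt &Q = p[(i + 1) % n];
    double dP = a * P.x + b * P.y - c;
    double dQ = a * Q.x + b * Q.y - c;
    if (dP <= 0) {
      out.push_back(P);
      if (dQ > 0) {
        double t = dP / (dP - dQ);
        out.push_back({P.x + t * (Q.x - P.x), P.y + t * (Q.y - P.y)});
      }
    } else if (dQ <= 0) {
      double t = dP / (dP - dQ);
      out.push_back({P.x + t * (Q.x - P.x), P.y + t * (Q.y - P.y)});
    }
  }
  dedupe(out);
  return out;
}

// intersection of two convex CCW polygons (Sutherland-Hodgman)
static Poly clipConvex(const Poly &subject, const Poly &clip) {
  Poly out = subject;
  size_t n = clip.size();
  for (size_t i = 0; i < n && !out.empty(); ++i) {
    const Pt &P = clip[i];
    const Pt &Q = clip[(i + 1) % n];
    // CCW edge P->Q: inside is left: cross(Q-P, x-P) >= 0
    // halfplane:  (Q.y-P.y)*x - (Q.x-P.x)*y <= Q.y*P.x... derive:
    // cross = (Q.x-P.x)*(y-P.y) - (Q.y-P.y)*(x-P.x) >= 0
    // => (Q.y-P.y)*x - (Q.x-P.x)*y <= (Q.y-P.y)*P.x - (Q.x-P.x)*P.y
    double a = Q.y - P.y, b = -(Q.x - P.x);
    if (a * a + b * b < 1e-18) continue;  // degenerate edge
    double c = a * P.x + b * P.y;
    out = clipHalf(out, a, b, c);
  }
  return out;
}

// convex piece minus convex piece -> fan of convex pieces (outside each
// successive edge of the subtrahend, inside all previous ones)
static void convexMinusConvex(const Poly &a, const Poly &b, CG &out) {
  // disjoint or contained fast paths avoid needless fan fragmentation
  Poly inter = clipConvex(a, b);
  double ia = inter.size() >= 3 ? std::fabs(ringArea(inter)) : 0.0;
  if (ia <= AREA_DROP) { out.push_back(a); return; }
  double aa = std::fabs(ringArea(a));
  if (ia >= aa - AREA_DROP) return;  // a entirely inside b
  Poly rem = a;
  size_t n = b.size();
  for (size_t i = 0; i < n && !rem.empty(); ++i) {
    const Pt &P = b[i];
    const Pt &Q = b[(i + 1) % n];
    double ca = Q.y - P.y, cb = -(Q.x - P.x);
    if (ca * ca + cb * cb < 1e-18) continue;  // degenerate edge
    double cc = ca * P.x + cb * P.y;
    // part of rem strictly outside this edge (>= c side)
    Poly outside = clipHalf(rem, -ca, -cb, -cc);
    if (!outside.empty() && std::fabs(ringArea(outside)) > AREA_DROP)
      out.push_back(outside);
    rem = clipHalf(rem, ca, cb, cc);
  }
  // rem now lies inside b: discarded
}

static bool pointInConvex(const Poly &p, double x, double y, double tol) {
  size_t n = p.size();
  Pt q = {x, y};
  for (size_t i = 0; i < n; ++i) {
    if (cross3(p[i], p[(i + 1) % n], q) < -tol) return false;
  }
  return true;
}

// ---------- conversion R <-> C++ ----------

static Poly matToPoly(const NumericMatrix &m) {
  Poly p;
  int n = m.nrow();
  p.reserve(n);
  for (int i = 0; i < n; ++i) p.push_back({m(i, 0), m(i, 1)});
  // drop closing duplicate
  dedupe(p);
  return p;
}

static NumericMatrix polyToMat(const Poly &p) {
  NumericMatrix m(p.size(), 2);
  for (size_t i = 0; i < p.size(); ++i) { m(i, 0) = p[i].x; m(i, 1) = p[i].y; }
  return m;
}

static CG listToCG(const List &l) {
  CG g;
  g.reserve(l.size());
  for (int i = 0; i < l.size(); ++i) {
    Poly p = matToPoly(as<NumericMatrix>(l[i]));
    if (p.size() >= 3) {
      if (ringArea(p) < 0) std::reverse(p.begin(), p.end());
      g.push_back(p);
    }
  }
  return g;
}

static List cgToList(const CG &g) {
  List l(g.size());
  for (size_t i = 0; i < g.size(); ++i) l[i] = polyToMat(g[i]);
  return l;
}

static std::vector<BBox> cgBBoxes(const CG &g) {
  std::vector<BBox> b;
  b.reserve(g.size());
  for (const Poly &p : g) b.push_back(polyBBox(p));
  return b;
}

// ---------- exported primitives ----------

// [[Rcpp::export]]
double cpp_cg_area(List g) {
  CG a = listToCG(g);
  double s = 0.0;
  for (const Poly &p : a) s += ringArea(p);
  return s;
}

// [[Rcpp::export]]
List cpp_cg_intersection(List ga, List gb) {
  CG a = listToCG(ga), b = listToCG(gb);
  std::vector<BBox> ba = cgBBoxes(a), bb = cgBBoxes(b);
  CG out;
  for (size_t i = 0; i < a.size(); ++i)
    for (size_t j = 0; j < b.size(); ++j) {
      if (!bboxOverlap(ba[i], bb[j])) continue;
      Poly c = clipConvex(a[i], b[j]);
      if (c.size() >= 3 && std::fabs(ringArea(c)) > AREA_DROP) out.push_back(c);
    }
  return cgToList(out);
}

// [[Rcpp::export]]
double cpp_cg_intersection_area(List ga, List gb, double stop_at = -1.0) {
  CG a = listToCG(ga), b = listToCG(gb);
  std::vector<BBox> ba = cgBBoxes(a), bb = cgBBoxes(b);
  double s = 0.0;
  for (size_t i = 0; i < a.size(); ++i)
    for (size_t j = 0; j < b.size(); ++j) {
      if (!bboxOverlap(ba[i], bb[j])) continue;
      Poly c = clipConvex(a[i], b[j]);
      if (c.size() >= 3) s += std::fabs(ringArea(c));
      if (stop_at > 0 && s > stop_at) return s;
    }
  return s;
}

// [[Rcpp::export]]
List cpp_cg_difference(List ga, List gb) {
  CG a = listToCG(ga), b = listToCG(gb);
  std::vector<BBox> bb = cgBBoxes(b);
  CG out;
  for (size_t i = 0; i < a.size(); ++i) {
    CG work;
    work.push_back(a[i]);
    for (size_t j = 0; j < b.size(); ++j) {
      BBox wb = polyBBox(a[i]);
      if (!bboxOverlap(wb, bb[j])) continue;
      CG next;
      for (const Poly &w : work) {
        if (!bboxOverlap(polyBBox(w), bb[j])) { next.push_back(w); continue; }
        convexMinusConvex(w, b[j], next);
      }
      work.swap(next);
      if (work.empty()) break;
    }
    for (Poly &w : work)
      if (std::fabs(ringArea(w)) > AREA_DROP) out.push_back(w);
  }
  return cgToList(out);
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_cg(NumericMatrix pts, List g, double tol = 1e-9) {
  CG a = listToCG(g);
  std::vector<BBox> ba = cgBBoxes(a);
  int n = pts.nrow();
  LogicalVector out(n);
  if (a.empty()) return out;
  // uniform bucket index over piece bboxes
  BBox outer = ba[0];
  for (const BBox &b : ba) {
    outer.xmin = std::min(outer.xmin, b.xmin);
    outer.xmax = std::max(outer.xmax, b.xmax);
    outer.ymin = std::min(outer.ymin, b.ymin);
    outer.ymax = std::max(outer.ymax, b.ymax);
  }
  int nbx = std::min(256, std::max(1, (int)std::sqrt((double)a.size()) * 4));
  int nby = nbx;
  double wx = (outer.xmax - outer.xmin) / nbx + 1e-300;
  double wy = (outer.ymax - outer.ymin) / nby + 1e-300;
  std::vector<std::vector<int>> bucket((size_t)nbx * nby);
  for (size_t i = 0; i < a.size(); ++i) {
    int i0 = std::max(0, (int)((ba[i].xmin - outer.xmin) / wx));
    int i1 = std::min(nbx - 1, (int)((ba[i].xmax - outer.xmin) / wx));
    int j0 = std::max(0, (int)((ba[i].ymin - outer.ymin) / wy));
    int j1 = std::min(nby - 1, (int)((ba[i].ymax - outer.ymin) / wy));
    for (int bi = i0; bi <= i1; ++bi)
      for (int bj = j0; bj <= j1; ++bj)
        bucket[(size_t)bj * nbx + bi].push_back((int)i);
  }
  for (int k = 0; k < n; ++k) {
    double x = pts(k, 0), y = pts(k, 1);
    bool in = false;
    if (x >= outer.xmin - tol && x <= outer.xmax + tol &&
        y >= outer.ymin - tol && y <= outer.ymax + tol) {
      int bi = std::min(nbx - 1, std::max(0, (int)((x - outer.xmin) / wx)));
      int bj = std::min(nby - 1, std::max(0, (int)((y - outer.ymin) / wy)));
      for (int i : bucket[(size_t)bj * nbx + bi]) {
        const BBox &b = ba[i];
        if (x < b.xmin - tol || x > b.xmax + tol ||
            y < b.ymin - tol || y > b.ymax + tol) continue;
        double sc = std::max(b.xmax - b.xmin, b.ymax - b.ymin);
        if (pointInConvex(a[i], x, y, tol * std::max(1.0, sc))) { in = true; break; }
      }
    }
    out[k] = in;
  }
  return out;
}

// ---------- ear-clipping triangulation ----------

// [[Rcpp::export]]
List cpp_triangulate(NumericMatrix ring) {
  Poly p = matToPoly(ring);
  // drop consecutive duplicates
  Poly q;
  for (const Pt &v : p) {
    if (q.empty() || std::fabs(q.back().x - v.x) > 1e-12 ||
        std::fabs(q.back().y - v.y) > 1e-12)
      q.push_back(v);
  }
  if (q.size() < 3) return List(0);
  double A = ringArea(q);
  if (A < 0) { std::reverse(q.begin(), q.end()); A = -A; }
  double tol = A * 1e-12;

  std::vector<int> idx(q.size());
  for (size_t i = 0; i < q.size(); ++i) idx[i] = (int)i;
  CG tris;
  int guard = 0, guardMax = (int)q.size() * (int)q.size() * 4 + 64;
  while (idx.size() > 3 && guard++ < guardMax) {
    bool clipped = false;
    size_t m = idx.size();
    for (size_t i = 0; i < m; ++i) {
      const Pt &a = q[idx[(i + m - 1) % m]];
      const Pt &b = q[idx[i]];
      const Pt &c = q[idx[(i + 1) % m]];
      double cr = cross3(a, b, c);
      if (cr < tol) {
        if (cr > -tol) {  // collinear: remove the vertex, no triangle
          idx.erase(idx.begin() + i);
          clipped = true;
          break;
        }
        continue;  // reflex
      }
      // ear test: no other vertex inside or on the triangle a,b,c —
      // inclusive, so a diagonal passing exactly through a reflex vertex
      // (e.g. the notch of an L) blocks the ear
      bool ok = true;
      for (size_t k = 0; k < m && ok; ++k) {
        if (k == i || k == (i + m - 1) % m || k == (i + 1) % m) continue;
        const Pt &v = q[idx[k]];
        if (cross3(a, b, v) >= -tol && cross3(b, c, v) >= -tol &&
            cross3(c, a, v) >= -tol)
          ok = false;
      }
      if (ok) {
        Poly t = {a, b, c};
        if (ringArea(t) > AREA_DROP) tris.push_back(t);
        idx.erase(idx.begin() + i);
        clipped = true;
        break;
      }
    }
    if (!clipped) {
      // numerically stuck: clip the most convex vertex unconditionally
      size_t best = 0; double bestCr = -1e300;
      for (size_t i = 0; i < idx.size(); ++i) {
        size_t m2 = idx.size();
        double cr = cross3(q[idx[(i + m2 - 1) % m2]], q[idx[i]],
                           q[idx[(i + 1) % m2]]);
        if (cr > bestCr) { bestCr = cr; best = i; }
      }
      size_t m2 = idx.size();
      Poly t = {q[idx[(best + m2 - 1) % m2]], q[idx[best]],
                q[idx[(best + 1) % m2]]};
      if (ringArea(t) > AREA_DROP) tris.push_back(t);
      idx.erase(idx.begin() + best);
    }
  }
  if (idx.size() == 3) {
    Poly t = {q[idx[0]], q[idx[1]], q[idx[2]]};
    if (ringArea(t) < 0) std::reverse(t.begin(), t.end());
    if (ringArea(t) > AREA_DROP) tris.push_back(t);
  }
  return cgToList(tris);
}

// ---------- Voronoi partition by halfplane clipping ----------

// [[Rcpp::export]]
List cpp_voronoi(NumericMatrix sites, double xmin, double ymin,
                 double xmax, double ymax) {
  int n = sites.nrow();
  List out(n);
  for (int i = 0; i < n; ++i) {
    Poly cell = {{xmin, ymin}, {xmax, ymin}, {xmax, ymax}, {xmin, ymax}};
    double sx = sites(i, 0), sy = sites(i, 1);
    for (int j = 0; j < n && !cell.empty(); ++j) {
      if (j == i) continue;
      double dx = sites(j, 0) - sx, dy = sites(j, 1) - sy;
      double mx = 0.5 * (sites(j, 0) + sx), my = 0.5 * (sites(j, 1) + sy);
      // keep points with (x-m).(d) <= 0  =>  dx*x + dy*y <= dx*mx + dy*my
      cell = clipHalf(cell, dx, dy, dx * mx + dy * my);
    }
    out[i] = polyToMat(cell);
  }
  return out;
}

// ---------- geometry helpers ----------

static void cgCentroid(const CG &g, double &cx, double &cy, double &area) {
  double sx = 0, sy = 0, sa = 0;
  for (const Poly &p : g) {
    size_t n = p.size();
    double a = 0, px = 0, py = 0;
    for (size_t i = 0; i < n; ++i) {
      size_t j = (i + 1) % n;
      double w = p[i].x * p[j].y - p[j].x * p[i].y;
      a += w;
      px += (p[i].x + p[j].x) * w;
      py += (p[i].y + p[j].y) * w;
    }
    a *= 0.5;
    if (std::fabs(a) > 0) { sx += px / 6.0; sy += py / 6.0; sa += a; }
  }
  area = sa;
  cx = sx / sa;
  cy = sy / sa;
}

// [[Rcpp::export]]
NumericVector cpp_cg_centroid(List g) {
  CG a = listToCG(g);
  double cx, cy, ar;
  cgCentroid(a, cx, cy, ar);
  return NumericVector::create(cx, cy);
}

static CG transformCG(const CG &g, double theta, double cx, double cy,
                      double tx, double ty) {
  double ct = std::cos(theta), st = std::sin(theta);
  CG out;
  out.reserve(g.size());
  for (const Poly &p : g) {
    Poly q;
    q.reserve(p.size());
    for (const Pt &v : p) {
      double dx = v.x - cx, dy = v.y - cy;
      q.push_back({ct * dx - st * dy + tx, st * dx + ct * dy + ty});
    }
    out.push_back(q);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_cg_transform(List g, double theta, double cx, double cy,
                      double tx, double ty) {
  return cgToList(transformCG(listToCG(g), theta, cx, cy, tx, ty));
}

// disjoint union of many decompositions: each part's pieces are already
// pairwise disjoint (representation invariant), so only earlier PARTS are
// subtracted — never sibling pieces, which would fragment along shared edges
static CG unionMany(const std::vector<CG> &parts) {
  CG u;
  std::vector<BBox> ub;
  for (const CG &part : parts) {
    CG add;
    for (const Poly &p : part) {
      CG work;
      work.push_back(p);
      BBox pb = polyBBox(p);
      for (size_t j = 0; j < u.size() && !work.empty(); ++j) {
        if (!bboxOverlap(pb, ub[j])) continue;
        CG next;
        for (const Poly &w : work) {
          if (!bboxOverlap(polyBBox(w), ub[j])) { next.push_back(w); continue; }
          convexMinusConvex(w, u[j], next);
        }
        work.swap(next);
      }
      for (Poly &w : work)
        if (std::fabs(ringArea(w)) > AREA_DROP) add.push_back(w);
    }
    for (Poly &w : add) {
      ub.push_back(polyBBox(w));
      u.push_back(w);
    }
  }
  return u;
}

// [[Rcpp::export]]
List cpp_cg_union_many(List gs) {
  std::vector<CG> parts;
  for (int i = 0; i < gs.size(); ++i) parts.push_back(listToCG(as<List>(gs[i])));
  return cgToList(unionMany(parts));
}

// ---------- placement + null model engine ----------

static double cgAreaC(const CG &g) {
  double s = 0;
  for (const Poly &p : g) s += ringArea(p);
  return s;
}

static CG intersectCG(const CG &a, const CG &b) {
  std::vector<BBox> ba = cgBBoxes(a), bb = cgBBoxes(b);
  CG out;
  for (size_t i = 0; i < a.size(); ++i)
    for (size_t j = 0; j < b.size(); ++j) {
      if (!bboxOverlap(ba[i], bb[j])) continue;
      Poly c = clipConvex(a[i], b[j]);
      if (c.size() >= 3 && std::fabs(ringArea(c)) > AREA_DROP) out.push_back(c);
    }
  return out;
}

static double interAreaCG(const CG &a, const std::vector<BBox> &ba,
                          const CG &b, const std::vector<BBox> &bb,
                          double stop_at) {
  double s = 0;
  for (size_t i = 0; i < a.size(); ++i)
    for (size_t j = 0; j < b.size(); ++j) {
      if (!bboxOverlap(ba[i], bb[j])) continue;
      Poly c = clipConvex(a[i], b[j]);
      if (c.size() >= 3) s += std::fabs(ringArea(c));
      if (stop_at > 0 && s > stop_at) return s;
    }
  return s;
}

// uniform point in a decomposition by rejection from its bbox (R RNG)
static bool uniformPointIn(const CG &g, const BBox &bb,
                           const std::vector<BBox> &pieceBB,
                           double &x, double &y) {
  for (int t = 0; t < 100000; ++t) {
    x = R::runif(bb.xmin, bb.xmax);
    y = R::runif(bb.ymin, bb.ymax);
    for (size_t i = 0; i < g.size(); ++i) {
      const BBox &b = pieceBB[i];
      if (x < b.xmin || x > b.xmax || y < b.ymin || y > b.ymax) continue;
      if (pointInConvex(g[i], x, y, 0.0)) return true;
    }
  }
  return false;
}

// one rigid placement of `piece` inside `eco`; shared by the null model,
// random_rigid_placement() and the synthetic generator at zero bias.
static CG placeOne(const CG &piece, double pcx, double pcy, double pieceArea,
                   const CG &eco, const BBox &ecoBB,
                   const std::vector<BBox> &ecoPieceBB,
                   const std::vector<BBox> &ecoBBoxes,
                   int max_tries, double containment, bool &fallback) {
  CG best;
  double bestFrac = -1.0;
  fallback = false;
  for (int t = 0; t < max_tries; ++t) {
    double theta = R::runif(0.0, 2.0 * M_PI);
    double tx, ty;
    if (!uniformPointIn(eco, ecoBB, ecoPieceBB, tx, ty)) break;
    CG cand = transformCG(piece, theta, pcx, pcy, tx, ty);
    std::vector<BBox> cb = cgBBoxes(cand);
    double inside = interAreaCG(cand, cb, eco, ecoBBoxes, -1.0);
    double frac = inside / pieceArea;
    if (frac >= containment - 1e-9) return cand;
    if (frac > bestFrac) { bestFrac = frac; best = cand; }
  }
  fallback = true;
  if (best.empty()) return best;
  return intersectCG(best, eco);  // clip best candidate to the ecoregion
}

// [[Rcpp::export]]
List cpp_place_piece(List piece, List ecoregion, int max_tries,
                     double containment) {
  CG p = listToCG(piece), e = listToCG(ecoregion);
  double pcx, pcy, pa;
  cgCentroid(p, pcx, pcy, pa);
  std::vector<BBox> epb = cgBBoxes(e);
  BBox eb = epb[0];
  for (const BBox &b : epb) {
    eb.xmin = std::min(eb.xmin, b.xmin); eb.xmax = std::max(eb.xmax, b.xmax);
    eb.ymin = std::min(eb.ymin, b.ymin); eb.ymax = std::max(eb.ymax, b.ymax);
  }
  bool fb;
  CG out = placeOne(p, pcx, pcy, pa, e, eb, epb, epb, max_tries, containment, fb);
  return List::create(_["geometry"] = cgToList(out), _["fallback"] = fb);
}

// count species whose range intersects the (disjoint) union pieces by more
// than eps_m2
static int countSpecies(const CG &uni, const std::vector<BBox> &ub,
                        const std::vector<CG> &ranges,
                        const std::vector<std::vector<BBox>> &rb,
                        const std::vector<BBox> &rOuter, double eps_m2) {
  if (uni.empty()) return 0;
  BBox outer = ub[0];
  for (const BBox &b : ub) {
    outer.xmin = std::min(outer.xmin, b.xmin);
    outer.xmax = std::max(outer.xmax, b.xmax);
    outer.ymin = std::min(outer.ymin, b.ymin);
    outer.ymax = std::max(outer.ymax, b.ymax);
  }
  int cnt = 0;
  for (size_t s = 0; s < ranges.size(); ++s) {
    if (!bboxOverlap(outer, rOuter[s])) continue;
    double a = interAreaCG(ranges[s], rb[s], uni, ub, eps_m2);
    if (a > eps_m2) ++cnt;
  }
  return cnt;
}

// full null-model run for one ecoregion: observed count + n_iter null counts
// [[Rcpp::export]]
List cpp_null_ecoregion(List pieces, List ranges, List ecoregion,
                        int n_iter, int max_tries, double containment,
                        double eps_m2) {
  int nP = pieces.size();
  std::vector<CG> P(nP);
  std::vector<double> pcx(nP), pcy(nP), parea(nP);
  for (int i = 0; i < nP; ++i) {
    P[i] = listToCG(as<List>(pieces[i]));
    cgCentroid(P[i], pcx[i], pcy[i], parea[i]);
  }
  int nS = ranges.size();
  std::vector<CG> Rg(nS);
  std::vector<std::vector<BBox>> Rb(nS);
  std::vector<BBox> Ro(nS);
  for (int s = 0; s < nS; ++s) {
    Rg[s] = listToCG(as<List>(ranges[s]));
    Rb[s] = cgBBoxes(Rg[s]);
    BBox o = Rb[s][0];
    for (const BBox &b : Rb[s]) {
      o.xmin = std::min(o.xmin, b.xmin); o.xmax = std::max(o.xmax, b.xmax);
      o.ymin = std::min(o.ymin, b.ymin); o.ymax = std::max(o.ymax, b.ymax);
    }
    Ro[s] = o;
  }
  CG E = listToCG(ecoregion);
  std::vector<BBox> Eb = cgBBoxes(E);
  BBox EB = Eb[0];
  for (const BBox &b : Eb) {
    EB.xmin = std::min(EB.xmin, b.xmin); EB.xmax = std::max(EB.xmax, b.xmax);
    EB.ymin = std::min(EB.ymin, b.ymin); EB.ymax = std::max(EB.ymax, b.ymax);
  }

  // observed: union of pieces as-is
  std::vector<CG> obsParts = P;
  CG obsU = unionMany(obsParts);
  std::vector<BBox> obsUb = cgBBoxes(obsU);
  int observed = countSpecies(obsU, obsUb, Rg, Rb, Ro, eps_m2);

  IntegerVector nullCounts(n_iter);
  int fallbacks = 0;
  for (int it = 0; it < n_iter; ++it) {
    std::vector<CG> placed(nP);
    for (int i = 0; i < nP; ++i) {
      bool fb;
      placed[i] = placeOne(P[i], pcx[i], pcy[i], parea[i], E, EB, Eb, Eb,
                           max_tries, containment, fb);
      if (fb) ++fallbacks;
    }
    CG u = unionMany(placed);
    std::vector<BBox> ub = cgBBoxes(u);
    nullCounts[it] = countSpecies(u, ub, Rg, Rb, Ro, eps_m2);
  }
  return List::create(_["observed"] = observed,
                      _["null_counts"] = nullCounts,
                      _["fallback_placements"] = fallbacks);
}

// species-richness raster: value = number of ranges intersecting each pixel
// [[Rcpp::export]]
IntegerMatrix cpp_richness_grid(List ranges, double xmin, double ymin,
                                double cell, int nx, int ny, double eps_m2) {
  IntegerMatrix out(ny, nx);  // row 1 = top row (north)
  int nS = ranges.size();
  for (int s = 0; s < nS; ++s) {
    CG g = listToCG(as<List>(ranges[s]));
    std::vector<BBox> gb = cgBBoxes(g);
    BBox o = gb[0];
    for (const BBox &b : gb) {
      o.xmin = std::min(o.xmin, b.xmin); o.xmax = std::max(o.xmax, b.xmax);
      o.ymin = std::min(o.ymin, b.ymin); o.ymax = std::max(o.ymax, b.ymax);
    }
    int i0 = std::max(0, (int)std::floor((o.xmin - xmin) / cell));
    int i1 = std::min(nx - 1, (int)std::floor((o.xmax - xmin) / cell));
    int j0 = std::max(0, (int)std::floor((o.ymin - ymin) / cell));
    int j1 = std::min(ny - 1, (int)std::floor((o.ymax - ymin) / cell));
    for (int i = i0; i <= i1; ++i) {
      for (int j = j0; j <= j1; ++j) {
        double x0 = xmin + i * cell, y0 = ymin + j * cell;
        Poly px = {{x0, y0}, {x0 + cell, y0}, {x0 + cell, y0 + cell},
                   {x0, y0 + cell}};
        BBox pb = {x0, y0, x0 + cell, y0 + cell};
        double a = 0;
        for (size_t k = 0; k < g.size(); ++k) {
          if (!bboxOverlap(pb, gb[k])) continue;
          Poly c = clipConvex(px, g[k]);
          if (c.size() >= 3) a += std::fabs(ringArea(c));
          if (a > eps_m2) break;
        }
        if (a > eps_m2) out(ny - 1 - j, i) += 1;  // top row = max y
      }
    }
  }
  return out;
}
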