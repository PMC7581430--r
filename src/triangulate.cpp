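// Incremental Bowyer-Watson Delaunay triangulation and planar geometry
// predicates used by the mesh generator. Coordinates are normalised to the
// unit box internally so the floating-point tolerances below are scale-free.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

static inline double orient2d(double ax, double ay, double bx, double by,
                              double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// > 0 iff d lies inside the circumcircle of CCW triangle (a, b, c)
static inline double incircle(double ax, double ay, double bx, double by,
                              double cx, double cy, double dx, double dy) {
  const double adx = ax - dx, ady = ay - dy;
  const double bdx = bx - dx, bdy = by - dy;
  const double cdx = cx - dx, cdy = cy - dy;
  const double ad = adx * adx + ady * ady;
  const double bd = bdx * bdx + bdy * bdy;
  const double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy) - ady * (bdx * cd - bd * cdx) +
         ad * (bdx * cdy - bdy * cdx);
}

struct Tri {
  int v[3];
  int n[3];  // neighbour across edge opposite v[i]; -1 on hull
  bool alive;
};

// [[Rcpp::export]]
IntegerMatrix delaunay_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 3) stop("need at least 3 points");

  // normalise to unit box
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    xmin = std::min(xmin, pts(i, 0)); xmax = std::max(xmax, pts(i, 0));
    ymin = std::min(ymin, pts(i, 1)); ymax = std::max(ymax, pts(i, 1));
  }
  const double scale = std::max(std::max(xmax - xmin, ymax - ymin), 1e-300);
  // In addition to the super-triangle, a distant convex ring of guard points
  // is inserted before the data so that every data point lies strictly inside
  // the existing finite hull; this keeps the incircle cavity search exact for
  // collinear boundary points. Guard triangles are stripped at the end.
  const int ng = 24;
  const int ntot = n + ng + 3;
  std::vector<double> px(ntot), py(ntot);
  for (int i = 0; i < n; ++i) {
    px[i] = (pts(i, 0) - xmin) / scale;
    py[i] = (pts(i, 1) - ymin) / scale;
  }
  for (int g = 0; g < ng; ++g) {
    const double a = 2.0 * M_PI * (g + 0.37) / ng;
    px[n + g] = 0.5 + 6.0 * std::cos(a);
    py[n + g] = 0.5 + 6.0 * std::sin(a);
  }
  // super-triangle (CCW), generously larger than the guard ring
  px[n + ng] = -1000.0;     py[n + ng] = -1000.0;
  px[n + ng + 1] = 1001.0;  py[n + ng + 1] = -1000.0;
  px[n + ng + 2] = 0.5;     py[n + ng + 2] = 1500.0;

  std::vector<Tri> T;
  T.reserve(2 * ntot + 16);
  T.push_back({{n + ng, n + ng + 1, n + ng + 2}, {-1, -1, -1}, true});
  int last = 0;

  const double eps_in = 1e-13;

  std::vector<int> bad, stack_;
  std::vector<char> inbad;
  inbad.reserve(2 * n + 16);

  for (int k = 0; k < n + ng; ++k) {
    const int ip = (k < ng) ? n + k : k - ng;  // guard ring first, then data
    const double qx = px[ip], qy = py[ip];

    // locate containing triangle by walking
    int t = last;
    if (t < 0 || !T[t].alive) {
      t = -1;
      for (int k = (int)T.size() - 1; k >= 0; --k)
        if (T[k].alive) { t = k; break; }
    }
    bool found = false;
    for (int step = 0; step < (int)T.size() * 4 + 64; ++step) {
      int move = -1;
      for (int e = 0; e < 3; ++e) {
        const int a = T[t].v[(e + 1) % 3], b = T[t].v[(e + 2) % 3];
        if (orient2d(px[a], py[a], px[b], py[b], qx, qy) < 0) {
          move = T[t].n[e];
          break;
        }
      }
      if (move < 0) { found = true; break; }
      t = move;
    }
    if (!found) {
      // fallback: linear scan with tolerant containment
      t = -1;
      for (int k = 0; k < (int)T.size(); ++k) {
        if (!T[k].alive) continue;
        bool ok = true;
        for (int e = 0; e < 3 && ok; ++e) {
          const int a = T[k].v[(e + 1) % 3], b = T[k].v[(e + 2) % 3];
          if (orient2d(px[a], py[a], px[b], py[b], qx, qy) < -1e-12) ok = false;
        }
        if (ok) { t = k; break; }
      }
      if (t < 0) stop("triangulation: point location failed");
    }

    // grow cavity of triangles whose circumcircle contains the point
    bad.clear();
    inbad.assign(T.size(), 0);
    stack_.clear();
    stack_.push_back(t);
    inbad[t] = 1;
    while (!stack_.empty()) {
      const int c = stack_.back(); stack_.pop_back();
      bad.push_back(c);
      for (int e = 0; e < 3; ++e) {
        const int nb = T[c].n[e];
        if (nb < 0 || inbad[nb] || !T[nb].alive) continue;
        const int *v = T[nb].v;
        if (incircle(px[v[0]], py[v[0]], px[v[1]], py[v[1]],
                     px[v[2]], py[v[2]], qx, qy) > eps_in) {
          inbad[nb] = 1;
          stack_.push_back(nb);
        }
      }
    }

    // cavity boundary edges (a, b) with outer neighbour
    struct BEdge { int a, b, outer, from; };
    std::vector<BEdge> bnd;
    for (int c : bad) {
      for (int e = 0; e < 3; ++e) {
        const int nb = T[c].n[e];
        if (nb >= 0 && inbad[nb]) continue;
        bnd.push_back({T[c].v[(e + 1) % 3], T[c].v[(e + 2) % 3], nb, c});
      }
    }
    for (int c : bad) T[c].alive = false;

    // retriangulate the star of the new point
    std::vector<int> newtri(bnd.size());
    for (size_t k = 0; k < bnd.size(); ++k) {
      T.push_back({{bnd[k].a, bnd[k].b, ip}, {-1, -1, -1}, true});
      newtri[k] = (int)T.size() - 1;
      inbad.push_back(0);
    }
    // link: edge opposite vertex 2 (= (a,b)) -> outer; fix outer back-pointer
    std::map<int, int> bystart, byend;
    for (size_t k = 0; k < bnd.size(); ++k) {
      bystart[bnd[k].a] = newtri[k];
      byend[bnd[k].b] = newtri[k];
    }
    for (size_t k = 0; k < bnd.size(); ++k) {
      const int id = newtri[k];
      T[id].n[2] = bnd[k].outer;
      if (bnd[k].outer >= 0) {
        Tri &O = T[bnd[k].outer];
        for (int e = 0; e < 3; ++e)
          if (O.n[e] == bnd[k].from) O.n[e] = id;
      }
      T[id].n[0] = bystart.count(bnd[k].b) ? bystart[bnd[k].b] : -1;  // edge (b, p)
      T[id].n[1] = byend.count(bnd[k].a) ? byend[bnd[k].a] : -1;      // edge (p, a)
    }
    if (!newtri.empty()) last = newtri[0];
  }

  // strip super-triangle
  int m = 0;
  for (const Tri &t : T)
    if (t.alive && t.v[0] < n && t.v[1] < n && t.v[2] < n) ++m;
  IntegerMatrix out(m, 3);
  int r = 0;
  for (const Tri &t : T) {
    if (!(t.alive && t.v[0] < n && t.v[1] < n && t.v[2] < n)) continue;
    out(r, 0) = t.v[0] + 1;
    out(r, 1) = t.v[1] + 1;
    out(r, 2) = t.v[2] + 1;
    ++r;
  }
  return out;
}

// Even-odd point-in-polygon for a set of rings (outer ring + holes).
// rings: list of k x 2 matrices (open rings, consecutive vertices joined,
// last joined to first). Returns logical per query point.
// [[Rcpp::export]]
LogicalVector points_in_rings_cpp(NumericMatrix q, List rings) {
  const int nq = q.nrow();
  LogicalVector res(nq);
  const int nr = rings.size();
  std::vector<NumericMatrix> R(nr);
  for (int r = 0; r < nr; ++r) R[r] = as<NumericMatrix>(rings[r]);
  for (int i = 0; i < nq; ++i) {
    const double x = q(i, 0), y = q(i, 1);
    bool inside = false;
    for (int r = 0; r < nr; ++r) {
      const NumericMatrix &P = R[r];
      const int k = P.nrow();
      for (int a = 0, b = k - 1; a < k; b = a++) {
        const double ax = P(a, 0), ay = P(a, 1), bx = P(b, 0), by = P(b, 1);
        if (((ay > y) != (by > y)) &&
            (x < (bx - ax) * (y - ay) / (by - ay) + ax))
          inside = !inside;
      }
    }
    res[i] = inside;
  }
  return res;
}

// Minimum distance from each query point to a set of segments.
// segs: k x 4 matrix (x1, y1, x2, y2)
// [[Rcpp::export]]
NumericVector min_seg_dist_cpp(NumericMatrix q, NumericMatrix segs) {
  const int nq = q.nrow(), ns = segs.nrow();
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    const double x = q(i, 0), y = q(i, 1);
    double best = R_PosInf;
    for (int s = 0; s < ns; ++s) {
      const double ax = segs(s, 0), ay = segs(s, 1);
      const double dx = segs(s, 2) - ax, dy = segs(s, 3) - ay;
      const double L2 = dx * dx + dy * dy;
      double t = L2 > 0 ? ((x - ax) * dx + (y - ay) * dy) / L2 : 0.0;
      t = std::max(0.0, std::min(1.0, t));
      const double ex = ax + t * dx - x, ey = ay + t * dy - y;
      best = std::min(best, ex * ex + ey * ey);
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
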