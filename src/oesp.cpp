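// Dynamic programming over local lattices: find the minimum-displacement
// lattice path whose consecutive distances, pseudo-bond angles and steric
// separation satisfy the protein-likeness constraints. Infinities are IEEE
// infinities throughout: they propagate through addition and min() exactly
// and are never approximated by large finite values.

#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct Grid {
  int n, Q;
  std::vector<double> pts;  // vertex (j,i) at pts[(j*Q+i)*3]
  std::vector<double> ctr;  // center j at ctr[j*3]
  const double* v(int j, int i) const {
    return &pts[(static_cast<size_t>(j) * Q + i) * 3];
  }
  const double* c(int j) const { return &ctr[static_cast<size_t>(j) * 3]; }
};

static inline double dist3(const double* a, const double* b) {
  const double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// vertex angle at b between arms to a and c, degrees in [0, 180]
static inline double vertexAngle(const double* a, const double* b,
                                 const double* c) {
  const double ux = a[0] - b[0], uy = a[1] - b[1], uz = a[2] - b[2];
  const double wx = c[0] - b[0], wy = c[1] - b[1], wz = c[2] - b[2];
  const double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
  const double nw = std::sqrt(wx * wx + wy * wy + wz * wz);
  double ct = (ux * wx + uy * wy + uz * wz) / (nu * nw);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return std::acos(ct) * 180.0 / M_PI;
}

static Grid buildGrid(const List& lattices, const NumericMatrix& centers) {
  Grid g;
  g.n = centers.nrow();
  NumericMatrix first = lattices[0];
  g.Q = first.nrow();
  g.pts.resize(static_cast<size_t>(g.n) * g.Q * 3);
  g.ctr.resize(static_cast<size_t>(g.n) * 3);
  for (int j = 0; j < g.n; ++j) {
    NumericMatrix L = lattices[j];
    if (L.nrow() != g.Q) stop("all lattices must have equal vertex counts");
    for (int i = 0; i < g.Q; ++i)
      for (int c = 0; c < 3; ++c)
        g.pts[(static_cast<size_t>(j) * g.Q + i) * 3 + c] = L(i, c);
    for (int c = 0; c < 3; ++c)
      g.ctr[static_cast<size_t>(j) * 3 + c] = centers(j, c);
  }
  return g;
}

// VScore for every vertex of lattice j; the clash penalty uses the centers
// of positions 0..j-2 only (no lookahead).
static std::vector<double> vScores(const Grid& g, int j, bool useClash,
                                   double z, double mult, bool literal) {
  std::vector<double> V(g.Q);
  for (int i = 0; i < g.Q; ++i) {
    const double d0 = dist3(g.v(j, i), g.c(j));
    double base = d0 * d0;
    if (useClash && j >= 2) {
      double s = 0.0, dmin = INF;
      bool zero = false;
      for (int m = 0; m <= j - 2; ++m) {
        const double dm = dist3(g.v(j, i), g.c(m));
        if (dm < dmin) dmin = dm;
        if (dm <= 0.0) { zero = true; break; }
        s += 1.0 / (dm * dm);
      }
      if (zero) { V[i] = INF; continue; }
      const bool trig = literal ? (d0 <= z) : (dmin <= z);
      V[i] = trig ? base + mult * s : base;
    } else {
      V[i] = base;
    }
  }
  return V;
}

static List resultList(const Grid& g, const std::vector<int>& path,
                       double score, bool feasible) {
  if (!feasible)
    return List::create(_["feasible"] = false, _["score"] = INF,
                        _["points"] = R_NilValue, _["index"] = R_NilValue);
  NumericMatrix pts(g.n, 3);
  IntegerVector idx(g.n);
  for (int j = 0; j < g.n; ++j) {
    const double* v = g.v(j, path[j]);
    pts(j, 0) = v[0]; pts(j, 1) = v[1]; pts(j, 2) = v[2];
    idx[j] = path[j] + 1;
  }
  return List::create(_["feasible"] = true, _["score"] = score,
                      _["points"] = pts, _["index"] = idx);
}

// Basic (useAngle = false) and simplified (useAngle = true) recurrences.
// The simplified strategy checks the angle against the predecessor stored on
// the best path into each vertex of the previous lattice: O(n Q^2), sound
// for the constraints but possibly suboptimal.
// [[Rcpp::export]]
List oespDpCpp(List lattices, NumericMatrix centers, LogicalVector brokenEdge,
               LogicalVector brokenAngle, double lo, double hi, double angLo,
               double angHi, double z, double mult, bool useAngle,
               bool useClash, bool literalTrigger) {
  Grid g = buildGrid(lattices, centers);
  const int n = g.n, Q = g.Q;
  std::vector<std::vector<int> > prev(n, std::vector<int>(Q, -1));
  std::vector<double> dp = vScores(g, 0, useClash, z, mult, literalTrigger);
  for (int j = 1; j < n; ++j) {
    std::vector<double> Vj = vScores(g, j, useClash, z, mult, literalTrigger);
    std::vector<double> nd(Q, INF);
    const bool be = brokenEdge[j - 1];
    const bool ba = (j >= 2) ? static_cast<bool>(brokenAngle[j - 1]) : true;
    for (int i = 0; i < Q; ++i) {
      if (Vj[i] == INF) continue;
      double best = INF;
      int bh = -1;
      const double* vi = g.v(j, i);
      for (int h = 0; h < Q; ++h) {
        const double p = dp[h];
        if (p == INF || p >= best) continue;  // strict <: lowest index wins
        if (!be) {
          const double d = dist3(g.v(j - 1, h), vi);
          if (d < lo || d > hi) continue;
        }
        if (useAngle && j >= 2 && !ba) {
          const double a =
              vertexAngle(g.v(j - 2, prev[j - 1][h]), g.v(j - 1, h), vi);
          if (a < angLo || a > angHi) continue;
        }
        best = p;
        bh = h;
      }
      if (bh >= 0) {
        nd[i] = Vj[i] + best;
        prev[j][i] = bh;
      }
    }
    dp.swap(nd);
  }
  int bi = -1;
  double best = INF;
  for (int i = 0; i < Q; ++i)
    if (dp[i] < best) { best = dp[i]; bi = i; }
  if (bi < 0) return resultList(g, std::vector<int>(), INF, false);
  std::vector<int> path(n);
  path[n - 1] = bi;
  for (int j = n - 1; j > 0; --j) path[j - 1] = prev[j][path[j]];
  return resultList(g, path, best, true);
}

// Advanced recurrence over (current, previous) vertex-pair states: exact
// optimum under distance + angle + clash-penalized vertex scores. O(n Q^3).
// [[Rcpp::export]]
List oespAdvancedCpp(List lattices, NumericMatrix centers,
                     LogicalVector brokenEdge, LogicalVector brokenAngle,
                     double lo, double hi, double angLo, double angHi,
                     double z, double mult, bool useClash,
                     bool literalTrigger) {
  Grid g = buildGrid(lattices, centers);
  const int n = g.n, Q = g.Q;
  if (n < 3) stop("advanced recurrence needs n >= 3");
  const size_t QQ = static_cast<size_t>(Q) * Q;
  // dp[i*Q + h]: best path ending at vertex i of lattice j through vertex h
  // of lattice j-1
  std::vector<double> dp(QQ, INF);
  {
    std::vector<double> V0 = vScores(g, 0, useClash, z, mult, literalTrigger);
    std::vector<double> V1 = vScores(g, 1, useClash, z, mult, literalTrigger);
    const bool be = brokenEdge[0];
    for (int i = 0; i < Q; ++i)
      for (int h = 0; h < Q; ++h) {
        double e = 0.0;
        if (!be) {
          const double d = dist3(g.v(0, h), g.v(1, i));
          if (d < lo || d > hi) e = INF;
        }
        dp[static_cast<size_t>(i) * Q + h] = V1[i] + e + V0[h];
      }
  }
  std::vector<std::vector<int> > ptr(n);
  for (int j = 2; j < n; ++j) {
    std::vector<double> Vj = vScores(g, j, useClash, z, mult, literalTrigger);
    std::vector<double> nd(QQ, INF);
    ptr[j].assign(QQ, -1);
    const bool be = brokenEdge[j - 1];
    const bool ba = brokenAngle[j - 1];
    for (int h = 0; h < Q; ++h) {
      const double* vh = g.v(j - 1, h);
      int freeG = -1;
      double freeBest = INF;
      if (ba) {  // angle waived: inner minimum is independent of i
        for (int gg = 0; gg < Q; ++gg) {
          const double p = dp[static_cast<size_t>(h) * Q + gg];
          if (p < freeBest) { freeBest = p; freeG = gg; }
        }
        if (freeG < 0) continue;
      }
      for (int i = 0; i < Q; ++i) {
        const double* vi = g.v(j, i);
        double e = 0.0;
        if (!be) {
          const double d = dist3(vh, vi);
          if (d < lo || d > hi) continue;
        }
        double best = INF;
        int bg = -1;
        if (ba) {
          best = freeBest;
          bg = freeG;
        } else {
          for (int gg = 0; gg < Q; ++gg) {
            const double p = dp[static_cast<size_t>(h) * Q + gg];
            if (p == INF || p >= best) continue;
            const double a = vertexAngle(g.v(j - 2, gg), vh, vi);
            if (a < angLo || a > angHi) continue;
            best = p;
            bg = gg;
          }
        }
        if (bg >= 0) {
          nd[static_cast<size_t>(i) * Q + h] = Vj[i] + e + best;
          ptr[j][static_cast<size_t>(i) * Q + h] = bg;
        }
      }
    }
    dp.swap(nd);
  }
  double best = INF;
  int bi = -1, bh = -1;
  for (int i = 0; i < Q; ++i)
    for (int h = 0; h < Q; ++h) {
      const double p = dp[static_cast<size_t>(i) * Q + h];
      if (p < best) { best = p; bi = i; bh = h; }
    }
  if (bi < 0) return resultList(g, std::vector<int>(), INF, false);
  std::vector<int> path(n);
  path[n - 1] = bi;
  path[n - 2] = bh;
  int i = bi, h = bh;
  for (int j = n - 1; j >= 2; --j) {
    const int gg = ptr[j][static_cast<size_t>(i) * Q + h];
    path[j - 2] = gg;
    i = h;
    h = gg;
  }
  return resultList(g, path, best, true);
}
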