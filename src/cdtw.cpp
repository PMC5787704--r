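// Constrained dynamic time warping (cDTW).
//
// Standard symmetric-step DTW over the local cost |x_i - y_j|^p, augmented
// with an elastic constraint: a warp path may take at most `max_run`
// consecutive steps in the same non-diagonal direction (horizontal =
// advancing x only, vertical = advancing y only). max_run = 0 admits only
// the diagonal path (equal lengths required). An optional Sakoe-Chiba band
// of half-width `band` (in frames) further restricts |i - j|.
//
// The DP state tracks (cell, direction, run length). Each visited cell
// contributes its local cost exactly once; ties in total cost are broken
// toward the shorter path so that path-length normalization is
// deterministic.

#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct Cell {
  double cost;
  int len;
};

static inline void relax(Cell &dst, double cost, int len) {
  if (cost < dst.cost || (cost == dst.cost && len < dst.len)) {
    dst.cost = cost;
    dst.len = len;
  }
}

// Core DP. Returns unnormalized optimal cost and its path length.
static Cell cdtw_core(const double *x, int n, const double *y, int m,
                      int max_run, int band, double exponent) {
  // states per cell: 0 = arrived by diagonal, 1..max_run = horizontal run,
  // max_run+1 .. 2*max_run = vertical run
  const int ns = 2 * max_run + 1;
  std::vector<Cell> prev((size_t)m * ns), cur((size_t)m * ns);
  const Cell bad = {INF, 0};

  auto cost_at = [&](int i, int j) {
    double d = std::fabs(x[i] - y[j]);
    return exponent == 1.0 ? d : std::pow(d, exponent);
  };
  auto inband = [&](int i, int j) {
    return band < 0 || std::abs(i - j) <= band;
  };

  // per-cell aggregates over the state dimension (computed once per cell):
  // best over all states (diagonal predecessors), best over {diag, any
  // vertical run} (fresh horizontal runs) and vice versa
  std::vector<Cell> prevAll(m), curAll(m), prevFh(m), curFh(m),
      prevFv(m), curFv(m);

  auto finish_cell = [&](std::vector<Cell> &states, std::vector<Cell> &all,
                         std::vector<Cell> &fh, std::vector<Cell> &fv,
                         int j) {
    const Cell *s = &states[(size_t)j * ns];
    Cell a = bad, h = bad, v = bad;
    relax(a, s[0].cost, s[0].len);
    relax(h, s[0].cost, s[0].len);
    relax(v, s[0].cost, s[0].len);
    for (int r = 1; r <= max_run; ++r) {
      relax(a, s[r].cost, s[r].len);                    // horizontal runs
      relax(v, s[r].cost, s[r].len);
      relax(a, s[max_run + r].cost, s[max_run + r].len); // vertical runs
      relax(h, s[max_run + r].cost, s[max_run + r].len);
    }
    all[j] = a;
    fh[j] = h;
    fv[j] = v;
  };

  for (int i = 0; i < n; ++i) {
    std::fill(cur.begin(), cur.end(), bad);
    for (int j = 0; j < m; ++j) {
      if (!inband(i, j)) {
        curAll[j] = bad; curFh[j] = bad; curFv[j] = bad;
        continue;
      }
      double c = cost_at(i, j);
      Cell *here = &cur[(size_t)j * ns];
      if (i == 0 && j == 0) {
        relax(here[0], c, 1);
        finish_cell(cur, curAll, curFh, curFv, j);
        continue;
      }
      // diagonal arrival from (i-1, j-1), best over all predecessor states
      if (i > 0 && j > 0 && prevAll[j - 1].cost < INF)
        relax(here[0], prevAll[j - 1].cost + c, prevAll[j - 1].len + 1);
      if (max_run > 0) {
        // horizontal arrival from (i-1, j)
        if (i > 0) {
          const Cell *p = &prev[(size_t)j * ns];
          if (prevFh[j].cost < INF)   // fresh run (diag or vertical pred)
            relax(here[1], prevFh[j].cost + c, prevFh[j].len + 1);
          for (int r = 1; r < max_run; ++r)
            if (p[r].cost < INF)
              relax(here[r + 1], p[r].cost + c, p[r].len + 1);
        }
        // vertical arrival from (i, j-1)
        if (j > 0) {
          const Cell *p = &cur[(size_t)(j - 1) * ns];
          if (curFv[j - 1].cost < INF)
            relax(here[max_run + 1], curFv[j - 1].cost + c,
                  curFv[j - 1].len + 1);
          for (int r = 1; r < max_run; ++r) {
            const Cell &q = p[max_run + r];
            if (q.cost < INF)
              relax(here[max_run + r + 1], q.cost + c, q.len + 1);
          }
        }
      }
      finish_cell(cur, curAll, curFh, curFv, j);
    }
    std::swap(prev, cur);
    std::swap(prevAll, curAll);
    std::swap(prevFh, curFh);
    std::swap(prevFv, curFv);
  }

  Cell best = bad;
  const Cell *last = &prev[(size_t)(m - 1) * ns];
  for (int s = 0; s < ns; ++s)
    if (last[s].cost < INF) relax(best, last[s].cost, last[s].len);
  return best;
}


double cdtw_cpp(NumericVector x, NumericVector y, int max_run, int band,
                double exponent, bool normalize) {
  int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("empty series");
  Cell r = cdtw_core(REAL(x), n, REAL(y), m, max_run, band, exponent);
  if (!(r.cost < INF)) return R_PosInf;
  return normalize ? r.cost / r.len : r.cost;
}

// All unordered pairs of a set of equal-or-varying-length series.

NumericMatrix cdtw_matrix_cpp(List series, int max_run, int band,
                              double exponent, bool normalize) {
  int n = series.size();
  std::vector<NumericVector> xs(n);
  for (int i = 0; i < n; ++i) xs[i] = as<NumericVector>(series[i]);
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      Cell r = cdtw_core(REAL(xs[i]), xs[i].size(), REAL(xs[j]), xs[j].size(),
                         max_run, band, exponent);
      double d = (r.cost < INF) ? (normalize ? r.cost / r.len : r.cost)
                                : R_PosInf;
      D(i, j) = d;
      D(j, i) = d;
    }
    Rcpp::checkUserInterrupt();
  }
  return D;
}

// hand-written .Call wrappers; registration lives in init.c so that the
// deSolve-facing C routines in pathway_rhs.c are registered alongside
extern "C" {
SEXP c_cdtw(SEXP xSEXP, SEXP ySEXP, SEXP max_runSEXP, SEXP bandSEXP,
            SEXP exponentSEXP, SEXP normalizeSEXP) {
  BEGIN_RCPP
  return wrap(cdtw_cpp(as<NumericVector>(xSEXP), as<NumericVector>(ySEXP),
                       as<int>(max_runSEXP), as<int>(bandSEXP),
                       as<double>(exponentSEXP), as<bool>(normalizeSEXP)));
  END_RCPP
}

SEXP c_cdtw_matrix(SEXP seriesSEXP, SEXP max_runSEXP, SEXP bandSEXP,
                   SEXP exponentSEXP, SEXP normalizeSEXP) {
  BEGIN_RCPP
  return wrap(cdtw_matrix_cpp(as<List>(seriesSEXP), as<int>(max_runSEXP),
                              as<int>(bandSEXP), as<double>(exponentSEXP),
                              as<bool>(normalizeSEXP)));
  END_RCPP
}
}
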