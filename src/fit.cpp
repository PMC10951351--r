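// Grouped Poisson linear relative-risk fitting and the quasi-2DMC
// Bayesian-model-averaging sampler.
//
// Model: lambda_g = offset_g * exp(kappa) * (1 + alpha d_g + beta d_g^2),
// subject to 1 + alpha d + beta d^2 > 0 in every group. kappa is profiled
// out in closed form: exp(kappa_hat) = N / sum(offset * r). The remaining
// coefficients are maximized by damped Newton with analytic derivatives,
// multi-start, and golden-section fallback. Profile-likelihood interval
// endpoints are found by expansion + bisection on the profile deviance.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

namespace {

const double NEG_INF = -std::numeric_limits<double>::infinity();

struct GroupData {
  std::vector<double> y, off, d, d2;
  double N = 0.0;     // total cases
  double cst = 0.0;   // sum y log(off) - sum lgamma(y + 1)
  int G = 0;

  void set_dose(const double *dd) {
    for (int i = 0; i < G; ++i) { d[i] = dd[i]; d2[i] = dd[i] * dd[i]; }
  }
};

GroupData make_data(const NumericVector &y, const NumericVector &off) {
  GroupData g;
  g.G = y.size();
  g.y.assign(y.begin(), y.end());
  g.off.assign(off.begin(), off.end());
  g.d.assign(g.G, 0.0);
  g.d2.assign(g.G, 0.0);
  for (int i = 0; i < g.G; ++i) {
    g.N += y[i];
    g.cst += y[i] * std::log(off[i]) - std::lgamma(y[i] + 1.0);
  }
  return g;
}

// full Poisson log-likelihood at (a, b) with kappa profiled out
double pll(const GroupData &g, double a, double b, double *kap = nullptr) {
  double u = 0.0, s = 0.0;
  for (int i = 0; i < g.G; ++i) {
    double r = 1.0 + a * g.d[i] + b * g.d2[i];
    if (r <= 1e-12) return NEG_INF;
    u += g.off[i] * r;
    s += g.y[i] * std::log(r);
  }
  double k = std::log(g.N / u);
  if (kap) *kap = k;
  return s + g.cst + g.N * k - g.N;
}

// gradient and Hessian of the profiled log-likelihood in (a, b)
void grad_hess(const GroupData &g, double a, double b,
               double gr[2], double H[3]) {
  double u = 0.0, P1 = 0.0, P2 = 0.0;
  double sy1 = 0.0, sy2 = 0.0, q11 = 0.0, q12 = 0.0, q22 = 0.0;
  for (int i = 0; i < g.G; ++i) {
    double r = 1.0 + a * g.d[i] + b * g.d2[i];
    u += g.off[i] * r;
    P1 += g.off[i] * g.d[i];
    P2 += g.off[i] * g.d2[i];
    double yr = g.y[i] / r, yr2 = g.y[i] / (r * r);
    sy1 += yr * g.d[i];
    sy2 += yr * g.d2[i];
    q11 += yr2 * g.d2[i];
    q12 += yr2 * g.d[i] * g.d2[i];
    q22 += yr2 * g.d2[i] * g.d2[i];
  }
  gr[0] = sy1 - g.N * P1 / u;
  gr[1] = sy2 - g.N * P2 / u;
  H[0] = -q11 + g.N * P1 * P1 / (u * u);
  H[1] = -q12 + g.N * P1 * P2 / (u * u);
  H[2] = -q22 + g.N * P2 * P2 / (u * u);
}

// golden-section maximization of f on [lo, hi] (assumes a bracket)
template <typename F>
double golden(F f, double lo, double hi, int iters = 120) {
  const double gr = 0.6180339887498949;
  double a = lo, b = hi;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = f(x1), f2 = f(x2);
  for (int i = 0; i < iters && (b - a) > 1e-12 * (1.0 + std::fabs(a)); ++i) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a); f2 = f(x2);
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a); f1 = f(x1);
    }
  }
  return (f1 > f2) ? x1 : x2;
}

// expand a bracket around `start` for a 1D concave-ish objective; the
// feasible region is (lo_bound, +inf)
template <typename F>
void bracket1d(F f, double start, double lo_bound, double &lo, double &hi) {
  double step = 0.5;
  double fx = f(start);
  if (!R_finite(fx)) {  // move into the feasible region
    start = (R_finite(lo_bound) ? lo_bound : 0.0) + 1.0;
    fx = f(start);
  }
  // right expansion
  hi = start;
  double fh = fx;
  for (int i = 0; i < 200; ++i) {
    double cand = hi + step;
    double fc = f(cand);
    if (fc <= fh) { hi = cand; break; }
    hi = cand; fh = fc; step *= 1.8;
    if (hi > 1e8) break;
  }
  // left expansion (respect the feasibility bound)
  step = 0.5;
  lo = start;
  double fl = fx;
  for (int i = 0; i < 200; ++i) {
    double cand = lo - step;
    if (R_finite(lo_bound) && cand <= lo_bound)
      cand = lo_bound + 0.25 * (lo - lo_bound);
    double fc = f(cand);
    if (fc <= fl) { lo = cand; break; }
    lo = cand; fl = fc; step *= 1.8;
    if (lo < -1e8) break;
    if (R_finite(lo_bound) && (lo - lo_bound) < 1e-12) break;
  }
}

// 1D Newton + golden fallback: maximize profiled ll over b at fixed a
double max_b_given_a(const GroupData &g, double a, double b_start,
                     double *ll_out) {
  // feasibility: b > bmin = max_g -(1 + a d) / d^2
  double bmin = NEG_INF;
  for (int i = 0; i < g.G; ++i) {
    if (g.d2[i] > 0) bmin = std::max(bmin, -(1.0 + a * g.d[i]) / g.d2[i]);
  }
  double b = b_start;
  if (!R_finite(pll(g, a, b))) b = bmin + 1.0;
  double ll = pll(g, a, b);
  bool newton_ok = false;
  for (int it = 0; it < 100; ++it) {
    double gr[2], H[3];
    grad_hess(g, a, b, gr, H);
    double db;
    if (H[2] < -1e-300) db = -gr[1] / H[2];
    else db = (gr[1] > 0 ? 1.0 : -1.0) * std::max(1.0, 0.5 * std::fabs(b));
    double t = 1.0;
    bool moved = false;
    for (int h = 0; h < 60; ++h) {
      double bb = b + t * db;
      if (bb > bmin) {
        double l2 = pll(g, a, bb);
        if (R_finite(l2) && l2 >= ll) { b = bb; ll = l2; moved = true; break; }
      }
      t *= 0.5;
    }
    if (std::fabs(gr[1]) < 1e-9 * (1.0 + std::fabs(ll))) {
      newton_ok = true;
      break;
    }
    if (!moved) break;
  }
  if (!newton_ok) {
    auto f = [&](double bb) { return pll(g, a, bb); };
    double lo, hi;
    bracket1d(f, b, bmin, lo, hi);
    double bg = golden(f, lo, hi);
    double lg = pll(g, a, bg);
    if (lg > ll) { b = bg; ll = lg; }
  }
  if (ll_out) *ll_out = ll;
  return b;
}

// maximize over a at fixed b (for the beta profile)
double max_a_given_b(const GroupData &g, double b, double a_start,
                     double *ll_out) {
  double amin = NEG_INF;
  for (int i = 0; i < g.G; ++i) {
    if (g.d[i] > 0) amin = std::max(amin, -(1.0 + b * g.d2[i]) / g.d[i]);
  }
  double a = a_start;
  if (!R_finite(pll(g, a, b))) a = amin + 1.0;
  double ll = pll(g, a, b);
  bool newton_ok = false;
  for (int it = 0; it < 100; ++it) {
    double gr[2], H[3];
    grad_hess(g, a, b, gr, H);
    double da;
    if (H[0] < -1e-300) da = -gr[0] / H[0];
    else da = (gr[0] > 0 ? 1.0 : -1.0) * std::max(1.0, 0.5 * std::fabs(a));
    double t = 1.0;
    bool moved = false;
    for (int h = 0; h < 60; ++h) {
      double aa = a + t * da;
      if (aa > amin) {
        double l2 = pll(g, aa, b);
        if (R_finite(l2) && l2 >= ll) { a = aa; ll = l2; moved = true; break; }
      }
      t *= 0.5;
    }
    if (std::fabs(gr[0]) < 1e-9 * (1.0 + std::fabs(ll))) {
      newton_ok = true;
      break;
    }
    if (!moved) break;
  }
  if (!newton_ok) {
    auto f = [&](double aa) { return pll(g, aa, b); };
    double lo, hi;
    bracket1d(f, a, amin, lo, hi);
    double ag = golden(f, lo, hi);
    double lg = pll(g, ag, b);
    if (lg > ll) { a = ag; ll = lg; }
  }
  if (ll_out) *ll_out = ll;
  return a;
}

struct FitOut {
  double a = 0, b = 0, kap = 0, ll = NEG_INF;
  bool conv = false;
};

// moment-style least-squares start for (a, b)
void ls_start(const GroupData &g, bool linear, double &a0, double &b0) {
  double offsum = 0.0;
  for (int i = 0; i < g.G; ++i) offsum += g.off[i];
  // target t_i = y_i / (off_i * N / offsum) - 1 ~ a d + b d^2
  double s11 = 0, s12 = 0, s22 = 0, t1 = 0, t2 = 0;
  for (int i = 0; i < g.G; ++i) {
    double t = g.y[i] * offsum / (g.off[i] * g.N) - 1.0;
    s11 += g.d[i] * g.d[i];
    s12 += g.d[i] * g.d2[i];
    s22 += g.d2[i] * g.d2[i];
    t1 += t * g.d[i];
    t2 += t * g.d2[i];
  }
  if (linear) {
    a0 = (s11 > 0) ? t1 / s11 : 0.0;
    b0 = 0.0;
  } else {
    double det = s11 * s22 - s12 * s12;
    if (std::fabs(det) > 1e-12) {
      a0 = (s22 * t1 - s12 * t2) / det;
      b0 = (s11 * t2 - s12 * t1) / det;
    } else { a0 = 0.0; b0 = 0.0; }
  }
  // pull an infeasible start back toward (0, 0)
  for (int i = 0; i < 60 && !R_finite(pll(g, a0, b0)); ++i) {
    a0 *= 0.5; b0 *= 0.5;
  }
}

FitOut fit_from(const GroupData &g, bool linear, double a0, double b0) {
  FitOut out;
  double a = a0, b = linear ? 0.0 : b0;
  double ll = pll(g, a, b);
  if (!R_finite(ll)) { a = 0.0; b = 0.0; ll = pll(g, a, b); }
  double gr[2], H[3];
  for (int it = 0; it < 200; ++it) {
    grad_hess(g, a, b, gr, H);
    double gnorm = linear ? std::fabs(gr[0])
                          : std::max(std::fabs(gr[0]), std::fabs(gr[1]));
    if (gnorm < 1e-10 * (1.0 + std::fabs(ll))) { out.conv = true; break; }
    double da, db;
    if (linear) {
      db = 0.0;
      da = (H[0] < -1e-300) ? -gr[0] / H[0]
                            : (gr[0] > 0 ? 1.0 : -1.0);
    } else {
      double det = H[0] * H[2] - H[1] * H[1];
      if (det > 0 && H[0] < 0) {
        da = -(H[2] * gr[0] - H[1] * gr[1]) / det;
        db = -(-H[1] * gr[0] + H[0] * gr[1]) / det;
      } else {  // not concave here: steepest ascent
        double sc = 1.0 / std::max(1.0, std::max(std::fabs(gr[0]),
                                                 std::fabs(gr[1])));
        da = gr[0] * sc;
        db = gr[1] * sc;
      }
    }
    double t = 1.0;
    bool moved = false;
    for (int h = 0; h < 60; ++h) {
      double l2 = pll(g, a + t * da, b + t * db);
      if (R_finite(l2) && l2 > ll) {
        a += t * da; b += t * db; ll = l2; moved = true; break;
      }
      t *= 0.5;
    }
    if (!moved) { out.conv = gnorm < 1e-6 * (1.0 + std::fabs(ll)); break; }
  }
  // coordinate polish guards rare non-concave corners
  if (!linear) {
    for (int rep = 0; rep < 2; ++rep) {
      b = max_b_given_a(g, a, b, &ll);
      a = max_a_given_b(g, b, a, &ll);
    }
    grad_hess(g, a, b, gr, H);
    double det = H[0] * H[2] - H[1] * H[1];
    // Newton decrement: the attainable log-likelihood improvement
    double dec = (det > 0 && H[0] < 0)
                     ? 0.5 * (H[2] * gr[0] * gr[0] -
                              2.0 * H[1] * gr[0] * gr[1] +
                              H[0] * gr[1] * gr[1]) / (-det)
                     : R_PosInf;
    out.conv = std::max(std::fabs(gr[0]), std::fabs(gr[1])) <
                   1e-6 * (1.0 + std::fabs(ll)) ||
               std::fabs(dec) < 1e-8 * (1.0 + std::fabs(ll));
  } else {
    auto f = [&](double aa) { return pll(g, aa, 0.0); };
    double amin = NEG_INF;
    for (int i = 0; i < g.G; ++i) {
      if (g.d[i] > 0) amin = std::max(amin, -1.0 / g.d[i]);
    }
    double lo, hi;
    bracket1d(f, a, amin, lo, hi);
    double ag = golden(f, lo, hi);
    if (pll(g, ag, 0.0) > ll) { a = ag; ll = pll(g, a, 0.0); }
    grad_hess(g, a, 0.0, gr, H);
    double dec = (H[0] < 0) ? 0.5 * gr[0] * gr[0] / (-H[0]) : R_PosInf;
    out.conv = std::fabs(gr[0]) < 1e-6 * (1.0 + std::fabs(ll)) ||
               dec < 1e-8 * (1.0 + std::fabs(ll));
  }
  out.a = a; out.b = linear ? 0.0 : b;
  out.ll = pll(g, out.a, out.b, &out.kap);
  return out;
}

FitOut fit_mle_cpp(const GroupData &g, bool linear) {
  double a0, b0;
  ls_start(g, linear, a0, b0);
  FitOut best = fit_from(g, linear, 0.0, 0.0);
  FitOut alt = fit_from(g, linear, a0, b0);
  if (alt.ll > best.ll) best = alt;
  if (!linear) {
    FitOut alt2 = fit_from(g, linear, 1.0, 1.0);
    if (alt2.ll > best.ll) best = alt2;
  }
  return best;
}

// profile log-likelihood of one coefficient (warm starts the nuisance)
double profile_val(const GroupData &g, bool linear, int which, double val,
                   double &warm) {
  if (linear) return pll(g, val, 0.0);
  double ll;
  if (which == 0) warm = max_b_given_a(g, val, warm, &ll);
  else warm = max_a_given_b(g, val, warm, &ll);
  return ll;
}

// one profile-CI endpoint: dir = +1 upper, -1 lower; flag 0 ok / 1 open /
// 2 at the positivity boundary
void ci_endpoint(const GroupData &g, bool linear, int which, double mle,
                 double nuisance_mle, double llhat, double q,
                 int dir, double &end, int &flag) {
  double target = llhat - q / 2.0;
  double warm = nuisance_mle;
  // feasibility bound applies only to the linear alpha (other cases are
  // unbounded because the nuisance coefficient can compensate)
  double bound = NEG_INF;
  if (linear && dir < 0) {
    for (int i = 0; i < g.G; ++i) {
      if (g.d[i] > 0) bound = std::max(bound, -1.0 / g.d[i]);
    }
  }
  double step = std::max(0.25, 0.5 * std::fabs(mle));
  double x = mle, fx = llhat;
  for (int i = 0; i < 300; ++i) {
    double x2 = x + dir * step;
    bool clipped = false;
    if (dir < 0 && R_finite(bound) && x2 <= bound) {
      x2 = bound + 1e-9 * (1.0 + std::fabs(bound));
      clipped = true;
    }
    double f2 = profile_val(g, linear, which, x2, warm);
    if (f2 < target) {
      // bracket found: bisect between x (inside) and x2 (outside)
      double in = x, out = x2;
      for (int j = 0; j < 200; ++j) {
        double mid = 0.5 * (in + out);
        double fm = profile_val(g, linear, which, mid, warm);
        if (fm >= target) in = mid; else out = mid;
        if (std::fabs(out - in) < 1e-10 * (1.0 + std::fabs(mid))) break;
      }
      end = 0.5 * (in + out);
      flag = 0;
      return;
    }
    if (clipped) { end = x2; flag = 2; return; }  // still above threshold
    x = x2; fx = f2;
    step *= 1.7;
    if (std::fabs(x) > 1e7) {
      end = dir > 0 ? R_PosInf : R_NegInf;
      flag = 1;
      return;
    }
  }
  end = dir > 0 ? R_PosInf : R_NegInf;
  flag = 1;
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_fit_batch(NumericVector y, NumericVector off,
                            NumericMatrix D, bool linear, double chisq_q,
                            bool want_ci) {
  int m = D.nrow(), G = D.ncol();
  if (y.size() != G || off.size() != G)
    stop("dose matrix and cohort have mismatched group counts");
  GroupData g = make_data(y, off);
  if (g.N < 1) stop("cohort has no cases");
  NumericMatrix out(m, 13);
  colnames(out) = CharacterVector::create(
      "alpha", "beta", "kappa", "loglik", "conv",
      "alo", "ahi", "aflo", "afhi", "blo", "bhi", "bflo", "bfhi");
  std::vector<double> drow(G);
  for (int k = 0; k < m; ++k) {
    for (int i = 0; i < G; ++i) drow[i] = D(k, i);
    g.set_dose(drow.data());
    FitOut f = fit_mle_cpp(g, linear);
    out(k, 0) = f.a;
    out(k, 1) = linear ? NA_REAL : f.b;
    out(k, 2) = f.kap;
    out(k, 3) = f.ll;
    out(k, 4) = f.conv ? 1.0 : 0.0;
    out(k, 5) = NA_REAL; out(k, 6) = NA_REAL;
    out(k, 9) = NA_REAL; out(k, 10) = NA_REAL;
    out(k, 7) = 0; out(k, 8) = 0; out(k, 11) = 0; out(k, 12) = 0;
    if (want_ci && f.conv) {
      double end; int flag;
      ci_endpoint(g, linear, 0, f.a, f.b, f.ll, chisq_q, -1, end, flag);
      out(k, 5) = end; out(k, 7) = flag;
      ci_endpoint(g, linear, 0, f.a, f.b, f.ll, chisq_q, +1, end, flag);
      out(k, 6) = end; out(k, 8) = flag;
      if (!linear) {
        ci_endpoint(g, linear, 1, f.b, f.a, f.ll, chisq_q, -1, end, flag);
        out(k, 9) = end; out(k, 11) = flag;
        ci_endpoint(g, linear, 1, f.b, f.a, f.ll, chisq_q, +1, end, flag);
        out(k, 10) = end; out(k, 12) = flag;
      }
    }
    if (m > 100 && k % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------------
// quasi-2DMC with BMA: blockwise Metropolis-Hastings over
// (kappa, alpha, beta, lambda_1..lambda_{m-1})

namespace {

struct MixState {
  // per-vector sufficient pieces at the current (a, b)
  std::vector<double> Q, S, ll;   // Q = sum y log r, S = sum off r
  std::vector<double> lam;        // m - 1 free weight parameters
  double a, b, kap;
  double amax, Tsum;              // anchors for sum exp(lt - amax)
  double lmax, Ssum;              // anchors for 1 + sum exp(lam)
  double mix;                     // current mixture log-likelihood
};

// lt_k = lam_k + ll_k (k < m - 1), lt_{m-1} = ll_{m-1}
inline double lt_of(const MixState &st, int k, int m) {
  return (k < m - 1) ? st.lam[k] + st.ll[k] : st.ll[k];
}

void refresh_anchors(MixState &st, int m) {
  st.amax = NEG_INF;
  for (int k = 0; k < m; ++k) st.amax = std::max(st.amax, lt_of(st, k, m));
  st.Tsum = 0.0;
  if (R_finite(st.amax)) {
    for (int k = 0; k < m; ++k) st.Tsum += std::exp(lt_of(st, k, m) - st.amax);
  }
  st.lmax = 0.0;
  for (int k = 0; k < m - 1; ++k) st.lmax = std::max(st.lmax, st.lam[k]);
  st.Ssum = std::exp(-st.lmax);
  for (int k = 0; k < m - 1; ++k) st.Ssum += std::exp(st.lam[k] - st.lmax);
  st.mix = (st.Tsum > 0.0 ? st.amax + std::log(st.Tsum) : NEG_INF) -
           (st.lmax + std::log(st.Ssum));
}

// ll_k at (Q, S, kap)
void fill_ll(MixState &st, double N, int m) {
  double ek = std::exp(st.kap);
  for (int k = 0; k < m; ++k) {
    st.ll[k] = R_finite(st.Q[k]) ? N * st.kap + st.Q[k] - ek * st.S[k]
                                 : NEG_INF;
  }
}

// Q_k, S_k at (a, b); infeasible vectors get Q = -Inf
bool fill_QS(std::vector<double> &Q, std::vector<double> &S,
             const NumericMatrix &D, const GroupData &g,
             double a, double b) {
  int m = D.nrow(), G = D.ncol();
  bool any_ok = false;
  for (int k = 0; k < m; ++k) {
    double q = 0.0, s = 0.0;
    bool ok = true;
    for (int i = 0; i < G; ++i) {
      double d = D(k, i);
      double r = 1.0 + a * d + b * d * d;
      if (r <= 1e-12) { ok = false; break; }
      q += g.y[i] * std::log(r);
      s += g.off[i] * r;
    }
    Q[k] = ok ? q : NEG_INF;
    S[k] = ok ? s : 0.0;
    any_ok = any_ok || ok;
  }
  return any_ok;
}

inline double log_prior(double x, double sd) {
  return -0.5 * x * x / (sd * sd);
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
List cpp_bma_chain(NumericVector y, NumericVector off, NumericMatrix D,
                   bool linear, double prior_sd, double psd_k,
                   double psd_ab, double psd_l, int block,
                   int n_burn, int n_keep,
                   double k0, double a0, double b0, double lam0) {
  int m = D.nrow(), G = D.ncol();
  if (y.size() != G || off.size() != G) stop("shape mismatch");
  GroupData g = make_data(y, off);
  int n_iter = n_burn + n_keep;

  MixState st;
  st.Q.assign(m, 0.0); st.S.assign(m, 0.0); st.ll.assign(m, 0.0);
  st.lam.assign(std::max(m - 1, 0), lam0);
  st.a = a0; st.b = linear ? 0.0 : b0; st.kap = k0;
  if (!fill_QS(st.Q, st.S, D, g, st.a, st.b))
    stop("initial state infeasible for every dose vector");
  fill_ll(st, g.N, m);
  refresh_anchors(st, m);

  NumericMatrix draws(n_keep, 3);
  std::vector<double> p_sum(m, 0.0);
  long acc_k = 0, acc_a = 0, acc_b = 0, acc_blk = 0, n_blk = 0;
  int n_blocks = (m - 1 + block - 1) / block;  // over the m - 1 lambdas

  std::vector<double> Qp(m), Sp(m), llp(m), lam_old(block);

  for (int it = 0; it < n_iter; ++it) {
    // --- (a) dose-response parameters, one at a time: kappa, alpha, beta
    for (int par = 0; par < (linear ? 2 : 3); ++par) {
      double ap = st.a, bp = st.b, kp = st.kap, prior_diff;
      bool theta_changed_ab = false;
      if (par == 0) {
        kp = st.kap + R::rnorm(0.0, psd_k);
        prior_diff = log_prior(kp, prior_sd) - log_prior(st.kap, prior_sd);
      } else if (par == 1) {
        ap = st.a + R::rnorm(0.0, psd_ab);
        prior_diff = log_prior(ap, prior_sd) - log_prior(st.a, prior_sd);
        theta_changed_ab = true;
      } else {
        bp = st.b + R::rnorm(0.0, psd_ab);
        prior_diff = log_prior(bp, prior_sd) - log_prior(st.b, prior_sd);
        theta_changed_ab = true;
      }
      // proposed per-vector log-likelihoods
      bool any_ok;
      if (theta_changed_ab) {
        any_ok = fill_QS(Qp, Sp, D, g, ap, bp);
      } else {
        Qp = st.Q; Sp = st.S;
        any_ok = true;
      }
      double mixp = NEG_INF;
      if (any_ok) {
        double ek = std::exp(kp);
        double am = NEG_INF;
        for (int k = 0; k < m; ++k) {
          llp[k] = R_finite(Qp[k]) ? g.N * kp + Qp[k] - ek * Sp[k] : NEG_INF;
          double lt = (k < m - 1) ? st.lam[k] + llp[k] : llp[k];
          am = std::max(am, lt);
        }
        if (R_finite(am)) {
          double ts = 0.0;
          for (int k = 0; k < m; ++k) {
            double lt = (k < m - 1) ? st.lam[k] + llp[k] : llp[k];
            ts += std::exp(lt - am);
          }
          mixp = am + std::log(ts) - (st.lmax + std::log(st.Ssum));
        }
      }
      double logacc = mixp - st.mix + prior_diff;
      bool accept = R_finite(mixp) &&
                    std::log(R::runif(0.0, 1.0)) < logacc;
      if (accept) {
        st.a = ap; st.b = bp; st.kap = kp;
        st.Q.swap(Qp); st.S.swap(Sp); st.ll.swap(llp);
        refresh_anchors(st, m);
        if (par == 0) ++acc_k; else if (par == 1) ++acc_a; else ++acc_b;
      }
    }

    // --- (b) lambda blocks, one joint accept per block
    for (int bI = 0; bI < n_blocks; ++bI) {
      int s = bI * block;
      int e = std::min(s + block, m - 1);
      ++n_blk;
      double dT = 0.0, dS = 0.0, prior_diff = 0.0;
      bool need_refresh = false;
      for (int k = s; k < e; ++k) {
        lam_old[k - s] = st.lam[k];
        double nl = st.lam[k] + R::rnorm(0.0, psd_l);
        // proposed contributions relative to the current anchors
        double lt_new = nl + st.ll[k];
        if (lt_new - st.amax > 30.0 || nl - st.lmax > 30.0) need_refresh = true;
        dT += std::exp(lt_new - st.amax) -
              std::exp(st.lam[k] + st.ll[k] - st.amax);
        dS += std::exp(nl - st.lmax) - std::exp(st.lam[k] - st.lmax);
        prior_diff += log_prior(nl, prior_sd) - log_prior(st.lam[k], prior_sd);
        st.lam[k] = nl;  // provisional; restored on reject
      }
      if (need_refresh) {
        // re-anchor against the current state, then recompute the deltas
        for (int k = s; k < e; ++k) std::swap(st.lam[k], lam_old[k - s]);
        refresh_anchors(st, m);
        dT = dS = 0.0;
        for (int k = s; k < e; ++k) {
          double nl = lam_old[k - s];  // the proposal
          dT += std::exp(nl + st.ll[k] - st.amax) -
                std::exp(st.lam[k] + st.ll[k] - st.amax);
          dS += std::exp(nl - st.lmax) - std::exp(st.lam[k] - st.lmax);
          std::swap(st.lam[k], lam_old[k - s]);  // proposal back in place
        }
      }
      double Tn = st.Tsum + dT, Sn = st.Ssum + dS;
      double mixp = (Tn > 0.0 && Sn > 0.0)
                        ? st.amax + std::log(Tn) - (st.lmax + std::log(Sn))
                        : NEG_INF;
      double logacc = mixp - st.mix + prior_diff;
      if (R_finite(mixp) && std::log(R::runif(0.0, 1.0)) < logacc) {
        st.Tsum = Tn; st.Ssum = Sn; st.mix = mixp;
        ++acc_blk;
        if (st.Tsum < 1e-10 || st.Ssum < 1e-10) refresh_anchors(st, m);
      } else {
        for (int k = s; k < e; ++k) st.lam[k] = lam_old[k - s];
      }
    }
    refresh_anchors(st, m);  // kill incremental drift once per iteration

    if (it >= n_burn) {
      int t = it - n_burn;
      draws(t, 0) = st.a;
      draws(t, 1) = linear ? NA_REAL : st.b;
      draws(t, 2) = st.kap;
      double inv = 1.0 / (st.Ssum);
      for (int k = 0; k < m - 1; ++k)
        p_sum[k] += std::exp(st.lam[k] - st.lmax) * inv;
      p_sum[m - 1] += std::exp(-st.lmax) * inv;
    }
    if (it % 64 == 0) Rcpp::checkUserInterrupt();
  }

  double n_theta = n_iter;
  NumericVector accept = NumericVector::create(
      acc_k / n_theta, acc_a / n_theta,
      linear ? NA_REAL : acc_b / n_theta,
      n_blk > 0 ? (double)acc_blk / n_blk : NA_REAL);
  NumericVector p_mean(m);
  for (int k = 0; k < m; ++k) p_mean[k] = p_sum[k] / n_keep;
  return List::create(Named("draws") = draws,
                      Named("accept") = accept,
                      Named("p_mean") = p_mean);
}
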