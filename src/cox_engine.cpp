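// Cox proportional-hazards engine: Newton-Raphson maximization of the
// Efron (or Breslow) tie-corrected partial likelihood, plus a bootstrap
// cutoff-scan driver that reuses the same core at high throughput.
//
// Conventions: data are sorted by ascending time internally; covariate
// columns are mean-centered before iteration (beta is unaffected, the
// exponentials stay in range); convergence is sup-norm of the score < tol;
// |beta| escaping `bound` flags divergence (separation) instead of
// returning a silent estimate.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct LGH {
  double loglik;
  arma::vec grad;
  arma::mat info;   // negative Hessian (observed information)
  bool ok;
};

// Xt is p x n (one contiguous column per subject); data sorted by
// ascending time. Raw accumulation loops: this kernel runs ~10^6 times
// inside the bootstrap scan.
LGH cox_lgh(const arma::vec& time, const arma::ivec& status,
            const arma::mat& Xt, const arma::vec& beta, bool efron) {
  const arma::uword n = Xt.n_cols, p = Xt.n_rows;
  LGH out;
  out.loglik = 0.0;
  out.grad = arma::zeros(p);
  out.info = arma::zeros(p, p);
  out.ok = true;

  std::vector<double> S1(p, 0.0), s1d(p), xsum(p), D1(p);
  std::vector<double> S2(p * p, 0.0), s2d(p * p);
  double* g = out.grad.memptr();
  double* I = out.info.memptr();
  double S0 = 0.0;

  arma::sword i = static_cast<arma::sword>(n) - 1;
  while (i >= 0) {
    const double t = time(static_cast<arma::uword>(i));
    arma::sword j = i;
    while (j >= 0 && time(static_cast<arma::uword>(j)) == t) --j;
    const arma::sword j0 = j + 1;

    double s0d = 0.0, etasum = 0.0;
    std::fill(s1d.begin(), s1d.end(), 0.0);
    std::fill(s2d.begin(), s2d.end(), 0.0);
    std::fill(xsum.begin(), xsum.end(), 0.0);
    int d = 0;

    for (arma::sword k = j0; k <= i; ++k) {
      const arma::uword u = static_cast<arma::uword>(k);
      const double* x = Xt.colptr(u);
      double eta = 0.0;
      for (arma::uword a = 0; a < p; ++a) eta += x[a] * beta(a);
      if (eta > 500.0) eta = 500.0;
      if (eta < -500.0) eta = -500.0;
      const double wk = std::exp(eta);
      S0 += wk;
      for (arma::uword a = 0; a < p; ++a) {
        S1[a] += wk * x[a];
        for (arma::uword b = 0; b <= a; ++b) S2[a * p + b] += wk * x[a] * x[b];
      }
      if (status(u) == 1) {
        ++d;
        s0d += wk;
        etasum += eta;
        for (arma::uword a = 0; a < p; ++a) {
          s1d[a] += wk * x[a];
          xsum[a] += x[a];
          for (arma::uword b = 0; b <= a; ++b)
            s2d[a * p + b] += wk * x[a] * x[b];
        }
      }
    }

    if (d > 0) {
      out.loglik += etasum;
      for (arma::uword a = 0; a < p; ++a) g[a] += xsum[a];
      for (int l = 0; l < d; ++l) {
        const double r = efron ? static_cast<double>(l) / d : 0.0;
        const double D0 = S0 - r * s0d;
        if (!(D0 > 0.0) || !std::isfinite(D0)) { out.ok = false; return out; }
        const double inv0 = 1.0 / D0;
        out.loglik -= std::log(D0);
        for (arma::uword a = 0; a < p; ++a) D1[a] = S1[a] - r * s1d[a];
        for (arma::uword a = 0; a < p; ++a) {
          g[a] -= D1[a] * inv0;
          for (arma::uword b = 0; b <= a; ++b)
            I[b * p + a] += (S2[a * p + b] - r * s2d[a * p + b]) * inv0 -
                            D1[a] * D1[b] * inv0 * inv0;
        }
      }
    }
    i = j;
  }
  // symmetrize (lower triangle accumulated into I[b*p+a], a >= b)
  for (arma::uword a = 0; a < p; ++a)
    for (arma::uword b = 0; b < a; ++b) out.info(b, a) = out.info(a, b);
  if (!std::isfinite(out.loglik)) out.ok = false;
  return out;
}

struct FitResult {
  arma::vec beta;
  arma::mat var;
  double loglik0, loglik, score_max;
  int iter;
  bool converged, singular;
};

// Newton-Raphson with step-halving. Sorted input required; Xt is p x n.
FitResult cox_newton(const arma::vec& time, const arma::ivec& status,
                     const arma::mat& Xt, bool efron, int maxit, double tol,
                     double bound) {
  const arma::uword p = Xt.n_rows;
  FitResult res;
  res.beta = arma::zeros(p);
  res.var = arma::mat(p, p, arma::fill::value(NA_REAL));
  res.iter = 0;
  res.converged = false;
  res.singular = false;

  LGH cur = cox_lgh(time, status, Xt, res.beta, efron);
  res.loglik0 = cur.loglik;
  res.loglik = cur.loglik;
  if (!cur.ok) { res.singular = true; res.score_max = NA_REAL; return res; }

  for (int it = 1; it <= maxit; ++it) {
    res.iter = it - 1;
    if (arma::abs(cur.grad).max() < tol) { res.converged = true; break; }

    arma::vec step;
    bool solved = arma::solve(step, cur.info, cur.grad,
                              arma::solve_opts::no_approx);
    if (!solved || !step.is_finite()) { res.singular = true; break; }

    arma::vec beta_new = res.beta + step;
    LGH nxt = cox_lgh(time, status, Xt, beta_new, efron);
    int halvings = 0;
    while ((!nxt.ok || nxt.loglik < cur.loglik - 1e-10) && halvings < 30) {
      step *= 0.5;
      beta_new = res.beta + step;
      nxt = cox_lgh(time, status, Xt, beta_new, efron);
      ++halvings;
    }
    if (!nxt.ok) { res.singular = true; break; }
    res.beta = beta_new;
    cur = nxt;
    res.loglik = cur.loglik;
    res.iter = it;
    if (arma::abs(res.beta).max() > bound) { res.converged = false; break; }
  }
  if (!res.singular && arma::abs(cur.grad).max() < tol &&
      arma::abs(res.beta).max() <= bound)
    res.converged = true;
  res.score_max = cur.ok ? arma::abs(cur.grad).max() : NA_REAL;

  arma::mat v;
  if (!res.singular && arma::inv_sympd(v, cur.info)) {
    res.var = v;
  } else if (!res.singular) {
    bool invok = arma::inv(v, cur.info);
    if (invok) res.var = v; else res.singular = true;
  }
  return res;
}

arma::uvec order_by_time(const arma::vec& time) {
  return arma::stable_sort_index(time, "ascend");
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cox_fit_cpp")]]
List cox_fit_cpp(NumericVector time, IntegerVector status, NumericMatrix X,
                 bool efron = true, int maxit = 100, double tol = 1e-7,
                 double bound = 15.0) {
  arma::vec t(time.begin(), time.size(), false);
  arma::ivec s(status.begin(), status.size(), false);
  arma::mat x(X.begin(), X.nrow(), X.ncol(), false);

  arma::uvec ord = order_by_time(t);
  arma::vec ts = t(ord);
  arma::ivec ss = s(ord);
  arma::mat xs = x.rows(ord);

  // mean-center columns (invariant for beta, stabilizes exponentials)
  arma::rowvec mu = arma::mean(xs, 0);
  xs.each_row() -= mu;

  FitResult res = cox_newton(ts, ss, xs.t(), efron, maxit, tol, bound);
  return List::create(
      _["beta"] = NumericVector(res.beta.begin(), res.beta.end()),
      _["var"] = wrap(res.var),
      _["loglik_null"] = res.loglik0,
      _["loglik"] = res.loglik,
      _["iterations"] = res.iter,
      _["converged"] = res.converged,
      _["singular"] = res.singular,
      _["score_max"] = res.score_max,
      _["n"] = (int)ts.n_elem,
      _["n_events"] = (int)arma::accu(ss == 1));
}

// Bootstrap cutoff scan: B resamples with replacement; every candidate
// cutoff is evaluated on the SAME B resampled cohorts. For each resample
// and cutoff the model is marker-high indicator + fixed covariate columns;
// the marker term's Wald p < alpha is tallied. Resample draws use R's RNG,
// so set.seed() upstream makes the scan reproducible.
//' @noRd
// [[Rcpp::export(name = ".cutoff_scan_cpp")]]
IntegerMatrix cutoff_scan_cpp(NumericVector time, IntegerVector status,
                              NumericMatrix Z, NumericVector marker,
                              NumericVector cutoffs, int B, bool efron = true,
                              int maxit = 100, double tol = 1e-7,
                              double bound = 15.0, double alpha = 0.05) {
  const int n = time.size();
  const int q = Z.ncol();
  const int C = cutoffs.size();
  arma::vec t0(time.begin(), n, false);
  arma::ivec s0(status.begin(), n, false);
  arma::mat z0(Z.begin(), n, q, false);
  arma::vec m0(marker.begin(), n, false);

  IntegerMatrix out(C, 2); // columns: n_significant, n_failed

  arma::vec tb(n);
  arma::ivec sb(n);
  arma::mat zb(n, q);
  arma::vec mb(n);
  arma::mat Xt(q + 1, n);

  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) {
      int k = static_cast<int>(unif_rand() * n);
      if (k == n) k = n - 1;
      tb(i) = t0(k);
      sb(i) = s0(k);
      mb(i) = m0(k);
      if (q > 0) zb.row(i) = z0.row(k);
    }
    arma::uvec ord = order_by_time(tb);
    arma::vec ts = tb(ord);
    arma::ivec ss = sb(ord);
    arma::vec ms = mb(ord);
    if (q > 0) {
      arma::mat zs = zb.rows(ord);
      arma::rowvec mu = arma::mean(zs, 0);
      zs.each_row() -= mu;
      Xt.rows(1, q) = zs.t();
    }

    const bool any_event = arma::any(ss == 1);

    for (int c = 0; c < C; ++c) {
      if (!any_event) { out(c, 1) += 1; continue; }
      const double cut = cutoffs[c];
      int nh = 0;
      for (int i = 0; i < n; ++i) {
        const double hi = (ms(i) > cut) ? 1.0 : 0.0;
        Xt(0, i) = hi;
        nh += (hi > 0.5);
      }
      if (nh == 0 || nh == n) { out(c, 1) += 1; continue; }
      const double mu0 = static_cast<double>(nh) / n;
      for (int i = 0; i < n; ++i) Xt(0, i) -= mu0;

      FitResult res = cox_newton(ts, ss, Xt, efron, maxit, tol, bound);
      if (!res.converged || res.singular || !std::isfinite(res.var(0, 0)) ||
          res.var(0, 0) <= 0.0) {
        out(c, 1) += 1;
        continue;
      }
      const double zstat = res.beta(0) / std::sqrt(res.var(0, 0));
      const double pval = 2.0 * R::pnorm(-std::fabs(zstat), 0.0, 1.0, 1, 0);
      if (pval < alpha) out(c, 0) += 1;
    }
  }
  return out;
}
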