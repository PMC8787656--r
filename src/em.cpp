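#include <Rcpp.h>
using namespace Rcpp;

// EM for a finite Gaussian mixture with diagonal (conditionally
// independent) components. Variances are either class-invariant
// (equal_var = true; sigma2 rows kept identical) or class-varying.
// Responsibilities are computed on the log scale with log-sum-exp.
// Convergence uses Aitken acceleration on the log-likelihood
// sequence (the usual stopping rule for mixture EM, which detects
// the asymptote of slow geometric convergence early), falling back
// to the plain absolute-change criterion.
//
// Returns parameter estimates, the log-likelihood trace, the
// posterior matrix matching the returned parameters, and flags for
// convergence, variance-floor activation and component degeneracy
// (an effective class count below one observation).
// [[Rcpp::export]]
List cpp_em(NumericMatrix X, NumericVector w0, NumericMatrix mu0,
            NumericMatrix s20, bool equal_var, int max_iter, double tol,
            double var_floor) {
  const int n = X.nrow(), J = X.ncol(), K = w0.size();
  NumericVector w = clone(w0);
  NumericMatrix mu = clone(mu0), s2 = clone(s20);
  NumericMatrix R(n, K);
  double *rp = REAL(R), *wp = REAL(w), *mup = REAL(mu), *s2p = REAL(s2);
  // row-contiguous copy of the data: xt[i*J + j]
  std::vector<double> xt((size_t)n * J);
  for (int j = 0; j < J; ++j) {
    const double *col = REAL(X) + (size_t)j * n;
    for (int i = 0; i < n; ++i) xt[(size_t)i * J + j] = col[i];
  }
  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  bool converged = false, floored = false, degenerate = false;
  double ll = R_NegInf, llm1 = R_NegInf, llm2 = R_NegInf;
  const double LOG2PI = std::log(2.0 * M_PI);

  std::vector<double> cst(K), inv2((size_t)K * J), logd(K), Nk(K);

  auto estep = [&]() -> double {
    for (int k = 0; k < K; ++k) {
      double c = std::log(wp[k]);
      for (int j = 0; j < J; ++j) {
        c += -0.5 * (LOG2PI + std::log(s2p[k + (size_t)j * K]));
        inv2[(size_t)k * J + j] = 0.5 / s2p[k + (size_t)j * K];
      }
      cst[k] = c;
    }
    double total = 0.0;
    for (int i = 0; i < n; ++i) {
      const double *xi = &xt[(size_t)i * J];
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double q = cst[k];
        const double *iv = &inv2[(size_t)k * J];
        for (int j = 0; j < J; ++j) {
          double d = xi[j] - mup[k + (size_t)j * K];
          q -= d * d * iv[j];
        }
        logd[k] = q;
        if (q > m) m = q;
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double e = std::exp(logd[k] - m);
        rp[i + (size_t)k * n] = e;
        s += e;
      }
      total += m + std::log(s);
      double inv = 1.0 / s;
      for (int k = 0; k < K; ++k) rp[i + (size_t)k * n] *= inv;
    }
    return total;
  };

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    ll = estep();
    trace.push_back(ll);
    if (iter > 0) {
      double dll = ll - llm1;
      bool stop_now = std::fabs(dll) < tol;
      if (!stop_now && iter > 1) {
        double denom = llm1 - llm2;
        if (denom > 0.0 && dll > 0.0) {
          double a = dll / denom;              // Aitken ratio
          if (a < 1.0) {
            double ll_inf = llm1 + dll / (1.0 - a);
            stop_now = std::fabs(ll_inf - ll) < tol;
          }
        }
      }
      if (stop_now) { converged = true; break; }
    }
    llm2 = llm1; llm1 = ll;

    // M-step
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      const double *rk = rp + (size_t)k * n;
      for (int i = 0; i < n; ++i) s += rk[i];
      Nk[k] = s;
      if (s < 1.0) degenerate = true;
    }
    if (degenerate) break;
    for (int k = 0; k < K; ++k) {
      wp[k] = Nk[k] / n;
      const double *rk = rp + (size_t)k * n;
      for (int j = 0; j < J; ++j) {
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += rk[i] * xt[(size_t)i * J + j];
        mup[k + (size_t)j * K] = s / Nk[k];
      }
    }
    if (equal_var) {
      for (int j = 0; j < J; ++j) {
        double s = 0.0;
        for (int k = 0; k < K; ++k) {
          const double *rk = rp + (size_t)k * n;
          double m = mup[k + (size_t)j * K];
          for (int i = 0; i < n; ++i) {
            double d = xt[(size_t)i * J + j] - m;
            s += rk[i] * d * d;
          }
        }
        double v = s / n;
        if (v < var_floor) { v = var_floor; floored = true; }
        for (int k = 0; k < K; ++k) s2p[k + (size_t)j * K] = v;
      }
    } else {
      for (int k = 0; k < K; ++k) {
        const double *rk = rp + (size_t)k * n;
        for (int j = 0; j < J; ++j) {
          double s = 0.0, m = mup[k + (size_t)j * K];
          for (int i = 0; i < n; ++i) {
            double d = xt[(size_t)i * J + j] - m;
            s += rk[i] * d * d;
          }
          double v = s / Nk[k];
          if (v < var_floor) { v = var_floor; floored = true; }
          s2p[k + (size_t)j * K] = v;
        }
      }
    }
  }
  if (!converged && !degenerate && iter == max_iter) {
    // sync posterior/log-likelihood with the final parameter values
    ll = estep();
    trace.push_back(ll);
  }

  return List::create(_["weights"] = w, _["means"] = mu, _["sigma2"] = s2,
                      _["loglik"] = ll,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["iterations"] = (int)trace.size(),
                      _["converged"] = converged, _["floored"] = floored,
                      _["degenerate"] = degenerate, _["posterior"] = R);
}
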