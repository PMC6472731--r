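#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo marginal probability of a "target present" response.
//
// S, sig_true: n x N stimulus and true-noise-SD matrices.
// Z: (n * m) x N standard-normal draws, trial-major (row = t + n * j).
// coef: n x N evidence coefficients 2 * mu / (sig_assumed^2 + sext^2)
//   (Bayesian-family rules only).
// rule: 0 pooled Bayesian evidence, 1 max, 2 min deviation,
//   3 Minkowski, 4 mean, 5 variance.
// pcore: 0 deterministic threshold, 1 probit (late noise),
//   2 binomial posterior-sampling vote.
// Ties at the threshold count as "absent".
// [[Rcpp::export(name = ".mc_present_prob_cpp")]]
NumericVector mc_present_prob(const NumericMatrix& S,
                              const NumericMatrix& Z,
                              const NumericMatrix& sig_true,
                              const NumericMatrix& coef,
                              const int rule,
                              const double mu_target,
                              const double beta,
                              const int pcore,
                              const int direction,
                              const double threshold,
                              const double mu_late,
                              const double sigma_late,
                              const int n_samples) {
  const int n = S.nrow(), N = S.ncol();
  const int m = Z.nrow() / n;
  NumericVector out(n);
  std::vector<double> x(N), a(N);
  const double logN = std::log((double) N);
  // draws outer, trials inner: row t + n * j is then sequential in Z
  for (int j = 0; j < m; ++j) {
    for (int t = 0; t < n; ++t) {
      const int r = t + n * j;
      for (int i = 0; i < N; ++i) x[i] = S(t, i) + sig_true(t, i) * Z(r, i);
      double d;
      switch (rule) {
        case 0: {
          double mx = R_NegInf;
          for (int i = 0; i < N; ++i) {
            a[i] = coef(t, i) * x[i];
            if (a[i] > mx) mx = a[i];
          }
          // sign-only shortcut for the deterministic Bayesian rule:
          // exp(mx) <= sum exp(a_i) <= N exp(mx), so d = log(mean) is
          // negative whenever mx <= 0 and positive whenever mx > log N
          if (pcore == 0) {
            if (mx <= 0.0) { d = -1.0; break; }
            if (mx > logN) { d = 1.0; break; }
          }
          double s = 0.0;
          for (int i = 0; i < N; ++i) s += std::exp(a[i] - mx);
          d = mx + std::log(s / N);
        } break;
        case 1: {
          d = x[0];
          for (int i = 1; i < N; ++i) if (x[i] > d) d = x[i];
        } break;
        case 2: {
          d = std::fabs(x[0] - mu_target);
          for (int i = 1; i < N; ++i) {
            double v = std::fabs(x[i] - mu_target);
            if (v < d) d = v;
          }
        } break;
        case 3: {
          double s = 0.0;
          for (int i = 0; i < N; ++i)
            s += std::pow(std::fabs(x[i] - mu_target), beta);
          d = std::pow(s, 1.0 / beta);
        } break;
        case 4: {
          double s = 0.0;
          for (int i = 0; i < N; ++i) s += x[i];
          d = s / N;
        } break;
        default: {
          double s = 0.0;
          for (int i = 0; i < N; ++i) s += x[i];
          const double mb = s / N;
          double v = 0.0;
          for (int i = 0; i < N; ++i) {
            const double e = x[i] - mb;
            v += e * e;
          }
          d = v / N;  // population 1/N convention
        } break;
      }
      double p;
      if (pcore == 0) {
        p = (direction * (d - threshold) > 0) ? 1.0 : 0.0;
      } else if (pcore == 1) {
        p = R::pnorm(direction * (d + mu_late - threshold) / sigma_late,
                     0.0, 1.0, 1, 0);
      } else {
        const double p1 = 1.0 / (1.0 + std::exp(-d));
        p = 1.0 - R::pbinom(std::floor(n_samples / 2.0), n_samples, p1, 1, 0);
        if (n_samples % 2 == 0)
          p += 0.5 * R::dbinom(n_samples / 2, n_samples, p1, 0);
      }
      out[t] += p;
    }
  }
  for (int t = 0; t < n; ++t) out[t] /= m;
  return out;
}
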