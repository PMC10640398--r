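#include <Rcpp.h>
using namespace Rcpp;

// Core likelihood/gradient kernel for the marker-informed NB mixture.
//
// Mean model:        log mu_igk = log s_i + delta_gk * rho_gk + beta_g0 + sum_p beta_gp x_ip
// Dispersion model:  phi_igk = max(sum_j a_j exp(-b_j (mu_igk - x_j)^2), PHI_FLOOR)
// NB convention:     Var = mu + mu^2 / phi  (phi = inverse dispersion / size)
//
// Positivity via reparameterization: delta = exp(delta_raw), a = softplus(a_raw),
// b = softplus(b_raw). Gradients returned on the raw scale.

static const double PHI_FLOOR = 1e-6;

static inline double softplus(double x) {
  return x > 30.0 ? x : log1p(exp(x));
}

static inline double sigmoid(double x) {
  return x >= 0.0 ? 1.0 / (1.0 + exp(-x)) : exp(x) / (1.0 + exp(x));
}

// digamma via argument-shift plus the standard asymptotic series (absolute
// error well below 1e-12 for the shifted argument >= 8)
static inline double fast_digamma(double x) {
  double acc = 0.0;
  while (x < 8.0) { acc -= 1.0 / x; x += 1.0; }
  const double inv = 1.0 / x, inv2 = inv * inv;
  return acc + log(x) - 0.5 * inv -
    inv2 * (1.0 / 12.0 - inv2 * (1.0 / 120.0 - inv2 * (1.0 / 252.0 - inv2 / 240.0)));
}

// log NB(y | mu, phi) pieces that involve the Gamma function, and the
// corresponding digamma difference, via the rising-factorial recurrence for
// small counts (exact, avoids lgamma/digamma calls):
//   lgamma(y+phi) - lgamma(phi) - lgamma(y+1) = sum_{m=0}^{y-1} log((phi+m)/(m+1))
//   digamma(y+phi) - digamma(phi)            = sum_{m=0}^{y-1} 1/(phi+m)
static inline void gamma_terms(double y, double phi, bool want_grad,
                               double &lg, double &dg) {
  lg = 0.0; dg = 0.0;
  if (y <= 0.5) return;
  if (y <= 8.5) {
    int yi = (int)(y + 0.5);
    for (int m = 0; m < yi; ++m) {
      lg += log((phi + m) / (m + 1.0));
      if (want_grad) dg += 1.0 / (phi + m);
    }
  } else {
    lg = std::lgamma(y + phi) - std::lgamma(phi) - std::lgamma(y + 1.0);
    if (want_grad) dg = fast_digamma(y + phi) - fast_digamma(phi);
  }
}

// Weighted data log-likelihood sum_{i,k} gamma_ik sum_g log NB(y_ig | mu_igk, phi_igk)
// and, if want_grad, its gradient w.r.t. delta_raw, beta0, beta, a_raw, b_raw.
// [[Rcpp::export]]
List nb_weighted_loglik(const NumericMatrix &Y,      // N x G counts
                        const NumericVector &s,      // N size factors
                        const NumericMatrix &X,      // N x P covariates (P may be 0)
                        const NumericMatrix &delta_raw, // G x K
                        const NumericVector &beta0,  // G
                        const NumericMatrix &beta,   // G x P
                        const NumericVector &a_raw,  // B
                        const NumericVector &b_raw,  // B
                        const NumericVector &centers,// B
                        const NumericMatrix &rho,    // G x K (0/1)
                        const NumericMatrix &gamma,  // N x K weights
                        bool want_grad) {
  const int N = Y.nrow(), G = Y.ncol(), K = delta_raw.ncol(), P = X.ncol();
  const int B = a_raw.size();

  std::vector<double> a(B), b(B), sig_a(B), sig_b(B);
  for (int j = 0; j < B; ++j) {
    a[j] = softplus(a_raw[j]);
    b[j] = softplus(b_raw[j]);
    sig_a[j] = sigmoid(a_raw[j]);
    sig_b[j] = sigmoid(b_raw[j]);
  }

  std::vector<double> logs(N);
  for (int i = 0; i < N; ++i) {
    if (!(s[i] > 0.0)) stop("size factors must be strictly positive");
    logs[i] = log(s[i]);
  }

  NumericMatrix g_delta(G, K), g_beta(G, std::max(P, 1));
  NumericVector g_beta0(G), g_a(B), g_b(B);
  std::vector<double> ej(B), tj(B);

  double total = 0.0;
  for (int k = 0; k < K; ++k) {
    for (int g = 0; g < G; ++g) {
      const double d_raw = delta_raw(g, k);
      const double delta = exp(d_raw);
      const double r = rho(g, k);
      const double base = delta * r + beta0[g];
      double acc_d = 0.0, acc_b0 = 0.0;
      for (int i = 0; i < N; ++i) {
        const double w = gamma(i, k);
        if (w < 1e-15 && w > -1e-15) continue;
        double lmu = logs[i] + base;
        if (P > 0) for (int p = 0; p < P; ++p) lmu += beta(g, p) * X(i, p);
        const double mu = exp(lmu);
        // RBF dispersion
        double phi = 0.0, dphidmu = 0.0;
        for (int j = 0; j < B; ++j) {
          const double t = mu - centers[j];
          const double e = exp(-b[j] * t * t);
          ej[j] = e; tj[j] = t;
          phi += a[j] * e;
          dphidmu += a[j] * e * (-2.0 * b[j] * t);
        }
        bool floored = false;
        if (phi < PHI_FLOOR) { phi = PHI_FLOOR; dphidmu = 0.0; floored = true; }

        const double y = Y(i, g);
        double lg, dgm;
        gamma_terms(y, phi, want_grad, lg, dgm);
        const double lpm = log(phi + mu);
        const double lphi = log(phi);
        const double lp = lg + phi * (lphi - lpm) + (y > 0.5 ? y * (lmu - lpm) : 0.0);
        total += w * lp;

        if (want_grad) {
          const double rinv = 1.0 / (phi + mu);
          const double dlmu = y / mu - (y + phi) * rinv;        // d logp / d mu
          const double dlphi = dgm + (lphi - lpm) + (mu - y) * rinv; // d logp / d phi
          const double dmu_tot = w * (dlmu + dlphi * dphidmu) * mu;  // chain through phi(mu); * dmu/dlmu
          acc_b0 += dmu_tot;
          if (r != 0.0) acc_d += dmu_tot;
          if (P > 0) for (int p = 0; p < P; ++p) g_beta(g, p) += dmu_tot * X(i, p);
          if (!floored) {
            const double wphi = w * dlphi;
            for (int j = 0; j < B; ++j) {
              g_a[j] += wphi * ej[j] * sig_a[j];
              g_b[j] += wphi * a[j] * ej[j] * (-tj[j] * tj[j]) * sig_b[j];
            }
          }
        }
      }
      if (want_grad) {
        g_beta0[g] += acc_b0;
        g_delta(g, k) += acc_d * delta; // d delta / d delta_raw = delta
      }
    }
  }

  if (!R_finite(total)) stop("non-finite log-likelihood encountered");
  if (!want_grad) return List::create(_["value"] = total);
  return List::create(_["value"] = total,
                      _["g_delta_raw"] = g_delta,
                      _["g_beta0"] = g_beta0,
                      _["g_beta"] = g_beta,
                      _["g_a_raw"] = g_a,
                      _["g_b_raw"] = g_b);
}

// Per-spot per-type NB log-likelihood matrix: L_ik = sum_g log NB(y_ig | mu_igk, phi_igk).
// [[Rcpp::export]]
NumericMatrix nb_loglik_matrix(const NumericMatrix &Y,
                               const NumericVector &s,
                               const NumericMatrix &X,
                               const NumericMatrix &delta_raw,
                               const NumericVector &beta0,
                               const NumericMatrix &beta,
                               const NumericVector &a_raw,
                               const NumericVector &b_raw,
                               const NumericVector &centers,
                               const NumericMatrix &rho) {
  const int N = Y.nrow(), G = Y.ncol(), K = delta_raw.ncol(), P = X.ncol();
  const int B = a_raw.size();

  std::vector<double> a(B), b(B);
  for (int j = 0; j < B; ++j) { a[j] = softplus(a_raw[j]); b[j] = softplus(b_raw[j]); }
  std::vector<double> logs(N);
  for (int i = 0; i < N; ++i) {
    if (!(s[i] > 0.0)) stop("size factors must be strictly positive");
    logs[i] = log(s[i]);
  }

  NumericMatrix L(N, K);
  for (int k = 0; k < K; ++k) {
    for (int g = 0; g < G; ++g) {
      const double base = exp(delta_raw(g, k)) * rho(g, k) + beta0[g];
      for (int i = 0; i < N; ++i) {
        double lmu = logs[i] + base;
        if (P > 0) for (int p = 0; p < P; ++p) lmu += beta(g, p) * X(i, p);
        const double mu = exp(lmu);
        double phi = 0.0;
        for (int j = 0; j < B; ++j) {
          const double t = mu - centers[j];
          phi += a[j] * exp(-b[j] * t * t);
        }
        if (phi < PHI_FLOOR) phi = PHI_FLOOR;
        const double y = Y(i, g);
        double lg, dgm;
        gamma_terms(y, phi, false, lg, dgm);
        const double lpm = log(phi + mu);
        L(i, k) += lg + phi * (log(phi) - lpm) + (y > 0.5 ? y * (lmu - lpm) : 0.0);
      }
    }
  }
  return L;
}
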