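#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Marginal log-likelihood (and analytic gradient) of the two-class
// engagement mixture IRT model, integrated over (theta[, psi]) by
// Gauss-Hermite quadrature.
//
// Unconstrained parameterization (order of the gradient vector):
//   beta[1..J]                item difficulties
//   lvt                       log Var(theta)          (only if vt_free)
//   coefs[1..K]               engagement-regression coefficients for the
//                             columns of X (intercept, item dummies,
//                             covariates, interactions)                (only if has_mix)
//   lsig, zrho                log Var(psi), atanh(corr(psi, theta))    (only if has_psi)
//   lz                        logit shared guessing probability        (only if zfree)
//
// Quadrature: theta = sd_t * u1[a]; psi = sd_p * (rho*u1[a] + sqrt(1-rho^2)*u2[b]).
// Encounters must be sorted by person; pidx/jidx are 0-based.

static inline double logistic(double x) {
  if (x >= 0.0) { double e = std::exp(-x); return 1.0 / (1.0 + e); }
  double e = std::exp(x); return e / (1.0 + e);
}

static const double P_FLOOR = 1e-12;

// [[Rcpp::export]]
List dlc_mll_cpp(NumericVector beta,
                 double lvt, bool vt_free, double vt_fixed,
                 NumericVector coefs, bool has_mix,
                 bool has_psi, double lsig, double zrho,
                 bool zfree, double lz,
                 IntegerVector pidx, IntegerVector jidx, IntegerVector y,
                 NumericVector zvec, NumericMatrix X,
                 NumericVector u1, NumericVector w1,
                 NumericVector u2, NumericVector w2,
                 bool want_grad) {
  const int J = beta.size();
  const int K = has_mix ? coefs.size() : 0;
  const int nEnc = pidx.size();
  const int A = u1.size();
  const int B = has_psi ? u2.size() : 1;
  const int Q = A * B;

  int nPers = 0;
  for (int e = 0; e < nEnc; ++e) if (pidx[e] + 1 > nPers) nPers = pidx[e] + 1;

  const double sd_t = vt_free ? std::exp(lvt / 2.0) : std::sqrt(vt_fixed);
  double sd_p = 0.0, rho = 0.0, sq = 1.0;
  if (has_psi) {
    sd_p = std::exp(lsig / 2.0);
    rho = std::tanh(zrho);
    sq = std::sqrt(std::max(1.0 - rho * rho, 0.0));
  }
  const double zf = zfree ? logistic(lz) : 0.0;

  // node geometry
  std::vector<double> theta(A), wq(Q), psi(Q), dpsi_zrho(Q);
  for (int a = 0; a < A; ++a) theta[a] = sd_t * u1[a];
  for (int a = 0; a < A; ++a) {
    for (int b = 0; b < B; ++b) {
      int q = a * B + b;
      wq[q] = w1[a] * (has_psi ? w2[b] : 1.0);
      if (has_psi) {
        psi[q] = sd_p * (rho * u1[a] + sq * u2[b]);
        dpsi_zrho[q] = sd_p * ((1.0 - rho * rho) * u1[a] - rho * sq * u2[b]);
      } else {
        psi[q] = 0.0;
        dpsi_zrho[q] = 0.0;
      }
    }
  }

  // Rasch success probability table, item x theta-node
  std::vector<double> p1tab((size_t)J * A);
  for (int j = 0; j < J; ++j)
    for (int a = 0; a < A; ++a)
      p1tab[(size_t)j * A + a] = logistic(theta[a] - beta[j]);

  // linear predictors (without psi); clamped so that the factored
  // exponentials below cannot overflow while pi saturates far beyond the
  // probability floor
  std::vector<double> eta(nEnc, 0.0), Eeta(nEnc, 1.0);
  std::vector<double> Epsi(Q, 1.0);
  if (has_mix) {
    for (int e = 0; e < nEnc; ++e) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += X(e, k) * coefs[k];
      if (s > 200.0) s = 200.0; else if (s < -200.0) s = -200.0;
      eta[e] = s;
      Eeta[e] = std::exp(-s);
    }
    for (int q = 0; q < Q; ++q) {
      double p = psi[q];
      if (p > 200.0) p = 200.0; else if (p < -200.0) p = -200.0;
      Epsi[q] = std::exp(-p);
    }
  }

  std::vector<double> Ps((size_t)nEnc * Q);
  std::vector<double> Pi(has_mix && want_grad ? (size_t)nEnc * Q : (size_t)1);
  std::vector<double> prodq(Q), Wn((size_t)nPers * Q, 0.0);

  double ll = 0.0;
  int e0 = 0;
  while (e0 < nEnc) {
    int person = pidx[e0];
    int e1 = e0;
    while (e1 < nEnc && pidx[e1] == person) ++e1;
    for (int q = 0; q < Q; ++q) prodq[q] = wq[q];
    for (int e = e0; e < e1; ++e) {
      const int j = jidx[e];
      const int yv = y[e];
      const double z = zfree ? zf : zvec[e];
      const double zy = yv ? z : 1.0 - z;
      const double Ee = Eeta[e];
      for (int a = 0; a < A; ++a) {
        const double p1 = p1tab[(size_t)j * A + a];
        const double py = yv ? p1 : 1.0 - p1;
        for (int b = 0; b < B; ++b) {
          const int q = a * B + b;
          double P;
          if (has_mix) {
            const double pi = 1.0 / (1.0 + Ee * Epsi[q]);
            P = pi * py + (1.0 - pi) * zy;
            if (want_grad) Pi[(size_t)e * Q + q] = pi;
          } else {
            P = py;
          }
          if (P < P_FLOOR) P = P_FLOOR;
          Ps[(size_t)e * Q + q] = P;
          prodq[q] *= P;
        }
      }
    }
    double Li = 0.0;
    for (int q = 0; q < Q; ++q) Li += prodq[q];
    if (Li <= 0.0 || !std::isfinite(Li)) {
      return List::create(_["loglik"] = R_NegInf,
                          _["grad"] = R_NilValue);
    }
    ll += std::log(Li);
    for (int q = 0; q < Q; ++q) Wn[(size_t)person * Q + q] = prodq[q] / Li;
    e0 = e1;
  }

  if (!want_grad) {
    return List::create(_["loglik"] = ll, _["grad"] = R_NilValue);
  }

  NumericVector gbeta(J);
  double glvt = 0.0, glsig = 0.0, gzrho = 0.0, glz = 0.0;
  NumericVector gcoef(K > 0 ? K : 1);
  if (K > 0) for (int k = 0; k < K; ++k) gcoef[k] = 0.0;

  for (int e = 0; e < nEnc; ++e) {
    const int i = pidx[e];
    const int j = jidx[e];
    const int yv = y[e];
    const double sy = yv ? 1.0 : -1.0;
    const double z = zfree ? zf : zvec[e];
    const double zy = yv ? z : 1.0 - z;

    double acc_coef = 0.0, acc_beta = 0.0, acc_lvt = 0.0,
           acc_lsig = 0.0, acc_zrho = 0.0, acc_lz = 0.0;
    for (int a = 0; a < A; ++a) {
      const double p1 = p1tab[(size_t)j * A + a];
      const double py = yv ? p1 : 1.0 - p1;
      const double dp1 = p1 * (1.0 - p1);
      for (int b = 0; b < B; ++b) {
        const int q = a * B + b;
        const double W = Wn[(size_t)i * Q + q];
        if (W < 1e-300) continue;
        const double P = Ps[(size_t)e * Q + q];
        const double c1 = W / P;
        double pi = 1.0;
        if (has_mix) {
          pi = Pi[(size_t)e * Q + q];
          const double gpi = (py - zy) * pi * (1.0 - pi) * c1;
          acc_coef += gpi;
          if (has_psi) {
            acc_lsig += gpi * psi[q] * 0.5;
            acc_zrho += gpi * dpsi_zrho[q];
          }
          if (zfree) acc_lz += (1.0 - pi) * sy * c1 * zf * (1.0 - zf);
        }
        const double dth = pi * sy * dp1 * c1;
        acc_beta -= dth;
        if (vt_free) acc_lvt += dth * theta[a] * 0.5;
      }
    }
    gbeta[j] += acc_beta;
    if (vt_free) glvt += acc_lvt;
    if (has_mix) {
      for (int k = 0; k < K; ++k) gcoef[k] += acc_coef * X(e, k);
      if (has_psi) { glsig += acc_lsig; gzrho += acc_zrho; }
      if (zfree) glz += acc_lz;
    }
  }

  int nPar = J + (vt_free ? 1 : 0) + (has_mix ? K : 0) +
             (has_psi ? 2 : 0) + (zfree ? 1 : 0);
  NumericVector grad(nPar);
  int pos = 0;
  for (int j = 0; j < J; ++j) grad[pos++] = gbeta[j];
  if (vt_free) grad[pos++] = glvt;
  if (has_mix) for (int k = 0; k < K; ++k) grad[pos++] = gcoef[k];
  if (has_psi) { grad[pos++] = glsig; grad[pos++] = gzrho; }
  if (zfree) grad[pos++] = glz;

  return List::create(_["loglik"] = ll, _["grad"] = grad);
}
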