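#include <Rcpp.h>
using namespace Rcpp;

// Draw from N(mu, sd^2) truncated to (-Inf, b). Inversion on the log scale:
// stable even when P(Z < b) is far in the lower tail.
static double rtnorm_upper(double mu, double sd, double b) {
  double alpha = (b - mu) / sd;
  double lp = R::pnorm(alpha, 0.0, 1.0, 1, 1); // log Phi(alpha)
  double u = R::unif_rand();
  double z = R::qnorm(lp + std::log(u), 0.0, 1.0, 1, 1);
  if (!R_finite(z)) z = alpha; // extreme tail: collapse to the bound
  return mu + sd * z;
}

// Inverse-gamma(shape, rate) draw.
static double rinvgamma(double shape, double rate) {
  return rate / R::rgamma(shape, 1.0);
}

// Sample beta | rest for a (possibly empty) centred covariate matrix with a
// flat prior. p is small, so a hand-rolled dense Cholesky suffices.
static void draw_beta(const NumericMatrix& X, const std::vector<double>& r,
                      double s1sq, std::vector<double>& beta) {
  const int n = X.nrow(), p = X.ncol();
  if (p == 0) return;
  std::vector<double> A(p * p, 0.0), bvec(p, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) {
      double xij = X(i, j);
      bvec[j] += xij * r[i];
      for (int k = j; k < p; ++k) A[j * p + k] += xij * X(i, k);
    }
  for (int j = 0; j < p; ++j) {
    for (int k = j; k < p; ++k) A[j * p + k] /= s1sq;
    bvec[j] /= s1sq;
    A[j * p + j] += 1e-10; // numerical ridge; prior is flat
  }
  std::vector<double> L(p * p, 0.0);
  for (int j = 0; j < p; ++j) {
    double d = A[j * p + j];
    for (int k = 0; k < j; ++k) d -= L[j * p + k] * L[j * p + k];
    L[j * p + j] = std::sqrt(std::max(d, 1e-300));
    for (int i = j + 1; i < p; ++i) {
      double s = A[j * p + i];
      for (int k = 0; k < j; ++k) s -= L[i * p + k] * L[j * p + k];
      L[i * p + j] = s / L[j * p + j];
    }
  }
  std::vector<double> z(p), mean(p);
  for (int i = 0; i < p; ++i) {
    double s = bvec[i];
    for (int k = 0; k < i; ++k) s -= L[i * p + k] * z[k];
    z[i] = s / L[i * p + i];
  }
  for (int i = p - 1; i >= 0; --i) {
    double s = z[i];
    for (int k = i + 1; k < p; ++k) s -= L[k * p + i] * mean[k];
    mean[i] = s / L[i * p + i];
  }
  std::vector<double> eps(p);
  for (int i = 0; i < p; ++i) eps[i] = R::norm_rand();
  for (int i = p - 1; i >= 0; --i) {
    double s = eps[i];
    for (int k = i + 1; k < p; ++k) s -= L[k * p + i] * beta[k];
    beta[i] = s / L[i * p + i];
  }
  for (int i = 0; i < p; ++i) beta[i] += mean[i];
}

// Log posterior of t = log(sigma) in the non-centred parametrization:
// residuals r ~ N(sigma * u, V) with sum-of-squares Sww = sum u^2 and
// cross-product Srw = sum r*u, plus the IG(nu/2, nu/a) mixture prior on
// sigma^2 (including the t-scale Jacobian).
static double asis_logpost(double t, double Sww, double Srw, double V,
                           double nu, double a) {
  double s = std::exp(t);
  return -(s * s * Sww - 2.0 * s * Srw) / (2.0 * V) - nu * t -
         (nu / a) * std::exp(-2.0 * t);
}

// Univariate slice sampler (Neal 2003, stepping out + shrinkage) for
// t = log(sigma) under asis_logpost.
static double slice_logsigma(double t0, double Sww, double Srw, double V,
                             double nu, double a) {
  const double w = 0.5;
  const int max_steps = 30;
  double f0 = asis_logpost(t0, Sww, Srw, V, nu, a);
  double logy = f0 - R::exp_rand();
  double L = t0 - w * R::unif_rand();
  double R_ = L + w;
  int j = std::floor(max_steps * R::unif_rand());
  int k = max_steps - 1 - j;
  while (j-- > 0 && asis_logpost(L, Sww, Srw, V, nu, a) > logy) L -= w;
  while (k-- > 0 && asis_logpost(R_, Sww, Srw, V, nu, a) > logy) R_ += w;
  for (int it = 0; it < 100; ++it) {
    double t1 = L + R::unif_rand() * (R_ - L);
    if (asis_logpost(t1, Sww, Srw, V, nu, a) > logy) return t1;
    if (t1 < t0) L = t1; else R_ = t1;
  }
  return t0;
}

// One Gibbs chain for the left-censored nested random-intercept model, in
// the hierarchically centred parametrization (subject means around centre
// means around the grand intercept), which mixes well when group means are
// strongly identified:
//   y_i ~ N(x_i' beta + a_{subj(i)}, s1sq)          (x: centred covariates)
//   a_j ~ N(m_{cent(j)}, s2sq)    [three-level]  or  a_j ~ N(b0, s2sq)
//   m_k ~ N(b0, s3sq)
// Censored observations (cens[i] == 1) are latent, known only to lie below
// lod[i], and are redrawn each sweep from the truncated normal. Standard
// deviations carry half-t(nu, 0, A) priors through the inverse-gamma
// mixture (sigma^2 | a ~ IG(nu/2, nu/a), a ~ IG(1/2, 1/A^2)); the grand
// intercept has a t(nu, b0_mean, b0_scale) prior via a normal scale
// mixture; covariate coefficients are flat. Uses R's RNG, so R-side
// seeding applies. Output columns: s1sq, s2sq, s3sq, b0, beta...
// [[Rcpp::export(name = ".gibbs_chain")]]
NumericMatrix gibbs_chain(NumericVector y_obs, IntegerVector cens,
                          NumericVector lod, NumericMatrix X,
                          IntegerVector subj, IntegerVector cent,
                          IntegerVector subj_cent, int n_subj, int n_cent,
                          bool three_level, int iter, int burn, int thin,
                          double nu, double A_e, double A_s, double A_c,
                          double b0_mean, double b0_scale,
                          NumericVector init_sigma_sq) {
  const int n = y_obs.size(), p = X.ncol();
  const int n_keep = (iter - burn) / thin;
  NumericMatrix out(n_keep, 4 + p);

  std::vector<double> y(n), mu(n, 0.0), r(n);
  std::vector<double> a(n_subj), m(n_cent, b0_mean);
  std::vector<double> beta(p, 0.0);
  std::vector<double> subj_sum(n_subj), cent_sum(n_cent);
  std::vector<int> subj_n(n_subj, 0), cent_nsubj(n_cent, 0);

  for (int i = 0; i < n; ++i) subj_n[subj[i]]++;
  for (int j = 0; j < n_subj; ++j) cent_nsubj[subj_cent[j]]++;

  double s1sq = init_sigma_sq[0], s2sq = init_sigma_sq[1],
         s3sq = three_level ? init_sigma_sq[2] : 1.0;
  // auxiliary mixture parameters live on the inverse-variance scale:
  // a ~ IG(1/2, 1/A^2) has mode 2/(3 A^2)
  double a1 = 1.0 / (A_e * A_e), a2 = 1.0 / (A_s * A_s),
         a3 = 1.0 / (A_c * A_c);
  double lambda0 = b0_scale * b0_scale;
  double b0 = b0_mean;
  for (int j = 0; j < n_subj; ++j) a[j] = b0_mean;

  for (int i = 0; i < n; ++i)
    y[i] = cens[i] ? lod[i] - 0.5 * std::sqrt(s1sq) * R::unif_rand() - 0.05
                   : y_obs[i];

  int keep = 0;
  for (int it = 0; it < iter; ++it) {
    // covariate part of the linear predictor
    if (p > 0)
      for (int i = 0; i < n; ++i) {
        double xb = 0.0;
        for (int j = 0; j < p; ++j) xb += X(i, j) * beta[j];
        mu[i] = xb;
      }

    // 1. impute censored responses
    double sd1 = std::sqrt(s1sq);
    for (int i = 0; i < n; ++i)
      if (cens[i]) y[i] = rtnorm_upper(mu[i] + a[subj[i]], sd1, lod[i]);

    // 2. subject means around their parent (centre mean or intercept)
    std::fill(subj_sum.begin(), subj_sum.end(), 0.0);
    for (int i = 0; i < n; ++i) subj_sum[subj[i]] += y[i] - mu[i];
    for (int j = 0; j < n_subj; ++j) {
      double parent = three_level ? m[subj_cent[j]] : b0;
      double prec = subj_n[j] / s1sq + 1.0 / s2sq;
      double mean = (subj_sum[j] / s1sq + parent / s2sq) / prec;
      a[j] = mean + R::norm_rand() / std::sqrt(prec);
    }

    // 3. centre means, then the grand intercept
    if (three_level) {
      std::fill(cent_sum.begin(), cent_sum.end(), 0.0);
      for (int j = 0; j < n_subj; ++j) cent_sum[subj_cent[j]] += a[j];
      for (int k = 0; k < n_cent; ++k) {
        double prec = cent_nsubj[k] / s2sq + 1.0 / s3sq;
        double mean = (cent_sum[k] / s2sq + b0 / s3sq) / prec;
        m[k] = mean + R::norm_rand() / std::sqrt(prec);
      }
      double prec = n_cent / s3sq + 1.0 / lambda0;
      double msum = 0.0;
      for (int k = 0; k < n_cent; ++k) msum += m[k];
      b0 = (msum / s3sq + b0_mean / lambda0) / prec +
           R::norm_rand() / std::sqrt(prec);
    } else {
      double prec = n_subj / s2sq + 1.0 / lambda0;
      double asum = 0.0;
      for (int j = 0; j < n_subj; ++j) asum += a[j];
      b0 = (asum / s2sq + b0_mean / lambda0) / prec +
           R::norm_rand() / std::sqrt(prec);
    }
    lambda0 = rinvgamma(0.5 * (nu + 1.0),
                        0.5 * (nu * b0_scale * b0_scale +
                               (b0 - b0_mean) * (b0 - b0_mean)));

    // 4. covariate coefficients (flat prior)
    if (p > 0) {
      for (int i = 0; i < n; ++i) r[i] = y[i] - a[subj[i]];
      draw_beta(X, r, s1sq, beta);
      for (int i = 0; i < n; ++i) {
        double xb = 0.0;
        for (int j = 0; j < p; ++j) xb += X(i, j) * beta[j];
        mu[i] = xb;
      }
    }

    // 5. variance components under the half-t mixture
    double sse = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = y[i] - mu[i] - a[subj[i]];
      sse += e * e;
    }
    s1sq = rinvgamma(0.5 * (nu + n), nu / a1 + 0.5 * sse);
    a1 = rinvgamma(0.5 * (nu + 1.0), nu / s1sq + 1.0 / (A_e * A_e));

    double ssu = 0.0;
    for (int j = 0; j < n_subj; ++j) {
      double d = a[j] - (three_level ? m[subj_cent[j]] : b0);
      ssu += d * d;
    }
    s2sq = rinvgamma(0.5 * (nu + n_subj), nu / a2 + 0.5 * ssu);
    a2 = rinvgamma(0.5 * (nu + 1.0), nu / s2sq + 1.0 / (A_s * A_s));

    if (three_level) {
      double ssv = 0.0;
      for (int k = 0; k < n_cent; ++k) {
        double d = m[k] - b0;
        ssv += d * d;
      }
      s3sq = rinvgamma(0.5 * (nu + n_cent), nu / a3 + 0.5 * ssv);
      a3 = rinvgamma(0.5 * (nu + 1.0), nu / s3sq + 1.0 / (A_c * A_c));
    }

    // 6. interweaving (ASIS): re-update each hierarchical SD in the
    // non-centred parametrization via slice sampling, then rescale the
    // group effects. Restores mixing when a variance component is small.
    if (s2sq > 1e-280) {
      double sd2 = std::sqrt(s2sq);
      double Sww = 0.0, Srw = 0.0;
      std::fill(subj_sum.begin(), subj_sum.end(), 0.0);
      for (int i = 0; i < n; ++i) subj_sum[subj[i]] += y[i] - mu[i];
      for (int j = 0; j < n_subj; ++j) {
        double parent = three_level ? m[subj_cent[j]] : b0;
        double ut = (a[j] - parent) / sd2;
        Sww += ut * ut * subj_n[j];
        Srw += ut * (subj_sum[j] - subj_n[j] * parent);
      }
      if (Sww > 0.0) {
        double t1 = slice_logsigma(std::log(sd2), Sww, Srw, s1sq, nu, a2);
        double sd2n = std::exp(t1);
        for (int j = 0; j < n_subj; ++j) {
          double parent = three_level ? m[subj_cent[j]] : b0;
          a[j] = parent + (a[j] - parent) * (sd2n / sd2);
        }
        s2sq = sd2n * sd2n;
      }
    }
    if (three_level && s3sq > 1e-280) {
      double sd3 = std::sqrt(s3sq);
      double Sww = 0.0, Srw = 0.0;
      std::fill(cent_sum.begin(), cent_sum.end(), 0.0);
      for (int j = 0; j < n_subj; ++j) cent_sum[subj_cent[j]] += a[j];
      for (int k = 0; k < n_cent; ++k) {
        double vt = (m[k] - b0) / sd3;
        Sww += vt * vt * cent_nsubj[k];
        Srw += vt * (cent_sum[k] - cent_nsubj[k] * b0);
      }
      if (Sww > 0.0) {
        double t1 = slice_logsigma(std::log(sd3), Sww, Srw, s2sq, nu, a3);
        double sd3n = std::exp(t1);
        for (int k = 0; k < n_cent; ++k)
          m[k] = b0 + (m[k] - b0) * (sd3n / sd3);
        s3sq = sd3n * sd3n;
      }
    }

    if (it >= burn && (it - burn) % thin == 0) {
      out(keep, 0) = s1sq;
      out(keep, 1) = s2sq;
      out(keep, 2) = three_level ? s3sq : 0.0;
      out(keep, 3) = b0;
      for (int j = 0; j < p; ++j) out(keep, 4 + j) = beta[j];
      ++keep;
    }
  }
  return out;
}
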