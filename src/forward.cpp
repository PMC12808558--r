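#include <Rcpp.h>
using namespace Rcpp;

// numerical guards: linear predictors are clipped at +/-35 before the
// inverse logit, and probabilities floored away from {0,1}
static const double ETA_CLIP = 35.0;
static const double P_FLOOR = 1e-12;

static inline double invlogit(double eta) {
  if (eta > ETA_CLIP) eta = ETA_CLIP;
  if (eta < -ETA_CLIP) eta = -ETA_CLIP;
  double p = 1.0 / (1.0 + std::exp(-eta));
  if (p < P_FLOOR) p = P_FLOOR;
  if (p > 1.0 - P_FLOOR) p = 1.0 - P_FLOOR;
  return p;
}

// Marginal log-likelihood of the dynamic occupancy model, summed over
// sites, by the scaled forward recursion over the latent state z in {0,1}.
//
// d: list built by prep_occ_data() --
//   n, T (ints); forest (int n, 1-based); Xpsi (n x k1);
//   Xgam, Xeps ((n*(T-1)) x k, row i + n*(t-1));
//   det_site, det_year (int R, 1-based), det_y (int R), Xp (R x k4)
// Parameters arrive as plain numeric vectors.
// [[Rcpp::export(name = ".occ_loglik_cpp")]]
NumericVector occ_loglik_cpp(List d,
                             NumericVector beta_psi,
                             NumericVector beta_gamma,
                             NumericVector beta_eps,
                             NumericVector beta_p,
                             NumericVector alpha_psi,
                             NumericVector alpha_gamma,
                             NumericVector alpha_eps,
                             NumericVector alpha_p) {
  const int n = as<int>(d["n"]);
  const int T = as<int>(d["T"]);
  const IntegerVector forest = d["forest"];
  const NumericMatrix Xpsi = d["Xpsi"];
  const NumericMatrix Xgam = d["Xgam"];
  const NumericMatrix Xeps = d["Xeps"];
  const IntegerVector det_site = d["det_site"];
  const IntegerVector det_year = d["det_year"];
  const IntegerVector det_y = d["det_y"];
  const NumericMatrix Xp_t = d["Xp_t"];  // k_p x R, contiguous per record
  const int R = det_site.size();

  std::vector<double> psi(n);
  for (int i = 0; i < n; ++i) {
    double eta = alpha_psi[forest[i] - 1];
    for (int k = 0; k < Xpsi.ncol(); ++k) eta += Xpsi(i, k) * beta_psi[k];
    psi[i] = invlogit(eta);
  }
  std::vector<double> gam(n * std::max(T - 1, 0)), eps(n * std::max(T - 1, 0));
  for (int t = 0; t < T - 1; ++t) {
    for (int i = 0; i < n; ++i) {
      const int r = i + n * t;
      double eg = alpha_gamma[forest[i] - 1], ee = alpha_eps[forest[i] - 1];
      for (int k = 0; k < Xgam.ncol(); ++k) eg += Xgam(r, k) * beta_gamma[k];
      for (int k = 0; k < Xeps.ncol(); ++k) ee += Xeps(r, k) * beta_eps[k];
      gam[r] = invlogit(eg);
      eps[r] = invlogit(ee);
    }
  }

  // per site-year detection log-likelihood given z = 1, and whether any
  // detection occurred (z = 0 has likelihood 1 iff no detections)
  std::vector<double> logd1(n * T, 0.0);
  std::vector<char> any_det(n * T, 0);
  for (int r = 0; r < R; ++r) {
    const int i = det_site[r] - 1, t = det_year[r] - 1;
    double eta = alpha_p[forest[i] - 1];
    const double *xr = &Xp_t(0, r);
    for (int k = 0; k < Xp_t.nrow(); ++k) eta += xr[k] * beta_p[k];
    const double p = invlogit(eta);
    const int idx = i + n * t;
    if (det_y[r] == 1) {
      logd1[idx] += std::log(p);
      any_det[idx] = 1;
    } else {
      logd1[idx] += std::log1p(-p);
    }
  }

  NumericVector ll(n);
  for (int i = 0; i < n; ++i) {
    double a0 = 1.0 - psi[i], a1 = psi[i], acc = 0.0;
    for (int t = 0; t < T; ++t) {
      if (t > 0) {
        const int r = i + n * (t - 1);
        const double b0 = a0 * (1.0 - gam[r]) + a1 * eps[r];
        const double b1 = a0 * gam[r] + a1 * (1.0 - eps[r]);
        a0 = b0;
        a1 = b1;
      }
      const int idx = i + n * t;
      const double m = any_det[idx] ? logd1[idx]
                                    : std::max(logd1[idx], 0.0);
      const double w1 = std::exp(logd1[idx] - m);
      const double w0 = any_det[idx] ? 0.0 : std::exp(-m);
      a0 *= w0;
      a1 *= w1;
      const double s = a0 + a1;
      acc += m + std::log(s);
      a0 /= s;
      a1 /= s;
    }
    ll[i] = acc;
  }
  return ll;
}

// Log-likelihood and its analytic gradient with respect to every
// coefficient and forest intercept, by the forward-backward algorithm.
// Posterior marginals q_t(z) and pairwise transition posteriors feed the
// standard hidden-Markov score identities:
//   d logL / d eta_psi   = q_1(1) - psi
//   d logL / d eta_gamma = xi(0,1)(1-gamma) - xi(0,0) gamma
//   d logL / d eta_eps   = xi(1,0)(1-eps)   - xi(1,1) eps
//   d logL / d eta_p(r)  = q_t(1) (y_r - p_r)
// [[Rcpp::export(name = ".occ_loglik_grad_cpp")]]
List occ_loglik_grad_cpp(List d,
                         NumericVector beta_psi,
                         NumericVector beta_gamma,
                         NumericVector beta_eps,
                         NumericVector beta_p,
                         NumericVector alpha_psi,
                         NumericVector alpha_gamma,
                         NumericVector alpha_eps,
                         NumericVector alpha_p) {
  const int n = as<int>(d["n"]);
  const int T = as<int>(d["T"]);
  const IntegerVector forest = d["forest"];
  const NumericMatrix Xpsi = d["Xpsi"];
  const NumericMatrix Xgam = d["Xgam"];
  const NumericMatrix Xeps = d["Xeps"];
  const IntegerVector det_site = d["det_site"];
  const IntegerVector det_year = d["det_year"];
  const IntegerVector det_y = d["det_y"];
  const NumericMatrix Xp_t = d["Xp_t"];
  const int R = det_site.size();
  const int kpsi = Xpsi.ncol(), kg = Xgam.ncol(), ke = Xeps.ncol(),
            kp = Xp_t.nrow(), nf = alpha_psi.size();

  std::vector<double> psi(n);
  for (int i = 0; i < n; ++i) {
    double eta = alpha_psi[forest[i] - 1];
    for (int k = 0; k < kpsi; ++k) eta += Xpsi(i, k) * beta_psi[k];
    psi[i] = invlogit(eta);
  }
  const int nt1 = n * std::max(T - 1, 0);
  std::vector<double> gam(nt1), eps(nt1);
  for (int t = 0; t < T - 1; ++t) {
    for (int i = 0; i < n; ++i) {
      const int r = i + n * t;
      double eg = alpha_gamma[forest[i] - 1], ee = alpha_eps[forest[i] - 1];
      for (int k = 0; k < kg; ++k) eg += Xgam(r, k) * beta_gamma[k];
      for (int k = 0; k < ke; ++k) ee += Xeps(r, k) * beta_eps[k];
      gam[r] = invlogit(eg);
      eps[r] = invlogit(ee);
    }
  }
  std::vector<double> logd1(n * T, 0.0), p_row(R);
  std::vector<char> any_det(n * T, 0);
  for (int r = 0; r < R; ++r) {
    const int i = det_site[r] - 1, t = det_year[r] - 1;
    double eta = alpha_p[forest[i] - 1];
    const double *xr = &Xp_t(0, r);
    for (int k = 0; k < kp; ++k) eta += xr[k] * beta_p[k];
    const double p = invlogit(eta);
    p_row[r] = p;
    const int idx = i + n * t;
    if (det_y[r] == 1) {
      logd1[idx] += std::log(p);
      any_det[idx] = 1;
    } else {
      logd1[idx] += std::log1p(-p);
    }
  }

  // forward (scaled, post-detection) and backward passes; q1 holds the
  // posterior P(z_t = 1 | data) per site-year
  std::vector<double> q1(n * T), geta_gam(nt1, 0.0), geta_eps(nt1, 0.0),
      geta_psi(n);
  double total_ll = 0.0;
  std::vector<double> a0v(T), a1v(T), w0v(T), w1v(T);
  for (int i = 0; i < n; ++i) {
    double a0 = 1.0 - psi[i], a1 = psi[i], acc = 0.0;
    for (int t = 0; t < T; ++t) {
      if (t > 0) {
        const int r = i + n * (t - 1);
        const double b0 = a0 * (1.0 - gam[r]) + a1 * eps[r];
        const double b1 = a0 * gam[r] + a1 * (1.0 - eps[r]);
        a0 = b0; a1 = b1;
      }
      const int idx = i + n * t;
      const double m = any_det[idx] ? logd1[idx]
                                    : std::max(logd1[idx], 0.0);
      const double w1 = std::exp(logd1[idx] - m);
      const double w0 = any_det[idx] ? 0.0 : std::exp(-m);
      a0 *= w0; a1 *= w1;
      const double s = a0 + a1;
      acc += m + std::log(s);
      a0 /= s; a1 /= s;
      a0v[t] = a0; a1v[t] = a1; w0v[t] = w0; w1v[t] = w1;
    }
    total_ll += acc;
    // backward
    double bb0 = 1.0, bb1 = 1.0;
    q1[i + n * (T - 1)] = a1v[T - 1];
    for (int t = T - 2; t >= 0; --t) {
      const int r = i + n * t;
      const double c0 = w0v[t + 1] * bb0, c1 = w1v[t + 1] * bb1;
      // pairwise posterior xi(z_t, z_{t+1}) (unnormalized)
      const double x00 = a0v[t] * (1.0 - gam[r]) * c0;
      const double x01 = a0v[t] * gam[r] * c1;
      const double x10 = a1v[t] * eps[r] * c0;
      const double x11 = a1v[t] * (1.0 - eps[r]) * c1;
      const double xs = x00 + x01 + x10 + x11;
      geta_gam[r] = (x01 * (1.0 - gam[r]) - x00 * gam[r]) / xs;
      geta_eps[r] = (x10 * (1.0 - eps[r]) - x11 * eps[r]) / xs;
      // new backward values at t
      double nb0 = (1.0 - gam[r]) * c0 + gam[r] * c1;
      double nb1 = eps[r] * c0 + (1.0 - eps[r]) * c1;
      const double bs = nb0 + nb1;
      bb0 = nb0 / bs; bb1 = nb1 / bs;
      const double qn0 = a0v[t] * bb0, qn1 = a1v[t] * bb1;
      q1[i + n * t] = qn1 / (qn0 + qn1);
    }
    if (T == 1) q1[i] = a1v[0];
    geta_psi[i] = q1[i] - psi[i];
  }

  // chain rule into coefficient / intercept gradients
  NumericVector gbpsi(kpsi), gbgam(kg), gbeps(ke), gbp(kp),
      gapsi(nf), gagam(nf), gaeps(nf), gap(nf);
  for (int i = 0; i < n; ++i) {
    const double g = geta_psi[i];
    for (int k = 0; k < kpsi; ++k) gbpsi[k] += g * Xpsi(i, k);
    gapsi[forest[i] - 1] += g;
  }
  for (int t = 0; t < T - 1; ++t) {
    for (int i = 0; i < n; ++i) {
      const int r = i + n * t;
      for (int k = 0; k < kg; ++k) gbgam[k] += geta_gam[r] * Xgam(r, k);
      for (int k = 0; k < ke; ++k) gbeps[k] += geta_eps[r] * Xeps(r, k);
      gagam[forest[i] - 1] += geta_gam[r];
      gaeps[forest[i] - 1] += geta_eps[r];
    }
  }
  for (int r = 0; r < R; ++r) {
    const int i = det_site[r] - 1, t = det_year[r] - 1;
    const double g = q1[i + n * t] * (det_y[r] - p_row[r]);
    const double *xr = &Xp_t(0, r);
    for (int k = 0; k < kp; ++k) gbp[k] += g * xr[k];
    gap[forest[i] - 1] += g;
  }
  return List::create(
      _["loglik"] = total_ll, _["gbpsi"] = gbpsi, _["gbgam"] = gbgam,
      _["gbeps"] = gbeps, _["gbp"] = gbp, _["gapsi"] = gapsi,
      _["gagam"] = gagam, _["gaeps"] = gaeps, _["gap"] = gap);
}
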