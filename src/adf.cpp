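// Core numerics for the neural-mass assumed-density filter.
//
// The augmented state is xi = [v_ep z_ep v_ip z_ip v_pe z_pe v_pi z_pi,
// u alpha_ep alpha_ip alpha_pe alpha_pi] (13 entries, pre->post synapse
// labels).  Dynamics: xi' = A xi + Bs g(xi) + w, where g_j = theta_j *
// phi(c_j' xi) for each of the 4 synapses, phi the erf sigmoid, and Bs the
// 13x4 routing matrix with dt/tau_j on the z-rows.  Gaussian moments of g
// are exact (Stein identity) for the mean and cross-covariance; the 4x4
// nonlinear-nonlinear block reduces, after conditioning theta on the
// presynaptic potentials and integrating one potential analytically, to
// one-dimensional Gauss-Hermite quadratures.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double sig_phi(double v, double v0, double vs) {
  return 0.5 * (1.0 + std::erf((v - v0) / vs));
}

// E[phi(V)] for V ~ N(m, s2): erf smeared by the Gaussian.
static inline double gsm(double m, double s2, double v0, double vs) {
  double g = vs * vs + 2.0 * s2;
  return 0.5 * (1.0 + std::erf((m - v0) / std::sqrt(g)));
}

// E[phi'(V)]
static inline double gss(double m, double s2, double v0, double vs) {
  double g = vs * vs + 2.0 * s2;
  double d = m - v0;
  return std::exp(-d * d / g) / std::sqrt(M_PI * g);
}

// [[Rcpp::export(name = ".cpp_gauss_sig_mean")]]
Rcpp::NumericVector cpp_gauss_sig_mean(Rcpp::NumericVector m,
                                       Rcpp::NumericVector s2,
                                       double v0, double vs) {
  int n = m.size();
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = gsm(m[i], s2[i], v0, vs);
  return out;
}

// [[Rcpp::export(name = ".cpp_gauss_sig_slope")]]
Rcpp::NumericVector cpp_gauss_sig_slope(Rcpp::NumericVector m,
                                        Rcpp::NumericVector s2,
                                        double v0, double vs) {
  int n = m.size();
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = gss(m[i], s2[i], v0, vs);
  return out;
}

// E[g_j g_k] where g_j = theta_j phi(v_j), (theta_j, theta_k, v_j, v_k)
// jointly Gaussian with moments (mt, T), (m, S) and cross-covariance G.
// E[theta_j theta_k | v] is quadratic in v (Gaussian conditioning); the
// inner variable is then integrated in closed form and the outer by
// Gauss-Hermite quadrature.  ghx/ghw: probabilists-normalized nodes
// (E[f(Z)] ~ sum w_i f(sqrt(2) x_i) with sum w = 1).
static double Egg_pair(const double m1, const double m2, const double s11,
                       const double s12, const double s22, const double mt1,
                       const double mt2, const double t11, const double t12,
                       const double t22, const double g11, const double g12,
                       const double g21, const double g22, double v0,
                       double vs, const vec& ghx_lo, const vec& ghw_lo,
                       const vec& ghx_hi, const vec& ghw_hi) {
  // closed-form eigen decomposition of the symmetric 2x2 S
  double tr = s11 + s22;
  double disc = std::sqrt(std::max((s11 - s22) * (s11 - s22) +
                                   4.0 * s12 * s12, 0.0));
  double l1 = 0.5 * (tr + disc), l2 = 0.5 * (tr - disc);  // l1 >= l2
  // eigenvector for l1
  double e1x, e1y;
  if (std::abs(s12) > 1e-300) {
    e1x = l1 - s22; e1y = s12;
  } else if (s11 >= s22) {
    e1x = 1.0; e1y = 0.0;
  } else {
    e1x = 0.0; e1y = 1.0;
  }
  double nrm = std::sqrt(e1x * e1x + e1y * e1y);
  e1x /= nrm; e1y /= nrm;
  double e2x = -e1y, e2y = e1x;

  double lmax = std::max(l1, 0.0);
  double tol = std::max(lmax * 1e-12, 1e-300);
  bool use1 = l1 > tol, use2 = l2 > tol;

  // pseudo-inverse restricted to the non-degenerate directions
  double i11 = 0, i12 = 0, i22 = 0;
  if (use1) {
    i11 += e1x * e1x / l1; i12 += e1x * e1y / l1; i22 += e1y * e1y / l1;
  }
  if (use2) {
    i11 += e2x * e2x / l2; i12 += e2x * e2y / l2; i22 += e2y * e2y / l2;
  }
  // conditional-mean loading Gc = G * Sinv, conditional covariance entry
  double gc11 = g11 * i11 + g12 * i12, gc12 = g11 * i12 + g12 * i22;
  double gc21 = g21 * i11 + g22 * i12, gc22 = g21 * i12 + g22 * i22;
  double c12 = t12 - (gc11 * g21 + gc12 * g22);

  if (!use1 && !use2) {
    return sig_phi(m1, v0, vs) * sig_phi(m2, v0, vs) * (c12 + mt1 * mt2);
  }

  // Semi-analytic reduction: the inner variable is integrated in closed
  // form (Gaussian-sigmoid moments up to second order), leaving a single
  // quadrature over the outer variable; the outer is taken as the larger
  // variance so the remaining 1-D integral is as benign as possible.
  double mo, soo, mi, sii, lo1, li1, lo2, li2;
  bool outer_is_1 = s11 >= s22;
  if (outer_is_1) {
    mo = m1; soo = s11; mi = m2; sii = s22;
    lo1 = gc11; li1 = gc12; lo2 = gc21; li2 = gc22;
  } else {
    mo = m2; soo = s22; mi = m1; sii = s11;
    lo1 = gc12; li1 = gc11; lo2 = gc22; li2 = gc21;
  }
  double soi = s12;
  double beta = soi / soo;                 // inner|outer regression slope
  double sv = std::max(sii - beta * soi, 0.0);

  // wide beliefs (outer sd beyond the sigmoid slope scale) need many more
  // nodes: the integrand approaches a step times a quadratic
  bool wide = soo > vs * vs;
  const vec& ghx = wide ? ghx_hi : ghx_lo;
  const vec& ghw = wide ? ghw_hi : ghw_lo;
  int q = ghx.n_elem;
  double sc = std::sqrt(2.0 * soo);
  double acc = 0.0;
  for (int i = 0; i < q; ++i) {
    double dout = sc * ghx[i];
    double vo = mo + dout;
    double mc = mi + beta * dout;          // conditional inner mean
    double del = mc - mi;                  // = beta * dout
    double M0 = gsm(mc, sv, v0, vs);
    double S1 = gss(mc, sv, v0, vs);
    double gam = vs * vs + 2.0 * sv;
    double S2 = -2.0 * (mc - v0) / gam * S1;  // E[phi''] under N(mc, sv)
    double Ed1 = del * M0 + sv * S1;          // E[(v_in - mi) phi]
    double Ed2 = del * del * M0 + 2.0 * del * sv * S1 + sv * M0 +
                 sv * sv * S2;                // E[(v_in - mi)^2 phi]
    double a1 = mt1 + lo1 * dout, b1 = li1;
    double a2 = mt2 + lo2 * dout, b2 = li2;
    double inner = (c12 + a1 * a2) * M0 + (a1 * b2 + a2 * b1) * Ed1 +
                   b1 * b2 * Ed2;
    acc += ghw[i] * sig_phi(vo, v0, vs) * inner;
  }
  return acc;
}

// diagonal case: E[(theta phi(v))^2] with scalar v
static double Egg_diag(const double m, const double s, const double mt,
                       const double t11, const double g, double v0,
                       double vs, const vec& ghx_lo, const vec& ghw_lo,
                       const vec& ghx_hi, const vec& ghw_hi) {
  if (s <= std::max(s * 1e-12, 1e-300)) {
    double ph = sig_phi(m, v0, vs);
    return ph * ph * (t11 + mt * mt);
  }
  double gc = g / s;
  double cvar = t11 - gc * g;
  double sc = std::sqrt(2.0 * s);
  bool wide = s > vs * vs;
  const vec& ghx = wide ? ghx_hi : ghx_lo;
  const vec& ghw = wide ? ghw_hi : ghw_lo;
  int q = ghx.n_elem;
  double acc = 0.0;
  for (int i = 0; i < q; ++i) {
    double d = sc * ghx[i];
    double u = mt + gc * d;
    double ph = sig_phi(m + d, v0, vs);
    acc += ghw[i] * ph * ph * (cvar + u * u);
  }
  return acc;
}

// One prediction step: returns mean, covariance and E[g].
static void predict_core(vec& mu, mat& P, const mat& A, const mat& Bs,
                         const mat& Cm, const uvec& ia, const mat& Q,
                         double v0, double vs, const vec& ghx,
                         const vec& ghw, const vec& ghx_hi,
                         const vec& ghw_hi) {
  int ns = Cm.n_rows;                      // 4 synapses
  vec m = Cm * mu;                         // presynaptic potential means
  mat Qc = P * Cm.t();                     // Cov(xi, v_k), 13 x 4
  mat S = Cm * Qc;                         // Cov(v), 4 x 4

  vec Ephi(ns), Eslope(ns), Ecurv(ns), Eg(ns), Ethslope(ns), mth(ns);
  for (int j = 0; j < ns; ++j) {
    double s2 = std::max(S(j, j), 0.0);
    double gam = vs * vs + 2.0 * s2;
    mth[j] = mu[ia[j]];
    Ephi[j] = gsm(m[j], s2, v0, vs);
    Eslope[j] = gss(m[j], s2, v0, vs);
    Ecurv[j] = -2.0 * (m[j] - v0) / gam * Eslope[j];  // E[phi''(v)]
    double ctv = Qc(ia[j], j);             // Cov(theta_j, v_j)
    Eg[j] = mth[j] * Ephi[j] + ctv * Eslope[j];
    Ethslope[j] = mth[j] * Eslope[j] + ctv * Ecurv[j]; // E[theta phi'(v)]
  }

  // Cov(xi, g_j) = P e_{a_j} E[phi_j] + P c_j E[theta_j phi'_j]
  mat Cxg(mu.n_elem, ns);
  for (int j = 0; j < ns; ++j)
    Cxg.col(j) = P.col(ia[j]) * Ephi[j] + Qc.col(j) * Ethslope[j];

  // Cov(g): quadrature on pairs
  mat Cgg(ns, ns);
  for (int j = 0; j < ns; ++j) {
    double sjj = std::max(S(j, j), 0.0);
    double egg = Egg_diag(m[j], sjj, mth[j], P(ia[j], ia[j]), Qc(ia[j], j),
                          v0, vs, ghx, ghw, ghx_hi, ghw_hi);
    Cgg(j, j) = egg - Eg[j] * Eg[j];
    for (int k = j + 1; k < ns; ++k) {
      double egg2 = Egg_pair(m[j], m[k], std::max(S(j, j), 0.0), S(j, k),
                             std::max(S(k, k), 0.0), mth[j], mth[k],
                             P(ia[j], ia[j]), P(ia[j], ia[k]),
                             P(ia[k], ia[k]), Qc(ia[j], j), Qc(ia[j], k),
                             Qc(ia[k], j), Qc(ia[k], k), v0, vs, ghx, ghw,
                             ghx_hi, ghw_hi);
      Cgg(j, k) = Cgg(k, j) = egg2 - Eg[j] * Eg[k];
    }
  }

  mat APA = A * P * A.t();
  mat ACB = A * Cxg * Bs.t();
  vec mu_new = A * mu + Bs * Eg;
  mat P_new = APA + ACB + ACB.t() + Bs * Cgg * Bs.t() + Q;
  mu = mu_new;
  P = 0.5 * (P_new + P_new.t());
}

// [[Rcpp::export(name = ".cpp_adf_predict")]]
Rcpp::List cpp_adf_predict(arma::vec mu, arma::mat P, const arma::mat& A,
                           const arma::mat& Bs, const arma::mat& Cm,
                           const arma::uvec& ia, const arma::mat& Q,
                           double v0, double vs, const arma::vec& ghx,
                           const arma::vec& ghw, const arma::vec& ghx_hi,
                           const arma::vec& ghw_hi) {
  predict_core(mu, P, A, Bs, Cm, ia, Q, v0, vs, ghx, ghw, ghx_hi, ghw_hi);
  return Rcpp::List::create(Rcpp::Named("mean") = mu,
                            Rcpp::Named("cov") = P);
}

// PSD repair policy: symmetrize; if a diagonal entry is negative, add one
// jitter of 1e-12 * trace/N; report failure if still negative.
static bool psd_repair(mat& P) {
  P = 0.5 * (P + P.t());
  if (P.diag().min() >= 0.0) return true;
  double jit = 1e-12 * trace(P) / P.n_rows;
  if (!(jit > 0)) jit = 1e-18;
  P.diag() += jit;
  return P.diag().min() >= 0.0;
}

// [[Rcpp::export(name = ".cpp_run_filter")]]
Rcpp::List cpp_run_filter(const arma::vec& y, const arma::mat& A,
                          const arma::mat& Bs, const arma::mat& Cm,
                          const arma::uvec& ia, const arma::mat& Q,
                          const arma::rowvec& H, double R, arma::vec mu,
                          arma::mat P, double v0, double vs,
                          const arma::vec& ghx, const arma::vec& ghw,
                          const arma::vec& ghx_hi, const arma::vec& ghw_hi,
                          bool store_gain) {
  int n = y.n_elem, nx = mu.n_elem;
  mat M(n, nx), V(n, nx);
  vec innov(n, fill::value(datum::nan));
  mat gains;
  if (store_gain) gains.set_size(n, nx);
  int first_bad = -1;  // 0-based; -1 = none
  double sse = 0.0;
  int nok = 0;

  for (int t = 0; t < n; ++t) {
    bool ok = true;
    if (!std::isfinite(y[t])) ok = false;
    if (ok) {
      predict_core(mu, P, A, Bs, Cm, ia, Q, v0, vs, ghx, ghw, ghx_hi,
                   ghw_hi);
      if (!mu.is_finite() || !P.is_finite() || !psd_repair(P)) ok = false;
    }
    double s = 0.0;
    if (ok) {
      s = as_scalar(H * P * H.t()) + R;
      if (!(s > 0.0) || !std::isfinite(s)) ok = false;
    }
    if (ok) {
      vec K = P * H.t() / s;
      double e = y[t] - as_scalar(H * mu);
      mu += K * e;
      mat IKH = eye(nx, nx) - K * H;
      P = IKH * P * IKH.t() + R * (K * K.t());  // Joseph form
      if (!mu.is_finite() || !P.is_finite() || !psd_repair(P)) ok = false;
      if (ok) {
        innov[t] = e;
        if (store_gain) gains.row(t) = K.t();
        double r = y[t] - as_scalar(H * mu);
        sse += r * r;
        ++nok;
      }
    }
    if (!ok) { first_bad = t; break; }
    M.row(t) = mu.t();
    V.row(t) = P.diag().t();
  }
  if (first_bad >= 0) {
    for (int t = first_bad; t < n; ++t) {
      M.row(t).fill(datum::nan);
      V.row(t).fill(datum::nan);
    }
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("mean") = M, Rcpp::Named("var") = V,
      Rcpp::Named("innovation") = innov,
      Rcpp::Named("first_bad") = first_bad + 1,  // 1-based, 0 = none
      Rcpp::Named("mse") = nok > 0 ? sse / nok : NA_REAL,
      Rcpp::Named("final_cov") = P);
  if (store_gain) out["gain"] = gains;
  return out;
}

// Simulation of the neural mass model with a (possibly time-varying)
// parameter trajectory, using the exact zero-order-hold discretization of
// each critically damped synaptic kernel (the nonlinear drive alpha*phi is
// held constant over the step).  theta: n x 5 [u, a_ep, a_ip, a_pe, a_pi];
// znoise: n x 4 process noise added to the z-states after each step; x0: 8
// initial states.  Scalar per-synapse updates (the loop route).
// [[Rcpp::export(name = ".cpp_simulate")]]
Rcpp::List cpp_simulate(const arma::mat& theta, double dt, double v0,
                        double vs, const arma::mat& znoise,
                        const arma::vec& x0, const arma::vec& tau) {
  int n = theta.n_rows;
  mat X(n, 8);
  vec yv(n);
  vec x = x0;
  double a11[4], a12[4], a21[4], a22[4], bv[4], bz[4];
  for (int j = 0; j < 4; ++j) {
    double E = std::exp(-dt / tau[j]);
    a11[j] = E * (1.0 + dt / tau[j]);
    a12[j] = E * dt;
    a21[j] = -E * dt / (tau[j] * tau[j]);
    a22[j] = E * (1.0 - dt / tau[j]);
    bv[j] = tau[j] * (1.0 - E * (1.0 + dt / tau[j]));
    bz[j] = dt * E / tau[j];
  }
  for (int t = 0; t < n; ++t) {
    X.row(t) = x.t();
    double u = theta(t, 0);
    double vp = x[0] - x[2] + u;  // v_ep - v_ip + u
    yv[t] = vp;
    double pre[4] = {x[4], x[6], vp, vp};  // v_e, v_i, v_p, v_p
    vec xn(8);
    for (int j = 0; j < 4; ++j) {
      double v = x[2 * j], z = x[2 * j + 1];
      double g = theta(t, j + 1) * sig_phi(pre[j], v0, vs);
      xn[2 * j] = a11[j] * v + a12[j] * z + bv[j] * g;
      xn[2 * j + 1] = a21[j] * v + a22[j] * z + bz[j] * g + znoise(t, j);
    }
    x = xn;
  }
  return Rcpp::List::create(Rcpp::Named("states") = X,
                            Rcpp::Named("observation") = yv);
}
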