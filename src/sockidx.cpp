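// Poisson-link delta GLMM with spatial (omega) and spatio-temporal (eps)
// Gaussian random fields on a knot mesh, Matern (nu = 1) correlation.
//
// Linear predictors per record i (year t, knot s):
//   p1_i = alpha1_t + omega1_s + eps1_{s,t} + X1_i . gamma1
//   p2_i = alpha2_t + omega2_s + eps2_{s,t} + X2_i . gamma2
// Poisson link: r1 = 1 - exp(-a * exp(p1)); r2 = a * exp(p1) / r1 * exp(p2)
// Observation: zero catch w.p. 1 - r1; positive catch ~ Gamma(mean r2, CV).
#define TMB_LIB_INIT R_init_sockidx
#include <TMB.hpp>

template <class Type>
Type objective_function<Type>::operator()() {
  using namespace density;

  DATA_VECTOR(catch_obs);      // catch per record (kg or count), >= 0
  DATA_IVECTOR(is_pos);        // 1 if catch_obs > 0
  DATA_VECTOR(log_area);       // log area swept (effort offset)
  DATA_IVECTOR(year_i);        // 0-based year index per record
  DATA_IVECTOR(knot_i);        // 0-based knot index per record
  DATA_MATRIX(X1);             // n x p covariate basis entering p1
  DATA_MATRIX(X2);             // n x p covariate basis entering p2
  DATA_MATRIX(D);              // knot-to-knot distance (km)
  DATA_SCALAR(kappa_scale);    // x* solving x K_1(x) = 0.1
  DATA_INTEGER(n_year);
  DATA_IVECTOR(include_field); // omega1, omega2, eps1, eps2 in {0,1}

  PARAMETER_VECTOR(alpha1);    // year intercepts, predictor 1
  PARAMETER_VECTOR(alpha2);    // year intercepts, predictor 2
  PARAMETER_VECTOR(gamma1);    // covariate coefficients, predictor 1
  PARAMETER_VECTOR(gamma2);    // covariate coefficients, predictor 2
  PARAMETER_VECTOR(log_sd);    // marginal log-SD: omega1, omega2, eps1, eps2
  PARAMETER(log_range);        // log distance (km) at which correlation = 0.1
  PARAMETER(log_cv);           // log CV of the positive-catch gamma

  PARAMETER_VECTOR(omega1);    // n_knot
  PARAMETER_VECTOR(omega2);    // n_knot
  PARAMETER_ARRAY(eps1);       // n_knot x n_year
  PARAMETER_ARRAY(eps2);       // n_knot x n_year

  int n = catch_obs.size();
  int n_knot = D.rows();

  Type range = exp(log_range);
  Type kappa = kappa_scale / range;
  matrix<Type> C(n_knot, n_knot);
  for (int i = 0; i < n_knot; i++) {
    C(i, i) = Type(1.0) + Type(1e-8);
    for (int j = 0; j < i; j++) {
      Type kd = kappa * D(i, j);
      Type c = kd * besselK(kd, Type(1.0));
      C(i, j) = c;
      C(j, i) = c;
    }
  }
  MVNORM_t<Type> mvn(C);
  vector<Type> sd = exp(log_sd);

  Type nll = Type(0.0);
  if (include_field(0)) nll += SCALE(mvn, sd(0))(omega1);
  if (include_field(1)) nll += SCALE(mvn, sd(1))(omega2);
  for (int t = 0; t < n_year; t++) {
    if (include_field(2)) {
      vector<Type> e(n_knot);
      for (int s = 0; s < n_knot; s++) e(s) = eps1(s, t);
      nll += SCALE(mvn, sd(2))(e);
    }
    if (include_field(3)) {
      vector<Type> e(n_knot);
      for (int s = 0; s < n_knot; s++) e(s) = eps2(s, t);
      nll += SCALE(mvn, sd(3))(e);
    }
  }

  Type cv = exp(log_cv);
  Type shape = Type(1.0) / (cv * cv);
  vector<Type> eta1(n), eta2(n);
  eta1.setZero();
  eta2.setZero();
  if (gamma1.size() > 0) eta1 = X1 * gamma1;
  if (gamma2.size() > 0) eta2 = X2 * gamma2;

  vector<Type> p1(n), p2(n);
  for (int i = 0; i < n; i++) {
    int t = year_i(i);
    int s = knot_i(i);
    Type lp1 = alpha1(t) + eta1(i);
    Type lp2 = alpha2(t) + eta2(i);
    if (include_field(0)) lp1 += omega1(s);
    if (include_field(2)) lp1 += eps1(s, t);
    if (include_field(1)) lp2 += omega2(s);
    if (include_field(3)) lp2 += eps2(s, t);
    p1(i) = lp1;
    p2(i) = lp2;

    Type log_m = log_area(i) + lp1;      // log(a * exp(p1))
    Type m = exp(log_m);
    if (is_pos(i) == 0) {
      nll += m;                          // -log(1 - r1) = a * exp(p1)
    } else {
      Type log_r1 = logspace_sub(Type(0.0), -m);
      Type log_r2 = log_m - log_r1 + lp2;
      nll -= log_r1;
      nll -= dgamma(catch_obs(i), shape, exp(log_r2) * cv * cv, true);
    }
  }

  REPORT(p1);
  REPORT(p2);
  ADREPORT(gamma1);
  ADREPORT(gamma2);
  return nll;
}
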