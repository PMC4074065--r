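#include <Rcpp.h>
using namespace Rcpp;

// Target-gene dynamics under saturable production with first-order decay:
//   dx/dt = vmax * (b + sum_A a_j u_j(t)^h) /
//           (1 + b + sum_A a_j u_j(t)^h + sum_I c_j u_j(t)^h) - d * x
// Regulator signals u^h are supplied pre-evaluated at substep midpoints
// (UA: activators, UC: inhibitors, each n_mid x n_reg). Production is
// treated as constant within each substep, which makes the linear-in-x
// update exact per substep:
//   x <- p/d + (x - p/d) * exp(-d*dt)   (x += p*dt when d ~ 0)

static inline void step_traj(const NumericMatrix& UA, const NumericMatrix& UC,
                             const NumericVector& a, const NumericVector& c,
                             double b, double vmax, double d,
                             double x0, double dt, int nsub,
                             int nstage, double* out) {
  const int na = UA.ncol(), nc = UC.ncol();
  double x = x0;
  out[0] = x0;
  const double ed = std::exp(-d * dt);
  int row = 0;
  for (int s = 1; s < nstage; ++s) {
    for (int k = 0; k < nsub; ++k, ++row) {
      double act = 0.0, inh = 0.0;
      for (int j = 0; j < na; ++j) act += a[j] * UA(row, j);
      for (int j = 0; j < nc; ++j) inh += c[j] * UC(row, j);
      double p = vmax * (b + act) / (1.0 + b + act + inh);
      if (d > 1e-12) {
        double xs = p / d;
        x = xs + (x - xs) * ed;
      } else {
        x += p * dt;
      }
    }
    out[s] = x;
  }
}

// [[Rcpp::export]]
NumericVector sim_traj_cpp(NumericMatrix UA, NumericMatrix UC,
                           NumericVector a, NumericVector c,
                           double b, double vmax, double d,
                           double x0, double dt, int nsub, int nstage) {
  NumericVector out(nstage);
  step_traj(UA, UC, a, c, b, vmax, d, x0, dt, nsub, nstage, out.begin());
  return out;
}

// Variance-weighted mean squared error of the simulated trajectory against
// the observed profile; the fit objective used by the ensemble search.
// [[Rcpp::export]]
double fit_error_cpp(NumericMatrix UA, NumericMatrix UC,
                     NumericVector a, NumericVector c,
                     double b, double vmax, double d,
                     double x0, double dt, int nsub,
                     NumericVector obs, NumericVector vars) {
  const int nstage = obs.size();
  std::vector<double> tr(nstage);
  step_traj(UA, UC, a, c, b, vmax, d, x0, dt, nsub, nstage, tr.data());
  double err = 0.0;
  for (int s = 0; s < nstage; ++s) {
    double r = tr[s] - obs[s];
    if (!std::isfinite(r)) return R_PosInf;
    err += r * r / vars[s];
  }
  return err / nstage;
}
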