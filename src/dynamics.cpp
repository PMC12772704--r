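// Fixed-step RK4 integration of the rate network
//   dx/dt = -x + W * tanh(x)
// and Benettin tangent-space iteration for the maximal Lyapunov exponent.
// The vector field is smooth and bounded (|W tanh(x)| <= ||W||_inf), so a
// fixed step keeps trajectories bit-reproducible across runs.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline vec vfield(const mat& W, const vec& x) {
  return -x + W * tanh(x);
}

// [[Rcpp::export]]
Rcpp::List rk4_integrate_cpp(const arma::mat& W, const arma::vec& x0,
                             double dt, double t_max, int store_stride,
                             double check_interval, double conv_tol,
                             int n_consec) {
  const int N = W.n_rows;
  const int n_steps = (int) std::round(t_max / dt);
  const int check_every = std::max(1, (int) std::round(check_interval / dt));
  const double sqrtN = std::sqrt((double) N);

  std::vector<double> dnorms; dnorms.reserve(n_steps + 1);
  std::vector<int> stored_idx;
  std::vector<vec> states, derivs;

  vec x = x0;
  vec k1 = vfield(W, x);
  dnorms.push_back(norm(k1));
  stored_idx.push_back(0); states.push_back(x); derivs.push_back(k1);

  bool converged = false;
  double t_fp = NA_REAL;
  int streak = 0;
  double streak_start = NA_REAL;
  int last = 0;

  for (int s = 1; s <= n_steps; ++s) {
    vec k2 = vfield(W, x + 0.5 * dt * k1);
    vec k3 = vfield(W, x + 0.5 * dt * k2);
    vec k4 = vfield(W, x + dt * k3);
    x += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (!x.is_finite()) Rcpp::stop("state became non-finite at t = %f", s * dt);
    k1 = vfield(W, x);
    dnorms.push_back(norm(k1));
    last = s;
    bool at_store = (s % store_stride == 0) || (s == n_steps);
    if (at_store) { stored_idx.push_back(s); states.push_back(x); derivs.push_back(k1); }
    if (s % check_every == 0) {
      if (dnorms.back() / sqrtN < conv_tol) {
        if (streak == 0) streak_start = s * dt;
        ++streak;
        if (streak >= n_consec) {
          converged = true;
          t_fp = streak_start;
          if (!at_store) { stored_idx.push_back(s); states.push_back(x); derivs.push_back(k1); }
          break;
        }
      } else {
        streak = 0;
      }
    }
  }

  const int T = states.size();
  mat Xs(T, N), Ds(T, N);
  vec ts(T);
  for (int i = 0; i < T; ++i) {
    Xs.row(i) = states[i].t();
    Ds.row(i) = derivs[i].t();
    ts(i) = stored_idx[i] * dt;
  }
  vec dn(dnorms.size());
  for (size_t i = 0; i < dnorms.size(); ++i) dn(i) = dnorms[i];

  return Rcpp::List::create(
    Rcpp::Named("times") = ts,
    Rcpp::Named("states") = Xs,
    Rcpp::Named("derivs") = Ds,
    Rcpp::Named("deriv_norms") = dn,
    Rcpp::Named("deriv_norm_dt") = dt,
    Rcpp::Named("t_end") = last * dt,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("t_fp") = t_fp);
}

// Joint RK4 on the trajectory x and one tangent vector v with
//   dv/dt = J(x) v = -v + W (sech^2(x) % v),
// renormalizing v every t_renorm time units and averaging log stretch
// factors over the measurement window (Benettin's method).
// [[Rcpp::export]]
Rcpp::List benettin_cpp(const arma::mat& W, const arma::vec& x0,
                        const arma::vec& v0, double dt, double t_transient,
                        double t_measure, double t_renorm) {
  const int renorm_every = std::max(1, (int) std::round(t_renorm / dt));
  const int n_trans = (int) std::round(t_transient / dt);
  const int n_total = n_trans + (int) std::round(t_measure / dt);

  vec x = x0;
  vec v = v0 / norm(v0);
  double log_sum = 0.0;   // accumulated over the measurement window
  double measured = 0.0;  // time actually measured

  for (int s = 1; s <= n_total; ++s) {
    // stage derivatives for (x, v); J depends on the stage state of x
    vec k1x = vfield(W, x);
    vec s1 = 1.0 - square(tanh(x));
    vec k1v = -v + W * (s1 % v);

    vec x2 = x + 0.5 * dt * k1x;
    vec k2x = vfield(W, x2);
    vec s2 = 1.0 - square(tanh(x2));
    vec v2 = v + 0.5 * dt * k1v;
    vec k2v = -v2 + W * (s2 % v2);

    vec x3 = x + 0.5 * dt * k2x;
    vec k3x = vfield(W, x3);
    vec s3 = 1.0 - square(tanh(x3));
    vec v3 = v + 0.5 * dt * k2v;
    vec k3v = -v3 + W * (s3 % v3);

    vec x4 = x + dt * k3x;
    vec k4x = vfield(W, x4);
    vec s4 = 1.0 - square(tanh(x4));
    vec v4 = v + dt * k3v;
    vec k4v = -v4 + W * (s4 % v4);

    x += (dt / 6.0) * (k1x + 2.0 * k2x + 2.0 * k3x + k4x);
    v += (dt / 6.0) * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);

    if (s % renorm_every == 0 || s == n_total) {
      double nv = norm(v);
      if (nv <= 0 || !std::isfinite(nv))
        Rcpp::stop("tangent vector degenerated during Lyapunov iteration");
      if (s > n_trans) {
        log_sum += std::log(nv);
        // time elapsed since the previous renormalization inside the window
        int since = (s % renorm_every == 0) ? renorm_every : (s % renorm_every);
        measured += since * dt;
      }
      v /= nv;
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("lambda_max") = log_sum / measured,
    Rcpp::Named("t_measured") = measured);
}
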