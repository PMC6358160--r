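// Steady-state solver for the three-population rate model.
//
// With the GC time constant set to 0 the GC rates follow their inputs
// algebraically, leaving coupled ODEs for the MC activities M and the CC
// activities C. Both are relaxed by explicit Euler until the maximum
// absolute rate of change drops below `tol`.
//
// The M-subsystem Jacobian is -(I + g * W_MG D W_MG^T) on the active set
// (D a 0/1 diagonal), so its stiffness grows with the number of GCs and
// with g. The initial step is therefore bounded by a spectral estimate of
// W_MG (power iteration), and the step is halved whenever the residual
// grows persistently, which keeps the scheme inside its stability region
// without assuming anything about the wiring.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double sigma_max_sq(const mat& W) {
  if (W.n_cols == 0 || W.n_rows == 0) return 0.0;
  vec v(W.n_cols, fill::ones);
  v /= norm(v);
  double s = 0.0;
  for (int it = 0; it < 30; ++it) {
    vec u = W * v;
    double nu = norm(u);
    if (nu == 0.0) return 0.0;
    v = W.t() * (u / nu);
    s = norm(v);
    if (s == 0.0) return 0.0;
    v /= s;
  }
  return s; // ||W^T W v|| -> sigma_max^2
}

// [[Rcpp::export]]
Rcpp::List steady_state_cpp(const arma::vec& S, const arma::vec& ctx_drive,
                            const arma::mat& W_MG, const arma::mat& W_GC,
                            const arma::mat& W_CM, const arma::mat& W_CC,
                            double g, double w_GC, double w_CM, double w_inh,
                            double alpha, double M_sp, double G_th,
                            double gamma_C, double C_th, double C_max,
                            double tau_M, double tau_C, double dt_max,
                            double tol, double t_max) {
  const uword n_mc = W_MG.n_rows;
  const uword n_g  = W_MG.n_cols;
  const uword n_cc = W_CM.n_rows;

  vec M(n_mc); M.fill(M_sp);
  vec C(n_cc, fill::zeros);
  vec G(n_g, fill::zeros);

  // stability-aware initial step (Gershgorin-free spectral bound on the
  // dominant M-M block); dt never exceeds dt_max * min(tau)
  double s2 = sigma_max_sq(W_MG);
  double L = 1.0 / tau_M + g * s2 / tau_M;
  double dt = std::min(dt_max * std::min(tau_M, tau_C), 1.8 / std::max(L, 1.0));

  double t = 0.0;
  double res = datum::inf, res_prev = datum::inf;
  int grow = 0;
  bool converged = false;
  int iter = 0;
  const int max_iter = 2000000;

  vec sig(n_cc), dM(n_mc), dC(n_cc);

  while (iter < max_iter && t < t_max) {
    ++iter;
    if (n_cc > 0)
      sig = C_max / (1.0 + exp(-gamma_C * (C - C_th)));

    vec Mp = clamp(M, 0.0, datum::inf);
    if (n_g > 0) {
      G = W_MG.t() * Mp;
      if (n_cc > 0) G += w_GC * (W_GC * sig);
    }

    dM = (-M + S + M_sp) / tau_M;
    if (n_g > 0) {
      vec Gth = clamp(G - G_th, 0.0, datum::inf);
      dM -= g * (W_MG * Gth) / tau_M;
    }

    if (n_cc > 0) {
      double sig_sum = accu(sig);
      dC = (-C + ctx_drive + w_CM * (W_CM * Mp)
            + alpha * (W_CC * sig) - w_inh * (sig_sum - sig)) / tau_C;
    }

    res = norm(dM, "inf");
    if (n_cc > 0) res = std::max(res, norm(dC, "inf"));
    if (res <= tol) { converged = true; break; }

    // residual-growth backoff: persistent growth means dt is outside the
    // stability region of the current active set
    if (res > 1.02 * res_prev) {
      if (++grow >= 3 && dt > 1e-5) { dt *= 0.5; grow = 0; }
    } else {
      grow = 0;
    }
    res_prev = res;

    M += dt * dM;
    if (n_cc > 0) C += dt * dC;
    t += dt;
  }

  // final algebraic GC evaluation at the returned (M, C)
  if (n_cc > 0)
    sig = C_max / (1.0 + exp(-gamma_C * (C - C_th)));
  if (n_g > 0) {
    G = W_MG.t() * clamp(M, 0.0, datum::inf);
    if (n_cc > 0) G += w_GC * (W_GC * sig);
  }

  return Rcpp::List::create(
    Rcpp::Named("M") = M, Rcpp::Named("G") = G, Rcpp::Named("C") = C,
    Rcpp::Named("residual") = res, Rcpp::Named("converged") = converged,
    Rcpp::Named("iterations") = iter);
}
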