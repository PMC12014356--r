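// Firth-penalized logistic regression core.
//
// Maximizes l(beta) + 0.5 * log det I(beta) (Jeffreys-prior penalty) by
// Newton-Raphson on the hat-adjusted score, with step-halving so the
// penalized log-likelihood never decreases. Supports fixing one
// coefficient, which is what the penalized likelihood-ratio test and the
// profile-penalized-likelihood confidence bounds need, plus a batched
// scan entry point (one carrier column swapped against fixed covariates,
// warm-started) for the genome-wide breakpoint tests.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double plik(const mat& X, const vec& y, const vec& beta,
                   vec& p, mat& XtWX) {
  vec eta = X * beta;
  p = 1.0 / (1.0 + exp(-eta));
  p = clamp(p, 1e-10, 1.0 - 1e-10);
  vec w = p % (1.0 - p);
  XtWX = X.t() * (X.each_col() % w);
  double ld, sign;
  log_det(ld, sign, XtWX);
  double ll = accu(y % log(p) + (1.0 - y) % log(1.0 - p));
  return ll + 0.5 * ld;
}

// Newton-Raphson with hat-adjusted score over coordinates free_idx;
// beta is updated in place. Returns penalized log-likelihood; XtWX holds
// the information at the solution.
static double newton_core(const mat& X, const vec& y, vec& beta,
                          const uvec& free_idx, mat& XtWX,
                          bool& converged, int& iter_out,
                          int max_iter, double tol, double max_step) {
  vec p;
  double pl = plik(X, y, beta, p, XtWX);
  converged = false;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    vec w = p % (1.0 - p);
    mat Vinv = inv_sympd(symmatu(XtWX));
    vec h = w % sum((X * Vinv) % X, 1);
    vec U = X.t() * (y - p + h % (0.5 - p));
    vec Uf = U.elem(free_idx);
    if (norm(Uf, "inf") < tol) { converged = true; break; }
    mat Iff = XtWX.submat(free_idx, free_idx);
    vec delta;
    bool ok = solve(delta, symmatu(Iff), Uf,
                    solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) break;
    double mx = norm(delta, "inf");
    if (mx > max_step) delta *= max_step / mx;
    double step = 1.0;
    vec beta_new; vec p_new; mat XtWX_new;
    double pl_new = -datum::inf;
    for (int h2 = 0; h2 < 30; ++h2) {
      beta_new = beta;
      beta_new.elem(free_idx) += step * delta;
      pl_new = plik(X, y, beta_new, p_new, XtWX_new);
      if (pl_new >= pl - 1e-12) break;
      step *= 0.5;
    }
    if (pl_new < pl - 1e-12) break;   // no improving step found
    bool tiny = norm(step * delta, "inf") < tol;
    beta = beta_new; p = p_new; XtWX = XtWX_new; pl = pl_new;
    if (tiny) { converged = true; break; }
  }
  if (!converged) {
    vec w = p % (1.0 - p);
    mat Vinv = inv_sympd(symmatu(XtWX));
    vec h = w % sum((X * Vinv) % X, 1);
    vec U = X.t() * (y - p + h % (0.5 - p));
    if (norm(U.elem(free_idx), "inf") < tol) converged = true;
  }
  iter_out = iter;
  return pl;
}

// [[Rcpp::export(name = ".firth_newton")]]
Rcpp::List firth_newton(const arma::mat& X, const arma::vec& y,
                        int fixed = -1, double fixed_value = 0.0,
                        int max_iter = 50, double tol = 1e-5,
                        double max_step = 5.0,
                        Rcpp::Nullable<Rcpp::NumericVector> init =
                          R_NilValue) {
  const uword k = X.n_cols;
  uvec free_idx;
  if (fixed >= 0) {
    std::vector<uword> f;
    for (uword j = 0; j < k; ++j) if ((int)j != fixed) f.push_back(j);
    free_idx = uvec(f);
  } else {
    free_idx = regspace<uvec>(0, k - 1);
  }
  vec beta(k, fill::zeros);
  if (init.isNotNull()) beta = Rcpp::as<vec>(init);
  if (fixed >= 0) beta(fixed) = fixed_value;

  mat XtWX;
  bool converged; int iter;
  double pl = newton_core(X, y, beta, free_idx, XtWX, converged, iter,
                          max_iter, tol, max_step);
  mat Vfull = inv_sympd(symmatu(XtWX));
  return Rcpp::List::create(
    Rcpp::Named("beta") = beta,
    Rcpp::Named("plik") = pl,
    Rcpp::Named("var") = Vfull,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("n_iter") = iter);
}

// Batched per-breakpoint Firth association: status ~ covariates + carrier.
// Xbase holds intercept + covariates (all samples); for breakpoint t the
// samples in miss[t] are dropped and the carrier indicator is 1 for
// alt[t]. Full and carrier-fixed-at-zero fits give the penalized-LRT
// two-sided p for the carrier coefficient. Warm-started from the
// covariate-only fit.
// [[Rcpp::export(name = ".firth_scan")]]
Rcpp::NumericMatrix firth_scan(const arma::mat& Xbase, const arma::vec& y,
                               const Rcpp::List& alt,
                               const Rcpp::List& miss,
                               int max_iter = 50, double tol = 1e-5,
                               double max_step = 5.0) {
  const uword n = Xbase.n_rows, k = Xbase.n_cols;
  const int m = alt.size();
  Rcpp::NumericMatrix out(m, 5);
  colnames(out) = Rcpp::CharacterVector::create(
    "beta", "se", "p_two_sided", "converged", "n_used");

  // covariate-only warm start on the full data
  uvec all_base = regspace<uvec>(0, k - 1);
  vec warm(k, fill::zeros);
  { mat XtWX; bool cv; int it;
    newton_core(Xbase, y, warm, all_base, XtWX, cv, it, max_iter, tol,
                max_step); }
  uvec free_full = regspace<uvec>(0, k);      // k+1 coefficients
  uvec free_con  = regspace<uvec>(0, k - 1);  // carrier fixed

  for (int t = 0; t < m; ++t) {
    uvec alt_i = Rcpp::as<uvec>(alt[t]);
    uvec miss_i = Rcpp::as<uvec>(miss[t]);
    mat X; vec yy; vec carrier;
    if (miss_i.n_elem == 0) {
      carrier = zeros<vec>(n);
      carrier.elem(alt_i).ones();
      X = join_rows(Xbase, carrier);
      yy = y;
    } else {
      uvec keep = regspace<uvec>(0, n - 1);
      std::vector<uword> kp; kp.reserve(n - miss_i.n_elem);
      std::vector<bool> drop(n, false);
      for (uword q = 0; q < miss_i.n_elem; ++q) drop[miss_i(q)] = true;
      vec car_full = zeros<vec>(n);
      car_full.elem(alt_i).ones();
      for (uword i = 0; i < n; ++i) if (!drop[i]) kp.push_back(i);
      uvec kpv(kp);
      X = join_rows(Xbase.rows(kpv), car_full.elem(kpv));
      yy = y.elem(kpv);
    }
    vec beta = join_cols(warm, vec{0.0});
    mat XtWX; bool cv_full; int it;
    double pl_full = newton_core(X, yy, beta, free_full, XtWX, cv_full,
                                 it, max_iter, tol, max_step);
    double se = datum::nan;
    mat Vfull;
    if (inv_sympd(Vfull, symmatu(XtWX))) se = std::sqrt(Vfull(k, k));
    vec beta0 = beta; beta0(k) = 0.0;
    bool cv_con; int it2;
    mat XtWX0;
    double pl_con = newton_core(X, yy, beta0, free_con, XtWX0, cv_con,
                                it2, max_iter, tol, max_step);
    double lrt = 2.0 * (pl_full - pl_con);
    if (lrt < 0) lrt = 0;
    out(t, 0) = beta(k);
    out(t, 1) = se;
    out(t, 2) = R::pchisq(lrt, 1.0, 0, 0);
    out(t, 3) = (cv_full && cv_con) ? 1.0 : 0.0;
    out(t, 4) = (double)yy.n_elem;
  }
  return out;
}

// Two-stage (null-model offset) per-breakpoint Firth test. eta0 is the
// linear predictor of the covariate-only null model; per breakpoint only
// the carrier coefficient is estimated, so non-carrier terms cancel in
// the penalized LRT and each test touches carrier rows only.
// [[Rcpp::export(name = ".firth_offset_scan")]]
Rcpp::NumericMatrix firth_offset_scan(const arma::vec& eta0,
                                      const arma::vec& y,
                                      const Rcpp::List& alt,
                                      int max_iter = 50,
                                      double tol = 1e-5,
                                      double max_step = 5.0) {
  const int m = alt.size();
  Rcpp::NumericMatrix out(m, 4);
  colnames(out) = Rcpp::CharacterVector::create(
    "beta", "se", "p_two_sided", "converged");
  for (int t = 0; t < m; ++t) {
    uvec idx = Rcpp::as<uvec>(alt[t]);
    vec e0 = eta0.elem(idx);
    vec yy = y.elem(idx);
    const uword nc = idx.n_elem;
    // penalized log-lik over carrier rows for carrier coefficient b
    auto pl1 = [&](double b, double& info) {
      vec p = 1.0 / (1.0 + exp(-(e0 + b)));
      p = clamp(p, 1e-10, 1.0 - 1e-10);
      info = accu(p % (1.0 - p));
      return accu(yy % log(p) + (1.0 - yy) % log(1.0 - p)) +
             0.5 * std::log(info);
    };
    double b = 0.0, info;
    double pl = pl1(b, info);
    double pl0 = pl;                       // value at b = 0 (for LRT)
    bool conv = false;
    for (int it = 0; it < max_iter; ++it) {
      vec p = 1.0 / (1.0 + exp(-(e0 + b)));
      p = clamp(p, 1e-10, 1.0 - 1e-10);
      vec w = p % (1.0 - p);
      double I = accu(w);
      vec h = w / I;
      double U = accu((yy - p) + h % (0.5 - p));
      if (std::abs(U) < tol) { conv = true; break; }
      double delta = U / I;
      if (std::abs(delta) > max_step) delta = std::copysign(max_step, delta);
      double step = 1.0, bn = b, pln = -datum::inf, in2;
      for (int h2 = 0; h2 < 30; ++h2) {
        bn = b + step * delta;
        pln = pl1(bn, in2);
        if (pln >= pl - 1e-12) break;
        step *= 0.5;
      }
      if (pln < pl - 1e-12) break;
      bool tiny = std::abs(step * delta) < tol;
      b = bn; pl = pln; info = in2;
      if (tiny) { conv = true; break; }
    }
    double lrt = 2.0 * (pl - pl0);
    if (lrt < 0) lrt = 0;
    out(t, 0) = b;
    out(t, 1) = 1.0 / std::sqrt(info);
    out(t, 2) = R::pchisq(lrt, 1.0, 0, 0);
    out(t, 3) = conv ? 1.0 : 0.0;
    (void)nc;
  }
  return out;
}
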