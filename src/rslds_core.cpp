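// Inner numerical kernels of the rSLDS mean-field EM: the Gaussian-chain
// smoother (information-form Kalman smoothing with state-averaged
// dynamics), the discrete forward-backward pass, the expected dynamics
// quadratic forms, the transition log-probabilities and the dynamics
// sufficient statistics.  All heavy per-bin loops live here.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double lse_vec(const rowvec& v) {
  double m = v.max();
  if (!std::isfinite(m)) return m;
  return m + std::log(accu(exp(v - m)));
}

// [[Rcpp::export]]
Rcpp::List cpp_chain_smoother(const arma::mat& Y, const arma::mat& gamma,
                              const arma::cube& A, const arma::mat& b,
                              const arma::cube& Q, const arma::mat& C,
                              const arma::vec& d, const arma::vec& sdiag,
                              const arma::ivec& seg, double prior_var) {
  const uword D = A.n_rows, T = Y.n_cols, K = A.n_slices;
  cube Qinv(D, D, K), AtQinv(D, D, K), AtQinvA(D, D, K);
  mat Qinv_b(D, K), AtQinv_b(D, K);
  for (uword k = 0; k < K; ++k) {
    Qinv.slice(k) = inv_sympd(Q.slice(k));
    AtQinv.slice(k) = A.slice(k).t() * Qinv.slice(k);
    AtQinvA.slice(k) = AtQinv.slice(k) * A.slice(k);
    Qinv_b.col(k) = Qinv.slice(k) * b.col(k);
    AtQinv_b.col(k) = AtQinv.slice(k) * b.col(k);
  }
  mat Cs = C.each_col() / sdiag;       // S^-1 C
  mat CtSinvC = C.t() * Cs;
  mat em_h = Cs.t() * (Y.each_col() - d);

  std::vector<bool> first(T), last(T);
  for (uword t = 0; t < T; ++t) {
    first[t] = (t == 0) || (seg[t] != seg[t - 1]);
    last[t] = (t == T - 1) || (seg[t + 1] != seg[t]);
  }
  cube F(D, D, T), B(D, D, T, fill::zeros);
  mat g(D, T);
  double logdetJ = 0.0;
  mat Jd(D, D);
  vec h(D);
  for (uword t = 0; t < T; ++t) {
    Jd = CtSinvC;
    h = em_h.col(t);
    if (first[t]) {
      Jd.diag() += 1.0 / prior_var;
    } else {
      for (uword k = 0; k < K; ++k) {
        double w = gamma(t, k);
        if (w > 1e-12) { Jd += w * Qinv.slice(k); h += w * Qinv_b.col(k); }
      }
    }
    if (!last[t]) {
      mat Bt(D, D, fill::zeros);
      for (uword k = 0; k < K; ++k) {
        double w = gamma(t + 1, k);
        if (w > 1e-12) {
          Jd += w * AtQinvA.slice(k);
          h -= w * AtQinv_b.col(k);
          Bt -= w * AtQinv.slice(k);
        }
      }
      B.slice(t) = Bt;
    }
    if (first[t]) {
      F.slice(t) = Jd;
      g.col(t) = h;
    } else {
      mat FiB = solve(F.slice(t - 1), B.slice(t - 1), solve_opts::likely_sympd);
      F.slice(t) = Jd - B.slice(t - 1).t() * FiB;
      g.col(t) = h - FiB.t() * g.col(t - 1);
    }
    F.slice(t) = 0.5 * (F.slice(t) + F.slice(t).t());
    double ld, sign;
    log_det(ld, sign, F.slice(t));
    logdetJ += ld;
  }
  mat mu(D, T);
  cube Sigma(D, D, T), Cross(D, D, T, fill::zeros);
  mat Finv = inv_sympd(F.slice(T - 1));
  mu.col(T - 1) = Finv * g.col(T - 1);
  Sigma.slice(T - 1) = Finv;
  for (sword t = T - 2; t >= 0; --t) {
    Finv = inv_sympd(F.slice(t));
    if (last[t]) {
      mu.col(t) = Finv * g.col(t);
      Sigma.slice(t) = Finv;
    } else {
      mu.col(t) = Finv * (g.col(t) - B.slice(t) * mu.col(t + 1));
      mat FB = Finv * B.slice(t);
      Sigma.slice(t) = Finv + FB * Sigma.slice(t + 1) * FB.t();
      Cross.slice(t) = -FB * Sigma.slice(t + 1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("mu") = mu,
                            Rcpp::Named("Sigma") = Sigma,
                            Rcpp::Named("Cross") = Cross,
                            Rcpp::Named("logdetJ") = logdetJ);
}

// [[Rcpp::export]]
arma::mat cpp_dyn_quad(const arma::mat& mu, const arma::cube& Sigma,
                       const arma::cube& Cross, const arma::cube& A,
                       const arma::mat& b, const arma::cube& Q,
                       const arma::ivec& seg) {
  const uword D = A.n_rows, T = mu.n_cols, K = A.n_slices;
  cube Qinv(D, D, K);
  vec logdetQ(K);
  for (uword k = 0; k < K; ++k) {
    Qinv.slice(k) = inv_sympd(Q.slice(k));
    double ld, sign;
    log_det(ld, sign, Q.slice(k));
    logdetQ[k] = ld;
  }
  mat out(T, K);
  out.fill(datum::nan);
  const double c0 = D * std::log(2.0 * datum::pi);
  for (uword t = 1; t < T; ++t) {
    if (seg[t] != seg[t - 1]) continue;
    mat Ptt = Sigma.slice(t) + mu.col(t) * mu.col(t).t();
    mat Pp = Sigma.slice(t - 1) + mu.col(t - 1) * mu.col(t - 1).t();
    mat Ecross = Cross.slice(t - 1) + mu.col(t - 1) * mu.col(t).t();
    for (uword k = 0; k < K; ++k) {
      const mat& Qi = Qinv.slice(k);
      const mat& Ak = A.slice(k);
      double q = accu(Qi % Ptt) - 2.0 * accu((Qi * Ak) % Ecross.t()) +
        accu((Ak.t() * Qi * Ak) % Pp) -
        2.0 * dot(b.col(k), Qi * mu.col(t)) +
        2.0 * dot(b.col(k), Qi * (Ak * mu.col(t - 1))) +
        dot(b.col(k), Qi * b.col(k));
      out(t, k) = -0.5 * (c0 + logdetQ[k] + q);
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_trans_logprob(const arma::mat& L, const arma::mat& Rw,
                             const arma::mat& mu, const arma::ivec& seg) {
  const uword K = L.n_rows, T = mu.n_cols;
  cube ltr(K, K, T);
  ltr.fill(datum::nan);
  mat Rx = Rw * mu;                    // K x T
  for (uword t = 1; t < T; ++t) {
    if (seg[t] != seg[t - 1]) continue;
    for (uword j = 0; j < K; ++j) {
      rowvec eta = L.row(j) + Rx.col(t - 1).t();
      ltr.slice(t).row(j) = eta - lse_vec(eta);
    }
  }
  return ltr;
}

// [[Rcpp::export]]
Rcpp::List cpp_hmm_fb(const arma::mat& lphi, const arma::cube& ltr,
                      const arma::ivec& seg) {
  const uword T = lphi.n_rows, K = lphi.n_cols;
  mat la(T, K), lb(T, K, fill::zeros);
  std::vector<bool> first(T), last(T);
  for (uword t = 0; t < T; ++t) {
    first[t] = (t == 0) || (seg[t] != seg[t - 1]);
    last[t] = (t == T - 1) || (seg[t + 1] != seg[t]);
  }
  double loglik = 0.0;
  for (uword t = 0; t < T; ++t) {
    rowvec ph = lphi.row(t);
    ph.replace(datum::nan, 0.0);
    if (first[t]) {
      la.row(t) = ph - std::log((double)K);
    } else {
      for (uword k = 0; k < K; ++k) {
        rowvec v = la.row(t - 1) + ltr.slice(t).col(k).t();
        la(t, k) = lse_vec(v) + ph[k];
      }
    }
  }
  for (sword t = T - 1; t >= 0; --t) {
    if (last[t]) {
      lb.row(t).zeros();
      loglik += lse_vec(la.row(t));
    } else {
      rowvec ph = lphi.row(t + 1);
      ph.replace(datum::nan, 0.0);
      for (uword j = 0; j < K; ++j) {
        rowvec v = ltr.slice(t + 1).row(j) + ph + lb.row(t + 1);
        lb(t, j) = lse_vec(v);
      }
    }
  }
  mat lg = la + lb;
  mat gamma(T, K);
  for (uword t = 0; t < T; ++t) {
    rowvec v = lg.row(t);
    gamma.row(t) = exp(v - lse_vec(v));
  }
  cube xi(K, K, T, fill::zeros);
  for (uword t = 1; t < T; ++t) {
    if (first[t]) continue;
    rowvec ph = lphi.row(t);
    ph.replace(datum::nan, 0.0);
    mat lx(K, K);
    for (uword j = 0; j < K; ++j) {
      lx.row(j) = la(t - 1, j) + ltr.slice(t).row(j) + ph + lb.row(t);
    }
    double m = lx.max();
    mat ex = exp(lx - (m + std::log(accu(exp(lx - m)))));
    xi.slice(t) = ex;
  }
  double ent = 0.0;
  for (uword t = 0; t < T; ++t) {
    if (first[t]) {
      for (uword k = 0; k < K; ++k) {
        double g = gamma(t, k);
        if (g > 0) ent -= g * std::log(g);
      }
    } else {
      for (uword j = 0; j < K; ++j) {
        double gp = std::max(gamma(t - 1, j), 1e-300);
        for (uword k = 0; k < K; ++k) {
          double x = xi(j, k, t);
          if (x > 0) ent -= x * std::log(std::max(x / gp, 1e-300));
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gamma") = gamma,
                            Rcpp::Named("xi") = xi,
                            Rcpp::Named("entropy") = ent,
                            Rcpp::Named("loglik") = loglik);
}

// [[Rcpp::export]]
Rcpp::List cpp_dyn_suffstats(const arma::mat& mu, const arma::cube& Sigma,
                             const arma::cube& Cross, const arma::mat& gamma,
                             const arma::ivec& seg) {
  const uword D = mu.n_rows, T = mu.n_cols, K = gamma.n_cols;
  cube Sxx(D + 1, D + 1, K, fill::zeros);
  cube Syx(D, D + 1, K, fill::zeros);
  cube Syy(D, D, K, fill::zeros);
  vec nk(K, fill::zeros);
  mat XX(D + 1, D + 1);
  mat YX(D, D + 1);
  for (uword t = 1; t < T; ++t) {
    if (seg[t] != seg[t - 1]) continue;
    mat Ptt = Sigma.slice(t) + mu.col(t) * mu.col(t).t();
    mat Pp = Sigma.slice(t - 1) + mu.col(t - 1) * mu.col(t - 1).t();
    mat Ecross_t = Cross.slice(t - 1).t() + mu.col(t) * mu.col(t - 1).t();
    XX.submat(0, 0, D - 1, D - 1) = Pp;
    XX.submat(0, D, D - 1, D) = mu.col(t - 1);
    XX.submat(D, 0, D, D - 1) = mu.col(t - 1).t();
    XX(D, D) = 1.0;
    YX.cols(0, D - 1) = Ecross_t;
    YX.col(D) = mu.col(t);
    for (uword k = 0; k < K; ++k) {
      double g = gamma(t, k);
      if (g < 1e-12) continue;
      Sxx.slice(k) += g * XX;
      Syx.slice(k) += g * YX;
      Syy.slice(k) += g * Ptt;
      nk[k] += g;
    }
  }
  return Rcpp::List::create(Rcpp::Named("Sxx") = Sxx,
                            Rcpp::Named("Syx") = Syx,
                            Rcpp::Named("Syy") = Syy,
                            Rcpp::Named("nk") = nk);
}
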