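// Vectorized evaluation of the log unnormalized posterior of the
// latent-trait MPT model (group-level covariance integrated out).
//
// psi rows: (mu[P], xi_trans[P], delta[F], omega_1[P], ..., omega_I[P])
// counts:   I x (ncat * ncond), condition-major category blocks
// V, W:     B x P branch exponent matrices (theta^V * (1-theta)^W)
// branch_cat: 0-based global category index per branch
// delta_map:  per parameter, 0-based index into the delta block, -1 fixed
// const_terms: all draw-independent log terms (multinomial coefficients,
//              prior and group-factor normalizing constants)
// gf_coef:  (nu + I) / 2, multiplies -log|Omega'Omega + I_P|
//
// per_participant = true returns the n x I matrix of raw per-participant
// log-likelihoods (no priors or constants; used inside MCMC sweeps where
// those terms cancel or are added in R).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// [[Rcpp::export]]
SEXP cpp_lt_logpost(const arma::mat& psi, const arma::mat& counts,
                    const arma::mat& V, const arma::mat& W,
                    const arma::ivec& branch_cat,
                    int P, int I, int ncond,
                    const arma::vec& cond_signs,
                    const arma::ivec& delta_map,
                    double xi_max, double sigma_delta,
                    double const_terms, double gf_coef,
                    bool per_participant) {
  const uword n = psi.n_rows;
  const uword B = V.n_rows;
  const uword ncat = counts.n_cols / ncond;
  const uword F = psi.n_cols - (uword)(P * (I + 2));

  vec out(n, fill::zeros);
  mat out_pp;
  if (per_participant) out_pp.set_size(n, I);

  vec theta(P), catp(ncat);
  mat Omega(I, P), M(P, P);

  for (uword j = 0; j < n; ++j) {
    const rowvec row = psi.row(j);
    vec mu(P), xi(P), dvec(P, fill::zeros);
    for (int p = 0; p < P; ++p) {
      mu(p) = row(p);
      xi(p) = xi_max * normcdf(row(P + p));
      if (delta_map(p) >= 0) dvec(p) = row(2 * P + delta_map(p));
    }
    for (int i = 0; i < I; ++i)
      for (int p = 0; p < P; ++p)
        Omega(i, p) = row(2 * P + F + (uword)i * P + p);

    double total = 0.0;
    bool dead = false;
    for (int i = 0; i < I && !(dead && !per_participant); ++i) {
      double ll_i = 0.0;
      for (int c = 0; c < ncond; ++c) {
        for (int p = 0; p < P; ++p)
          theta(p) = normcdf(mu(p) + cond_signs(c) * dvec(p) +
                             xi(p) * Omega(i, p));
        catp.zeros();
        for (uword b = 0; b < B; ++b) {
          double pr = 1.0;
          for (int p = 0; p < P; ++p) {
            double v = V(b, p), w = W(b, p);
            if (v > 0) pr *= (v == 1.0) ? theta(p) : std::pow(theta(p), v);
            if (w > 0) pr *= (w == 1.0) ? (1.0 - theta(p))
                                        : std::pow(1.0 - theta(p), w);
          }
          catp(branch_cat(b)) += pr;
        }
        for (uword l = 0; l < ncat; ++l) {
          double cnt = counts(i, (uword)c * ncat + l);
          if (cnt > 0) {
            if (catp(l) <= 0.0) { ll_i = -datum::inf; break; }
            ll_i += cnt * std::log(catp(l));
          }
        }
        if (!std::isfinite(ll_i)) break;
      }
      if (per_participant) out_pp(j, i) = ll_i;
      total += ll_i;
      if (!std::isfinite(ll_i)) dead = true;
    }
    if (per_participant) continue;

    if (dead) { out(j) = -datum::inf; continue; }

    // priors on mu, xi_trans, delta (normalizing constants in const_terms)
    double pr = -0.5 * dot(mu, mu);
    for (int p = 0; p < P; ++p) pr -= 0.5 * row(P + p) * row(P + p);
    for (uword f = 0; f < F; ++f) {
      double d = row(2 * P + f);
      pr -= d * d / (2.0 * sigma_delta * sigma_delta);
    }

    // Q-marginalized group-level factor: -(nu+I)/2 log|Omega'Omega + I|
    M = Omega.t() * Omega;
    M.diag() += 1.0;
    double ldet, sign;
    log_det(ldet, sign, M);

    out(j) = total + pr - gf_coef * ldet + const_terms;
  }

  if (per_participant) return Rcpp::wrap(out_pp);
  return Rcpp::wrap(out);
}
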