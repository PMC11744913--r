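#include <Rcpp.h>
using namespace Rcpp;

// log of the angular projected-normal integral term:
// log( 1 + t * Phi(t) / phi(t) ), numerically stable for large |t|
static double log_pn_term(double t) {
  if (t > 6.0) {
    // Phi(t) ~ 1 and the +1 is negligible next to t/phi(t)
    return std::log(t) + 0.5 * t * t + 0.5 * std::log(2.0 * M_PI);
  }
  double phi = R::dnorm(t, 0.0, 1.0, 0);
  double Phi = R::pnorm(t, 0.0, 1.0, 1, 0);
  return std::log1p(t * Phi / phi);
}

// Projected-normal log-likelihood of angles (on the doubled circle) given
// per-cell latent mean vectors. cell is 0-based.
// [[Rcpp::export]]
double pn_loglik_cpp(NumericVector b1, NumericVector b2, IntegerVector cell,
                     NumericVector cx, NumericVector sx) {
  const int n = cx.size();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    int c = cell[i];
    double t = b1[c] * cx[i] + b2[c] * sx[i];
    double norm2 = b1[c] * b1[c] + b2[c] * b2[c];
    ll += -std::log(2.0 * M_PI) - 0.5 * norm2 + log_pn_term(t);
  }
  return ll;
}

// One chain of the Gibbs sampler for the projected-normal circular GLM in
// cell-means form.  Latent representation: y_i = r_i * (cos th_i, sin th_i),
// y_i ~ N2(B[cell_i], I).  Alternates
//   (i)  r_i | B, th_i  ~ density proportional to r * exp(-(r - t_i)^2 / 2),
//        r > 0, sampled exactly by slice sampling (uniform slice height,
//        then inverse-cdf of the linear density on the slice interval), and
//   (ii) B[c] | r, th  ~ N2 with precision (n_c + prior_prec) per coordinate
//        (conjugate update; diffuse zero-mean normal prior).
// Uses R's RNG, so set.seed() in R makes runs reproducible.
// [[Rcpp::export]]
List pn_gibbs_chain(IntegerVector cell, NumericVector cx, NumericVector sx,
                    int n_cells, int iters, int burnin,
                    double prior_prec, bool track_loglik) {
  const int n = cx.size();
  const int keep = iters - burnin;
  if (keep <= 0) stop("iters must exceed burnin");

  std::vector<double> r(n, 1.0);
  NumericVector b1(n_cells), b2(n_cells);
  std::vector<double> s1(n_cells), s2(n_cells);
  std::vector<int> ncell(n_cells, 0);
  for (int i = 0; i < n; ++i) ncell[cell[i]]++;

  GetRNGstate();
  for (int c = 0; c < n_cells; ++c) {  // diffuse random start
    b1[c] = norm_rand();
    b2[c] = norm_rand();
  }

  NumericMatrix draws1(keep, n_cells), draws2(keep, n_cells);
  NumericVector loglik(track_loglik ? keep : 0);

  for (int it = 0; it < iters; ++it) {
    std::fill(s1.begin(), s1.end(), 0.0);
    std::fill(s2.begin(), s2.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      int c = cell[i];
      double t = b1[c] * cx[i] + b2[c] * sx[i];
      double d = r[i] - t;
      double ell = std::sqrt(d * d - 2.0 * std::log(unif_rand()));
      double lo = t - ell; if (lo < 0.0) lo = 0.0;
      double hi = t + ell;
      double u = unif_rand();
      double rn = std::sqrt(lo * lo + u * (hi * hi - lo * lo));
      r[i] = rn;
      s1[c] += rn * cx[i];
      s2[c] += rn * sx[i];
    }
    for (int c = 0; c < n_cells; ++c) {
      double prec = ncell[c] + prior_prec;
      double sdv = 1.0 / std::sqrt(prec);
      b1[c] = s1[c] / prec + sdv * norm_rand();
      b2[c] = s2[c] / prec + sdv * norm_rand();
    }
    if (it >= burnin) {
      int k = it - burnin;
      for (int c = 0; c < n_cells; ++c) {
        draws1(k, c) = b1[c];
        draws2(k, c) = b2[c];
      }
      if (track_loglik)
        loglik[k] = pn_loglik_cpp(b1, b2, cell, cx, sx);
    }
  }
  PutRNGstate();

  return List::create(_["b1"] = draws1, _["b2"] = draws2,
                      _["loglik"] = loglik);
}
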