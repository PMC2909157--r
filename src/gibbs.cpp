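#include <Rcpp.h>
using namespace Rcpp;

// Single-site, systematic-scan Gibbs sampler for the multibreed maternal
// animal model. The coefficient matrix C of the mixed-model equations is
// held in a fixed sparsity pattern (CSC, both triangles); only its values
// are refreshed each iteration from the current (co)variance components:
//   C = W'W / sigma2_e + K^-1 + sum_X G0X^-1 (x) A*X^-1 + I / sigma2_pe.
// Location parameters are sampled one at a time in a fixed scan order
// (fixed effects, then per source direct then maternal, then permanent
// environment), each from N((r_j - sum_{k!=j} C_jk theta_k) / C_jj,
// 1 / C_jj). Variance components are then drawn from their conjugate full
// conditionals: scaled inverse chi-squared for sigma2_e and sigma2_pe,
// inverse Wishart for each 2x2 G0X. R's RNG stream is used throughout so
// set.seed() makes chains reproducible.

static inline void inv2x2(const double m[3], double out[3]) {
  // m, out = (oo, om, mm)
  double det = m[0] * m[2] - m[1] * m[1];
  if (!(det > 0.0) || !(m[0] > 0.0))
    stop("2x2 scale matrix is not positive definite in the sampler");
  out[0] = m[2] / det;
  out[1] = -m[1] / det;
  out[2] = m[0] / det;
}

// inverse-Wishart draw, dimension 2: G ~ IW(df, V) via Bartlett on V^-1
static inline void riw2(double df, const double V[3], double out[3]) {
  double Vinv[3];
  inv2x2(V, Vinv);
  // lower Cholesky of Vinv
  double l11 = std::sqrt(Vinv[0]);
  double l21 = Vinv[1] / l11;
  double l22 = std::sqrt(Vinv[2] - l21 * l21);
  // Bartlett factor (lower triangular)
  double c11 = std::sqrt(R::rchisq(df));
  double c21 = R::norm_rand();
  double c22 = std::sqrt(R::rchisq(df - 1.0));
  // M = L * C, W = M M' ~ Wishart(df, Vinv)
  double m11 = l11 * c11;
  double m21 = l21 * c11 + l22 * c21;
  double m22 = l22 * c22;
  double W[3];
  W[0] = m11 * m11;
  W[1] = m11 * m21;
  W[2] = m21 * m21 + m22 * m22;
  inv2x2(W, out);
}

// [[Rcpp::export]]
List gibbs_chain_cpp(List Wmat, NumericVector y,
                     IntegerVector Cp, IntegerVector Ci,
                     NumericVector wtw_x, NumericVector static_x,
                     IntegerVector diag_pos,
                     IntegerVector pe_idx,
                     List sources,
                     double nu_e, double ss0_e,
                     double nu_pe, double ss0_pe,
                     NumericMatrix G0_init, double s2pe_init, double s2e_init,
                     int n_iter, int burn_in, int thin,
                     bool keep_locations) {
  const IntegerVector Wi = Wmat["i"];
  const IntegerVector Wp = Wmat["p"];
  const NumericVector Wx = Wmat["x"];
  const int n = y.size();
  const int m = Cp.size() - 1;
  const int nnz = Ci.size();
  const int n_src = sources.size();

  // unpack per-source structures
  std::vector<IntegerVector> idx_o(n_src), idx_m(n_src);
  std::vector<IntegerVector> Ap(n_src), Ai(n_src);
  std::vector<NumericVector> Ax(n_src);
  std::vector<IntegerVector> pos_oo(n_src), pos_om(n_src), pos_mo(n_src),
      pos_mm(n_src);
  std::vector<NumericVector> Psi(n_src);
  std::vector<double> nu(n_src);
  std::vector<int> qx(n_src);
  for (int s = 0; s < n_src; s++) {
    List so = sources[s];
    idx_o[s] = as<IntegerVector>(so["idx_o"]);
    idx_m[s] = as<IntegerVector>(so["idx_m"]);
    Ap[s] = as<IntegerVector>(so["Ap"]);
    Ai[s] = as<IntegerVector>(so["Ai"]);
    Ax[s] = as<NumericVector>(so["Ax"]);
    pos_oo[s] = as<IntegerVector>(so["pos_oo"]);
    pos_om[s] = as<IntegerVector>(so["pos_om"]);
    pos_mo[s] = as<IntegerVector>(so["pos_mo"]);
    pos_mm[s] = as<IntegerVector>(so["pos_mm"]);
    Psi[s] = as<NumericVector>(so["Psi"]); // (oo, om, mm)
    nu[s] = as<double>(so["nu"]);
    qx[s] = idx_o[s].size();
  }

  const int d = pe_idx.size();
  // W'y (precomputed here from W and y)
  std::vector<double> Wty(m, 0.0);
  for (int j = 0; j < m; j++) {
    double acc = 0.0;
    for (int k = Wp[j]; k < Wp[j + 1]; k++) acc += Wx[k] * y[Wi[k]];
    Wty[j] = acc;
  }

  std::vector<double> theta(m, 0.0);
  std::vector<double> Cx(nnz, 0.0);
  std::vector<double> e(n, 0.0);
  std::vector<double> g0(3 * n_src);
  for (int s = 0; s < n_src; s++) {
    g0[3 * s + 0] = G0_init(0, s);
    g0[3 * s + 1] = G0_init(1, s);
    g0[3 * s + 2] = G0_init(2, s);
  }
  double s2pe = s2pe_init, s2e = s2e_init;

  const int n_comp = 3 * n_src + 2;
  int n_saved = 0;
  for (int it = burn_in; it < n_iter; it++)
    if ((it - burn_in) % thin == 0) n_saved++;
  NumericMatrix samples(n_saved, n_comp);
  IntegerVector saved_iter(n_saved);
  NumericMatrix loc_draws(keep_locations ? n_saved : 0,
                          keep_locations ? m : 0);
  std::vector<double> theta_sum(m, 0.0);
  int n_post = 0;

  std::vector<double> to(0), tm(0); // scratch A*inv %*% u products

  int row_out = 0;
  for (int it = 0; it < n_iter; it++) {
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
    // ---- refresh C values from current variance components ----
    const double inv_se = 1.0 / s2e;
    for (int k = 0; k < nnz; k++) Cx[k] = wtw_x[k] * inv_se + static_x[k];
    for (int s = 0; s < n_src; s++) {
      double gi[3];
      inv2x2(&g0[3 * s], gi);
      const int na = Ax[s].size();
      for (int k = 0; k < na; k++) {
        const double a = Ax[s][k];
        Cx[pos_oo[s][k]] += gi[0] * a;
        Cx[pos_om[s][k]] += gi[1] * a;
        Cx[pos_mo[s][k]] += gi[1] * a;
        Cx[pos_mm[s][k]] += gi[2] * a;
      }
    }
    const double inv_pe = 1.0 / s2pe;
    for (int j = 0; j < d; j++) Cx[diag_pos[pe_idx[j]]] += inv_pe;

    // ---- systematic single-site scan over all location parameters ----
    for (int j = 0; j < m; j++) {
      double lin = 0.0;
      for (int k = Cp[j]; k < Cp[j + 1]; k++) lin += Cx[k] * theta[Ci[k]];
      const double cjj = Cx[diag_pos[j]];
      lin -= cjj * theta[j];
      const double mean = (Wty[j] * inv_se - lin) / cjj;
      theta[j] = mean + R::norm_rand() / std::sqrt(cjj);
      if (!std::isfinite(theta[j]))
        stop("non-finite location draw at iteration %d (unknown %d)", it + 1,
             j + 1);
    }

    // ---- residual and scalar variances ----
    for (int i = 0; i < n; i++) e[i] = y[i];
    for (int j = 0; j < m; j++) {
      const double t = theta[j];
      if (t != 0.0)
        for (int k = Wp[j]; k < Wp[j + 1]; k++) e[Wi[k]] -= Wx[k] * t;
    }
    double sse = 0.0;
    for (int i = 0; i < n; i++) sse += e[i] * e[i];
    s2e = (sse + ss0_e) / R::rchisq(nu_e + n);

    double ssp = 0.0;
    for (int j = 0; j < d; j++) {
      const double t = theta[pe_idx[j]];
      ssp += t * t;
    }
    s2pe = (ssp + ss0_pe) / R::rchisq(nu_pe + d);

    // ---- genetic covariance matrices ----
    for (int s = 0; s < n_src; s++) {
      const int q = qx[s];
      double V[3] = {Psi[s][0], Psi[s][1], Psi[s][2]};
      if (q > 0) {
        to.assign(q, 0.0);
        tm.assign(q, 0.0);
        for (int j = 0; j < q; j++) {
          const double uo = theta[idx_o[s][j]];
          const double um = theta[idx_m[s][j]];
          for (int k = Ap[s][j]; k < Ap[s][j + 1]; k++) {
            const int i = Ai[s][k];
            const double a = Ax[s][k];
            to[i] += a * uo;
            tm[i] += a * um;
          }
        }
        double soo = 0.0, som = 0.0, smm = 0.0;
        for (int j = 0; j < q; j++) {
          const double uo = theta[idx_o[s][j]];
          const double um = theta[idx_m[s][j]];
          soo += uo * to[j];
          som += uo * tm[j];
          smm += um * tm[j];
        }
        V[0] += soo;
        V[1] += som;
        V[2] += smm;
      }
      riw2(nu[s] + q, V, &g0[3 * s]);
      if (!std::isfinite(g0[3 * s]) || !std::isfinite(g0[3 * s + 2]))
        stop("non-finite covariance draw at iteration %d", it + 1);
    }

    // ---- bookkeeping ----
    if (it >= burn_in) {
      for (int j = 0; j < m; j++) theta_sum[j] += theta[j];
      n_post++;
      if ((it - burn_in) % thin == 0) {
        for (int s = 0; s < n_src; s++) {
          samples(row_out, 3 * s + 0) = g0[3 * s + 0];
          samples(row_out, 3 * s + 1) = g0[3 * s + 1];
          samples(row_out, 3 * s + 2) = g0[3 * s + 2];
        }
        samples(row_out, n_comp - 2) = s2pe;
        samples(row_out, n_comp - 1) = s2e;
        saved_iter[row_out] = it + 1;
        if (keep_locations)
          for (int j = 0; j < m; j++) loc_draws(row_out, j) = theta[j];
        row_out++;
      }
    }
  }

  NumericVector theta_mean(m);
  for (int j = 0; j < m; j++)
    theta_mean[j] = n_post > 0 ? theta_sum[j] / n_post : NA_REAL;

  return List::create(_["samples"] = samples, _["iteration"] = saved_iter,
                      _["theta_mean"] = theta_mean,
                      _["locations"] = loc_draws);
}
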