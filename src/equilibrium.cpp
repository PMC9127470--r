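#include <Rcpp.h>
using namespace Rcpp;

// Damped fixed-point solver for the competitive trimeric-complex equilibrium.
//
// For every environment e (a row of L / A0 / B0) find free receptor levels
// a_j, b_k satisfying
//   a_j * (1 + sum_ik K_ijk L_i b_k) = A0_j
//   b_k * (1 + sum_ij K_ijk L_i a_j) = B0_k
// by iterating the relaxation a <- A0/(1+...), b <- B0/(1+...), damped when
// the update oscillates. The map is monotone and bounded (0 <= a <= A0), so
// damping 0.5 is enough in practice; non-converged environments are flagged
// and finished off by the R-level fallback.
//
// K is passed as a numeric vector with dim (nL, nI, nII).

// [[Rcpp::export]]
List solve_equilibrium_batch_cpp(NumericVector K, NumericMatrix L,
                                 NumericMatrix A0, NumericMatrix B0,
                                 double tol, int maxit,
                                 NumericMatrix a_init, NumericMatrix b_init,
                                 bool warm) {
  IntegerVector dims = K.attr("dim");
  const int nL = dims[0], nI = dims[1], nII = dims[2];
  const int nE = L.nrow();

  NumericMatrix a(nE, nI), b(nE, nII);
  IntegerVector iters(nE);
  LogicalVector conv(nE);

  // precompute, per environment, C[j][k] = sum_i K_ijk * L_ei
  std::vector<double> C(nI * nII);

  for (int e = 0; e < nE; ++e) {
    for (int j = 0; j < nI; ++j)
      for (int k = 0; k < nII; ++k) {
        double s = 0.0;
        for (int i = 0; i < nL; ++i)
          s += K[i + nL * (j + nI * k)] * L(e, i);
        C[j + nI * k] = s;
      }

    std::vector<double> av(nI), bv(nII), an(nI), bn(nII);
    for (int j = 0; j < nI; ++j) av[j] = warm ? a_init(e, j) : A0(e, j);
    for (int k = 0; k < nII; ++k) bv[k] = warm ? b_init(e, k) : B0(e, k);

    double damp = 1.0, prev_delta = R_PosInf;
    int it = 0;
    bool ok = false;
    for (it = 0; it < maxit; ++it) {
      double delta = 0.0;
      for (int j = 0; j < nI; ++j) {
        double denom = 1.0;
        for (int k = 0; k < nII; ++k) denom += C[j + nI * k] * bv[k];
        an[j] = A0(e, j) / denom;
      }
      for (int k = 0; k < nII; ++k) {
        double denom = 1.0;
        for (int j = 0; j < nI; ++j) denom += C[j + nI * k] * an[j];
        bn[k] = B0(e, k) / denom;
      }
      for (int j = 0; j < nI; ++j) {
        double upd = av[j] + damp * (an[j] - av[j]);
        double ref = (av[j] > 0.0) ? av[j] : 1.0;
        double d = std::abs(upd - av[j]) / ref;
        if (d > delta) delta = d;
        av[j] = upd;
      }
      for (int k = 0; k < nII; ++k) {
        double upd = bv[k] + damp * (bn[k] - bv[k]);
        double ref = (bv[k] > 0.0) ? bv[k] : 1.0;
        double d = std::abs(upd - bv[k]) / ref;
        if (d > delta) delta = d;
        bv[k] = upd;
      }
      if (delta < tol) { ok = true; break; }
      // engage damping when the relaxation oscillates instead of contracting
      if (delta > prev_delta && damp > 0.4999) damp = 0.5;
      prev_delta = delta;
    }
    for (int j = 0; j < nI; ++j) a(e, j) = av[j];
    for (int k = 0; k < nII; ++k) b(e, k) = bv[k];
    iters[e] = it + 1;
    conv[e] = ok;
  }

  return List::create(_["a"] = a, _["b"] = b,
                      _["iterations"] = iters, _["converged"] = conv);
}

// Total pathway output S_e = sum_ijk eps_ijk K_ijk L_ei a_ej b_ek
// [[Rcpp::export]]
NumericVector pathway_output_cpp(NumericVector K, NumericVector E,
                                 NumericMatrix L, NumericMatrix a,
                                 NumericMatrix b) {
  IntegerVector dims = K.attr("dim");
  const int nL = dims[0], nI = dims[1], nII = dims[2];
  const int nE = L.nrow();
  NumericVector S(nE);
  for (int e = 0; e < nE; ++e) {
    double s = 0.0;
    for (int k = 0; k < nII; ++k)
      for (int j = 0; j < nI; ++j) {
        double ab = a(e, j) * b(e, k);
        if (ab == 0.0) continue;
        for (int i = 0; i < nL; ++i) {
          int idx = i + nL * (j + nI * k);
          s += E[idx] * K[idx] * L(e, i) * ab;
        }
      }
    S[e] = s;
  }
  return S;
}
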