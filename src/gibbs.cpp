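#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Meuwissen & Luo style inbreeding: for each animal, accumulate the
// gene-flow contributions L_j^2 * d_j of its ancestors; a_ii = sum = 1 + F.
// Parent indices are 1-based, 0 = unknown. Pedigree must be topologically
// ordered (checked on the R side).
// [[Rcpp::export]]
NumericVector inbreeding_cpp(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n);
  std::vector<double> d(n);
  std::vector<double> L(n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], dd = dam[i];
    double fs = s > 0 ? F[s - 1] : -1.0;
    double fd = dd > 0 ? F[dd - 1] : -1.0;
    d[i] = 0.5 - 0.25 * (fs + fd);
    if (s == 0 || dd == 0) { F[i] = 0.0; continue; }
    std::fill(L.begin(), L.begin() + i + 1, 0.0);
    L[i] = 1.0;
    double aii = 0.0;
    for (int j = i; j >= 0; --j) {
      double lj = L[j];
      if (lj == 0.0) continue;
      aii += lj * lj * d[j];
      if (sire[j] > 0) L[sire[j] - 1] += 0.5 * lj;
      if (dam[j] > 0) L[dam[j] - 1] += 0.5 * lj;
    }
    F[i] = aii - 1.0;
  }
  return F;
}

// 2x2 symmetric solve-and-sample helper: draw from N(P^{-1} r, P^{-1})
// via the lower Cholesky of P.
static inline void draw_bvn(const double P11, const double P12, const double P22,
                            const double r1, const double r2,
                            double &x1, double &x2) {
  double l11 = std::sqrt(P11);
  double l21 = P12 / l11;
  double l22 = std::sqrt(P22 - l21 * l21);
  // mean: solve P m = r with P = L L'
  double z1 = r1 / l11;
  double z2 = (r2 - l21 * z1) / l22;
  double m2 = z2 / l22;
  double m1 = (z1 - l21 * m2) / l11;
  // draw: m + L'^{-1} eps
  double e1 = norm_rand(), e2 = norm_rand();
  double y2 = e2 / l22;
  double y1 = (e1 - l21 * y2) / l11;
  x1 = m1 + y1;
  x2 = m2 + y2;
}

// Inverse-Wishart(2x2) draw: G = W^{-1}, W ~ Wishart(df, S^{-1}).
static inline void draw_iw2(const double df,
                            const double S11, const double S12, const double S22,
                            double &G11, double &G12, double &G22) {
  // Sinv
  double det = S11 * S22 - S12 * S12;
  double V11 = S22 / det, V12 = -S12 / det, V22 = S11 / det;
  // lower chol of Sinv
  double l11 = std::sqrt(V11);
  double l21 = V12 / l11;
  double l22 = std::sqrt(V22 - l21 * l21);
  // Bartlett lower-triangular
  double a11 = std::sqrt(Rf_rchisq(df));
  double a22 = std::sqrt(Rf_rchisq(df - 1.0));
  double a21 = norm_rand();
  // T = L * A (lower)
  double t11 = l11 * a11;
  double t21 = l21 * a11 + l22 * a21;
  double t22 = l22 * a22;
  double W11 = t11 * t11;
  double W12 = t11 * t21;
  double W22 = t21 * t21 + t22 * t22;
  double dw = W11 * W22 - W12 * W12;
  G11 = W22 / dw;
  G12 = -W12 / dw;
  G22 = W11 / dw;
}

// One-step reaction norm Gibbs sampler.
//
// Model per record r on animal i = animal[r], contemporary group j = cg[r]:
//   y_r = x_r' beta + lj_j + a_i + b_i * lj_j + pm_{dam(r)} + e_r
// Priors: beta flat; lj ~ N(0, s2cg); (a, b) ~ N(0, G (x) A) via the sparse
// A-inverse passed as full symmetric triplets; pm ~ N(0, s2pe);
// G ~ IW(nuG, SG); scalar variances ~ scaled inverse chi-square.
// [[Rcpp::export]]
List gibbs_rn_cpp(NumericVector y, NumericMatrix Xf,
                  IntegerVector cg, IntegerVector animal, IntegerVector dam,
                  int n_animal, int n_cg, int n_dam,
                  IntegerVector ai, IntegerVector aj, NumericVector ax,
                  int n_iter, int burn_in, int thin,
                  double nuG, NumericMatrix SG,
                  double nu_cg, double s2_cg0,
                  double nu_pe, double s2_pe0,
                  double nu_e, double s2_e0,
                  bool fix_slopes, int report,
                  Nullable<List> init = R_NilValue) {
  RNGScope scope;
  const int m = y.size();
  const int p = Xf.ncol();

  // index lists
  std::vector< std::vector<int> > cg_rec(n_cg), an_rec(n_animal), dam_rec(n_dam);
  for (int r = 0; r < m; ++r) {
    cg_rec[cg[r] - 1].push_back(r);
    an_rec[animal[r] - 1].push_back(r);
    if (dam[r] > 0) dam_rec[dam[r] - 1].push_back(r);
  }

  // A-inverse adjacency (triplets are the full symmetric pattern)
  std::vector<double> Adiag(n_animal, 0.0);
  std::vector< std::vector< std::pair<int, double> > > Aoff(n_animal);
  const int nnz = ai.size();
  for (int k = 0; k < nnz; ++k) {
    int i = ai[k] - 1, j = aj[k] - 1;
    if (i == j) Adiag[i] += ax[k];
    else Aoff[i].push_back(std::make_pair(j, ax[k]));
  }

  // fixed-effect normal equations (X'X and its Cholesky, once)
  std::vector<double> XtX(p * p, 0.0);
  for (int r = 0; r < m; ++r)
    for (int c1 = 0; c1 < p; ++c1)
      for (int c2 = 0; c2 < p; ++c2)
        XtX[c1 * p + c2] += Xf(r, c1) * Xf(r, c2);
  // lower Cholesky of XtX
  std::vector<double> Lx(p * p, 0.0);
  for (int c1 = 0; c1 < p; ++c1) {
    for (int c2 = 0; c2 <= c1; ++c2) {
      double s = XtX[c1 * p + c2];
      for (int k = 0; k < c2; ++k) s -= Lx[c1 * p + k] * Lx[c2 * p + k];
      if (c1 == c2) Lx[c1 * p + c1] = std::sqrt(s);
      else Lx[c1 * p + c2] = s / Lx[c2 * p + c2];
    }
  }

  // state
  std::vector<double> beta(p, 0.0);
  double ybar = 0.0;
  for (int r = 0; r < m; ++r) ybar += y[r];
  beta[0] = ybar / m;
  std::vector<double> lj(n_cg, 0.0), a(n_animal, 0.0), b(n_animal, 0.0),
                      pm(n_dam, 0.0);
  double G11 = SG(0, 0) / (nuG - 3.0), G12 = SG(0, 1) / (nuG - 3.0),
         G22 = SG(1, 1) / (nuG - 3.0);
  if (fix_slopes) { G12 = 0.0; G22 = 0.0; }
  double s2cg = s2_cg0, s2pe = s2_pe0, s2e = s2_e0;
  if (init.isNotNull()) {
    List ini(init);
    NumericVector ia = ini["a"], ib = ini["b"], il = ini["lj"], ipm = ini["pm"];
    for (int i = 0; i < n_animal; ++i) { a[i] = ia[i]; b[i] = ib[i]; }
    for (int j = 0; j < n_cg; ++j) lj[j] = il[j];
    for (int k = 0; k < n_dam; ++k) pm[k] = ipm[k];
    G11 = as<double>(ini["G11"]); G12 = as<double>(ini["G12"]);
    G22 = as<double>(ini["G22"]);
    s2cg = as<double>(ini["s2cg"]); s2pe = as<double>(ini["s2pe"]);
    s2e = as<double>(ini["s2e"]);
  }

  // fitted fixed part cache
  std::vector<double> xb(m, 0.0);
  auto refresh_xb = [&]() {
    for (int r = 0; r < m; ++r) {
      double v = 0.0;
      for (int c = 0; c < p; ++c) v += Xf(r, c) * beta[c];
      xb[r] = v;
    }
  };
  refresh_xb();

  const int n_save = (n_iter - burn_in) / thin;
  NumericMatrix S_beta(n_save, p), S_cg(n_save, n_cg), S_a(n_save, n_animal),
                S_b(n_save, n_animal), S_pm(n_save, std::max(n_dam, 1)),
                S_G(n_save, 3);
  NumericVector S_s2cg(n_save), S_s2pe(n_save), S_s2e(n_save);
  int isave = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // --- beta | rest (flat prior) ---
    {
      std::vector<double> rhs(p, 0.0);
      for (int r = 0; r < m; ++r) {
        int i = animal[r] - 1, j = cg[r] - 1;
        double res = y[r] - a[i] - (1.0 + b[i]) * lj[j];
        if (dam[r] > 0) res -= pm[dam[r] - 1];
        for (int c = 0; c < p; ++c) rhs[c] += Xf(r, c) * res;
      }
      // solve L L' mean = rhs; draw = mean + sqrt(s2e) L'^{-1} z
      std::vector<double> z(p), mvec(p);
      for (int c = 0; c < p; ++c) {
        double s = rhs[c];
        for (int k = 0; k < c; ++k) s -= Lx[c * p + k] * z[k];
        z[c] = s / Lx[c * p + c];
      }
      for (int c = p - 1; c >= 0; --c) {
        double s = z[c];
        for (int k = c + 1; k < p; ++k) s -= Lx[k * p + c] * mvec[k];
        mvec[c] = s / Lx[c * p + c];
      }
      std::vector<double> eps(p);
      for (int c = 0; c < p; ++c) eps[c] = norm_rand();
      std::vector<double> dv(p);
      double sde = std::sqrt(s2e);
      for (int c = p - 1; c >= 0; --c) {
        double s = eps[c];
        for (int k = c + 1; k < p; ++k) s -= Lx[k * p + c] * dv[k];
        dv[c] = s / Lx[c * p + c];
      }
      for (int c = 0; c < p; ++c) beta[c] = mvec[c] + sde * dv[c];
      refresh_xb();
    }

    // --- contemporary-group effects ---
    for (int j = 0; j < n_cg; ++j) {
      double prec = 1.0 / s2cg, rhs = 0.0;
      for (size_t k = 0; k < cg_rec[j].size(); ++k) {
        int r = cg_rec[j][k];
        int i = animal[r] - 1;
        double w = 1.0 + b[i];
        double res = y[r] - xb[r] - a[i];
        if (dam[r] > 0) res -= pm[dam[r] - 1];
        prec += w * w / s2e;
        rhs += w * res / s2e;
      }
      lj[j] = rhs / prec + norm_rand() / std::sqrt(prec);
    }

    // --- (a, b) per animal, joint 2x2 block (or scalar a if slopes fixed) ---
    {
      double det = G11 * G22 - G12 * G12;
      double Gi11 = 0.0, Gi12 = 0.0, Gi22 = 0.0;
      if (!fix_slopes) { Gi11 = G22 / det; Gi12 = -G12 / det; Gi22 = G11 / det; }
      for (int i = 0; i < n_animal; ++i) {
        double t1 = 0.0, t2 = 0.0;  // sum_j Ainv_ij u_j
        for (size_t k = 0; k < Aoff[i].size(); ++k) {
          int j = Aoff[i][k].first;
          double v = Aoff[i][k].second;
          t1 += v * a[j];
          t2 += v * b[j];
        }
        if (fix_slopes) {
          double prec = Adiag[i] / G11, rhs = -t1 / G11;
          for (size_t k = 0; k < an_rec[i].size(); ++k) {
            int r = an_rec[i][k];
            double res = y[r] - xb[r] - lj[cg[r] - 1];
            if (dam[r] > 0) res -= pm[dam[r] - 1];
            prec += 1.0 / s2e;
            rhs += res / s2e;
          }
          a[i] = rhs / prec + norm_rand() / std::sqrt(prec);
        } else {
          double P11 = Adiag[i] * Gi11, P12 = Adiag[i] * Gi12,
                 P22 = Adiag[i] * Gi22;
          double r1 = -(Gi11 * t1 + Gi12 * t2);
          double r2 = -(Gi12 * t1 + Gi22 * t2);
          for (size_t k = 0; k < an_rec[i].size(); ++k) {
            int r = an_rec[i][k];
            double w2 = lj[cg[r] - 1];
            double res = y[r] - xb[r] - w2;  // subtract the fixed 1*lj part
            if (dam[r] > 0) res -= pm[dam[r] - 1];
            P11 += 1.0 / s2e;
            P12 += w2 / s2e;
            P22 += w2 * w2 / s2e;
            r1 += res / s2e;
            r2 += w2 * res / s2e;
          }
          draw_bvn(P11, P12, P22, r1, r2, a[i], b[i]);
        }
      }
    }

    // --- per-CG sign-flip moves: lj_j -> -lj_j with member slopes
    // (1+b) -> -(1+b). Valid when every member's records sit in that CG
    // (one record per animal); the likelihood is invariant and the
    // acceptance ratio involves only the (a, b) prior.
    if (!fix_slopes) {
      double det = G11 * G22 - G12 * G12;
      double Gi12 = -G12 / det, Gi22 = G11 / det;
      // per-animal member flag for the current CG
      std::vector<int> inM(n_animal, 0);
      for (int j = 0; j < n_cg; ++j) {
        // members = animals with a record in CG j (records are per-animal)
        std::vector<int> mem;
        bool ok = true;
        for (size_t k = 0; k < cg_rec[j].size(); ++k) {
          int i = animal[cg_rec[j][k]] - 1;
          if (an_rec[i].size() != 1) { ok = false; break; }
          mem.push_back(i);
        }
        if (!ok || mem.empty()) continue;
        for (size_t k = 0; k < mem.size(); ++k) inM[mem[k]] = 1;
        double dSab = 0.0, dSbb = 0.0;
        for (size_t k = 0; k < mem.size(); ++k) {
          int i = mem[k];
          double di = -2.0 * (1.0 + b[i]);
          double ta = Adiag[i] * a[i];
          double tb = Adiag[i] * b[i];
          double dm = Adiag[i] * di;  // delta' Ainv delta, diagonal part
          for (size_t h = 0; h < Aoff[i].size(); ++h) {
            int jj = Aoff[i][h].first;
            double v = Aoff[i][h].second;
            ta += v * a[jj];
            tb += v * b[jj];
            if (inM[jj]) dm += v * (-2.0 * (1.0 + b[jj]));
          }
          dSab += di * ta;
          dSbb += 2.0 * di * tb + di * dm;
        }
        double logA = -0.5 * (2.0 * Gi12 * dSab + Gi22 * dSbb);
        if (std::log(unif_rand()) < logA) {
          lj[j] = -lj[j];
          for (size_t k = 0; k < mem.size(); ++k) {
            int i = mem[k];
            b[i] = -2.0 - b[i];
          }
        }
        for (size_t k = 0; k < mem.size(); ++k) inM[mem[k]] = 0;
      }
    }

    // --- ridge moves: Metropolis-Hastings along the two soft
    // non-identifiability directions of the one-step model.
    // Scale: lj -> c*lj, (1+b) -> (1+b)/c (likelihood-invariant);
    // location: lj -> lj - t, a -> a + t*b, beta0 -> beta0 + t.
    // Both are accepted by the prior ratio plus Jacobian, so the exact
    // posterior is preserved while the chain traverses the ridge.
    if (!fix_slopes) {
      // prior cross-sums over the A-inverse pattern
      double Saa = 0.0, Sab = 0.0, Sbb = 0.0, Sa1 = 0.0, Sb1 = 0.0, S11 = 0.0;
      for (int i = 0; i < n_animal; ++i) {
        double rs = Adiag[i];
        Saa += Adiag[i] * a[i] * a[i];
        Sab += Adiag[i] * a[i] * b[i];
        Sbb += Adiag[i] * b[i] * b[i];
        for (size_t k = 0; k < Aoff[i].size(); ++k) {
          int j = Aoff[i][k].first;
          double v = Aoff[i][k].second;
          rs += v;
          Saa += v * a[i] * a[j];
          Sab += v * a[i] * b[j];
          Sbb += v * b[i] * b[j];
        }
        Sa1 += rs * a[i];
        Sb1 += rs * b[i];
        S11 += rs;
      }
      double det = G11 * G22 - G12 * G12;
      double Gi11 = G22 / det, Gi12 = -G12 / det, Gi22 = G11 / det;
      double Sll = 0.0, Sl1 = 0.0;
      for (int j = 0; j < n_cg; ++j) { Sll += lj[j] * lj[j]; Sl1 += lj[j]; }

      for (int rep = 0; rep < 4; ++rep) {
        // joint scale move: lj -> c*lj, (1+b) -> (1+b)/c, s2cg -> c^2 s2cg,
        // G -> T G T' with T = diag(1, 1/c). The likelihood, the lj prior
        // and the b-variance prior are all invariant; what remains is the
        // zero-mean prior on the slopes (the term that identifies the
        // environmental scale), the variance-prior ratios and Jacobians.
        double lc = 0.10 * norm_rand();
        double c = std::exp(lc);
        double det = G11 * G22 - G12 * G12;
        double Gi11 = G22 / det, Gi12 = -G12 / det, Gi22 = G11 / det;
        double omc = 1.0 - c;
        double dQ = 2.0 * omc * (Gi12 * Sa1 + Gi22 * Sb1) +
                    omc * omc * Gi22 * S11;
        // scaled-inverse-chi-square prior ratio for s2cg (zero for flat)
        double dPrCg = -(nu_cg / 2.0 + 1.0) * 2.0 * lc -
                       0.5 * nu_cg * s2_cg0 * (1.0 / (c * c * s2cg) - 1.0 / s2cg);
        // inverse-Wishart prior ratio for G (zero for flat: SG = 0, nuG = -3)
        double dPrG = (nuG + 3.0) * lc -
                      0.5 * (2.0 * SG(0, 1) * (c - 1.0) * Gi12 +
                             SG(1, 1) * (c * c - 1.0) * Gi22);
        double logA = -0.5 * dQ - lc + dPrCg + dPrG;
        if (std::log(unif_rand()) < logA) {
          for (int j = 0; j < n_cg; ++j) lj[j] *= c;
          double dshift = (1.0 - c) / c;
          for (int i = 0; i < n_animal; ++i) b[i] = b[i] / c + dshift;
          s2cg *= c * c;
          G12 /= c;
          G22 /= c * c;
          Sll *= c * c; Sl1 *= c;
          Sab = Sab / c + dshift * Sa1;
          Sbb = Sbb / c / c + 2.0 * dshift * Sb1 / c + dshift * dshift * S11;
          Sb1 = Sb1 / c + dshift * S11;
        }
        // location move: lj -> lj - t, a -> a + t*b, beta0 -> beta0 + t
        {
          det = G11 * G22 - G12 * G12;
          Gi11 = G22 / det; Gi12 = -G12 / det; Gi22 = G11 / det;
          double t = std::sqrt(s2cg / n_cg) * norm_rand();
          double Saa2 = Saa + 2.0 * t * Sab + t * t * Sbb;
          double Sab2b = Sab + t * Sbb;
          double dQ2 = Gi11 * (Saa2 - Saa) + 2.0 * Gi12 * (Sab2b - Sab);
          double dLl2 = -(t * t * n_cg - 2.0 * t * Sl1) / (2.0 * s2cg);
          double logA2 = dLl2 - 0.5 * dQ2;
          if (std::log(unif_rand()) < logA2) {
            for (int j = 0; j < n_cg; ++j) lj[j] -= t;
            for (int i = 0; i < n_animal; ++i) a[i] += t * b[i];
            beta[0] += t;
            for (int r = 0; r < m; ++r) xb[r] += t;
            Sll += t * t * n_cg - 2.0 * t * Sl1;
            Sl1 -= t * n_cg;
            Saa = Saa2; Sab = Sab2b;
            Sa1 += t * Sb1;
          }
        }
      }
    }

    // --- maternal permanent environment ---
    for (int dmi = 0; dmi < n_dam; ++dmi) {
      double prec = 1.0 / s2pe, rhs = 0.0;
      for (size_t k = 0; k < dam_rec[dmi].size(); ++k) {
        int r = dam_rec[dmi][k];
        int i = animal[r] - 1;
        double res = y[r] - xb[r] - a[i] - (1.0 + b[i]) * lj[cg[r] - 1];
        prec += 1.0 / s2e;
        rhs += res / s2e;
      }
      pm[dmi] = rhs / prec + norm_rand() / std::sqrt(prec);
    }

    // --- genetic (co)variances ---
    {
      double s11 = 0.0, s12 = 0.0, s22 = 0.0;  // U' Ainv U
      for (int i = 0; i < n_animal; ++i) {
        s11 += Adiag[i] * a[i] * a[i];
        s12 += Adiag[i] * a[i] * b[i];
        s22 += Adiag[i] * b[i] * b[i];
        for (size_t k = 0; k < Aoff[i].size(); ++k) {
          int j = Aoff[i][k].first;
          double v = Aoff[i][k].second;
          s11 += v * a[i] * a[j];
          s12 += v * a[i] * b[j];
          s22 += v * b[i] * b[j];
        }
      }
      if (fix_slopes) {
        double sc = (SG(0, 0) > 0.0) ? nuG * SG(0, 0) / (nuG - 3.0) : 0.0;
        double dfree = (SG(0, 0) > 0.0) ? nuG : -2.0;
        G11 = (s11 + sc) / Rf_rchisq(dfree + n_animal);
      } else {
        draw_iw2(nuG + n_animal, SG(0, 0) + s11, SG(0, 1) + s12,
                 SG(1, 1) + s22, G11, G12, G22);
      }
    }

    // --- scalar variances ---
    {
      double ss = 0.0;
      for (int j = 0; j < n_cg; ++j) ss += lj[j] * lj[j];
      s2cg = (ss + nu_cg * s2_cg0) / Rf_rchisq(nu_cg + n_cg);
    }
    if (n_dam > 0) {
      double ss = 0.0;
      for (int dmi = 0; dmi < n_dam; ++dmi) ss += pm[dmi] * pm[dmi];
      s2pe = (ss + nu_pe * s2_pe0) / Rf_rchisq(nu_pe + n_dam);
    }
    {
      double ss = 0.0;
      for (int r = 0; r < m; ++r) {
        int i = animal[r] - 1;
        double e = y[r] - xb[r] - a[i] - (1.0 + b[i]) * lj[cg[r] - 1];
        if (dam[r] > 0) e -= pm[dam[r] - 1];
        ss += e * e;
      }
      s2e = (ss + nu_e * s2_e0) / Rf_rchisq(nu_e + m);
    }

    if (report > 0 && it % report == 0) {
      Rcpp::Rcout << "iter " << it << " s2_i=" << G11 << " s2_l=" << G22
                  << " s_il=" << G12 << " s2_cg=" << s2cg
                  << " s2_pe=" << s2pe << " s2_e=" << s2e << std::endl;
    }

    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int c = 0; c < p; ++c) S_beta(isave, c) = beta[c];
      for (int j = 0; j < n_cg; ++j) S_cg(isave, j) = lj[j];
      for (int i = 0; i < n_animal; ++i) {
        S_a(isave, i) = a[i];
        S_b(isave, i) = b[i];
      }
      for (int dmi = 0; dmi < n_dam; ++dmi) S_pm(isave, dmi) = pm[dmi];
      S_G(isave, 0) = G11;
      S_G(isave, 1) = G12;
      S_G(isave, 2) = G22;
      S_s2cg[isave] = s2cg;
      S_s2pe[isave] = s2pe;
      S_s2e[isave] = s2e;
      ++isave;
    }
    if (it % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["beta"] = S_beta, _["cg"] = S_cg, _["a"] = S_a,
                      _["b"] = S_b, _["pm"] = S_pm, _["G"] = S_G,
                      _["sigma2_cg"] = S_s2cg, _["sigma2_pe"] = S_s2pe,
                      _["sigma2_e"] = S_s2e);
}
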