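// Inner machinery of the Laplace marginal likelihood: per-subject joint
// negative log density g(eta) and its vectorized damped-Newton (Levenberg)
// mode search. Mirrors the reference R implementation in R/likelihood.R;
// kept in C++ because g is evaluated thousands of times per fit.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Panel {
  // observation-dose pairs (0-based indices)
  std::vector<int> pair_obs, pair_subj;
  std::vector<double> pair_te, pair_R0, pair_dur;
  std::vector<int> obs_subj;
  std::vector<double> dv;
  int ns, n_obs;
};

Panel make_panel(const List& panel) {
  Panel p;
  IntegerVector po = panel["pair_obs"], ps = panel["pair_subj"],
                os = panel["obs_subj"];
  NumericVector te = panel["pair_te"], r0 = panel["pair_R0"],
                du = panel["pair_dur"], dv = panel["dv"];
  p.ns = as<int>(panel["ns"]);
  p.n_obs = as<int>(panel["n_obs"]);
  p.pair_obs.assign(po.begin(), po.end());
  p.pair_subj.assign(ps.begin(), ps.end());
  for (size_t i = 0; i < p.pair_obs.size(); ++i) {
    p.pair_obs[i] -= 1;
    p.pair_subj[i] -= 1;
  }
  p.obs_subj.assign(os.begin(), os.end());
  for (size_t i = 0; i < p.obs_subj.size(); ++i) p.obs_subj[i] -= 1;
  p.pair_te.assign(te.begin(), te.end());
  p.pair_R0.assign(r0.begin(), r0.end());
  p.pair_dur.assign(du.begin(), du.end());
  p.dv.assign(dv.begin(), dv.end());
  return p;
}

// per-subject g at one eta configuration; etas is ns x d (column-major),
// bsv_idx maps eta columns onto structural parameters 0=CL,1=Vc,2=Vp,3=Q
void eval_g(const Panel& p, const double* tCL, const double* tVc,
            const double* tVp, const double* tQ, bool two_cpt,
            const double* om, const int* bsv_idx, int d,
            double sigma_add, double sigma_prop, bool log_ls,
            const double* etas, double* gout) {
  int ns = p.ns, n_obs = p.n_obs;
  std::vector<double> lam1(ns), lam2(ns), C1(ns), C2(ns);
  std::vector<bool> bad_subj(ns, false);
  for (int i = 0; i < ns; ++i) {
    double pv[4] = {tCL[i], tVc[i], two_cpt ? tVp[i] : 0.0,
                    two_cpt ? tQ[i] : 0.0};
    for (int k = 0; k < d; ++k) pv[bsv_idx[k]] *= std::exp(etas[i + k * ns]);
    double CL = pv[0], Vc = pv[1], Vp = pv[2], Q = pv[3];
    if (!std::isfinite(CL) || !std::isfinite(Vc) || CL <= 0 || Vc <= 0 ||
        CL > 1e12 || Vc > 1e12) {
      bad_subj[i] = true;
      lam1[i] = 1; lam2[i] = 0; C1[i] = 0; C2[i] = 0;
      continue;
    }
    double k10 = CL / Vc;
    if (!two_cpt) {
      lam1[i] = k10; lam2[i] = 0; C1[i] = 1.0 / Vc; C2[i] = 0;
      continue;
    }
    double k12 = Q / Vc, k21 = Q / Vp;
    double s = k10 + k12 + k21, pr = k10 * k21;
    double disc = s * s - 4 * pr;
    if (disc < 0) disc = 0;
    double root = std::sqrt(disc);
    double a = (s + root) / 2, b = (s - root) / 2;
    if (a - b <= 1e-9 * a) {  // repeated-root epsilon guard
      double eps = 1e-9 * a;
      a += eps;
      b = b - eps > 0 ? b - eps : 0;
    }
    double denom = Vc * (a - b);
    lam1[i] = a; lam2[i] = b;
    C1[i] = (a - k21) / denom;
    C2[i] = (k21 - b) / denom;
  }
  std::vector<double> pred(n_obs, 0.0);
  int npair = (int)p.pair_obs.size();
  for (int j = 0; j < npair; ++j) {
    int s = p.pair_subj[j];
    double te = p.pair_te[j];
    if (te <= 0 || bad_subj[s]) continue;
    double dur = p.pair_dur[j], R0 = p.pair_R0[j];
    double ti = te < dur ? te : dur;
    double tp = te > dur ? te - dur : 0.0;
    double c = 0.0;
    if (C1[s] != 0 && lam1[s] > 0)
      c += R0 * C1[s] / lam1[s] * (1 - std::exp(-lam1[s] * ti)) *
           std::exp(-lam1[s] * tp);
    if (C2[s] != 0 && lam2[s] > 0)
      c += R0 * C2[s] / lam2[s] * (1 - std::exp(-lam2[s] * ti)) *
           std::exp(-lam2[s] * tp);
    pred[p.pair_obs[j]] += c;
  }
  const double LOG2PI = 1.8378770664093453;
  for (int i = 0; i < ns; ++i) gout[i] = 0.0;
  for (int o = 0; o < n_obs; ++o) {
    int s = p.obs_subj[o];
    double f = pred[o];
    if (log_ls) {
      // least squares on the log scale: a well-conditioned surrogate used
      // only to seed the mode search
      if (bad_subj[s] || !std::isfinite(f)) {
        gout[s] += 1e10;
        continue;
      }
      double r = std::log(p.dv[o] + 1e-6) - std::log((f > 0 ? f : 0) + 1e-6);
      gout[s] += 0.5 * r * r / 0.01;
      continue;
    }
    double v = sigma_add * sigma_add + sigma_prop * sigma_prop * f * f;
    if (bad_subj[s] || !std::isfinite(f) || v <= 0) {
      gout[s] += 1e10;
      continue;
    }
    double r = p.dv[o] - f;
    gout[s] += 0.5 * (r * r / v + std::log(v) + LOG2PI);
  }
  for (int i = 0; i < ns; ++i) {
    for (int k = 0; k < d; ++k) {
      double e = etas[i + k * ns];
      if (log_ls) gout[i] += 0.005 * e * e / om[k];
      else gout[i] += 0.5 * (e * e / om[k] + std::log(om[k]) + LOG2PI);
    }
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_subject_g(List panel, NumericVector tCL, NumericVector tVc,
                            NumericVector tVp, NumericVector tQ, bool two_cpt,
                            NumericVector om, IntegerVector bsv_idx,
                            double sigma_add, double sigma_prop,
                            NumericMatrix etas, bool log_ls = false) {
  Panel p = make_panel(panel);
  int d = om.size();
  NumericVector g(p.ns);
  eval_g(p, tCL.begin(), tVc.begin(), tVp.begin(), tQ.begin(), two_cpt,
         om.begin(), bsv_idx.begin(), d, sigma_add, sigma_prop, log_ls,
         etas.begin(), g.begin());
  return g;
}

// [[Rcpp::export]]
List cpp_find_modes(List panel, NumericVector tCL, NumericVector tVc,
                    NumericVector tVp, NumericVector tQ, bool two_cpt,
                    NumericVector om, IntegerVector bsv_idx,
                    double sigma_add, double sigma_prop,
                    NumericMatrix etas_start, int max_iter, double grad_tol,
                    double h, bool log_ls = false) {
  Panel p = make_panel(panel);
  int ns = p.ns, d = om.size();
  std::vector<double> etas(etas_start.begin(), etas_start.end());
  std::vector<double> g0(ns), gp1(ns), gm1(ns), gp2(ns), gm2(ns);
  std::vector<double> gpp(ns), gmm(ns), gpm(ns), gmp(ns), gn(ns);
  std::vector<double> grad1(ns), grad2(ns), H11(ns), H22(ns), H12(ns);
  std::vector<double> work(ns * d), lam(ns, 1e-4);
  const double* omp = om.begin();
  const int* bi = bsv_idx.begin();
  const double* c1 = tCL.begin();
  const double* c2 = tVc.begin();
  const double* c3 = tVp.begin();
  const double* c4 = tQ.begin();
  auto G = [&](const std::vector<double>& e, std::vector<double>& out) {
    eval_g(p, c1, c2, c3, c4, two_cpt, omp, bi, d, sigma_add, sigma_prop,
           log_ls, e.data(), out.data());
  };
  auto shifted = [&](int k1, double d1v, int k2, double d2v) {
    work = etas;
    if (k1 >= 0) for (int i = 0; i < ns; ++i) work[i + k1 * ns] += d1v;
    if (k2 >= 0) for (int i = 0; i < ns; ++i) work[i + k2 * ns] += d2v;
    return std::cref(work);
  };
  for (int iter = 0; iter < max_iter; ++iter) {
    G(etas, g0);
    shifted(0, h, -1, 0); G(work, gp1);
    shifted(0, -h, -1, 0); G(work, gm1);
    if (d == 2) {
      shifted(1, h, -1, 0); G(work, gp2);
      shifted(1, -h, -1, 0); G(work, gm2);
      shifted(0, h, 1, h); G(work, gpp);
      shifted(0, -h, 1, -h); G(work, gmm);
      shifted(0, h, 1, -h); G(work, gpm);
      shifted(0, -h, 1, h); G(work, gmp);
    }
    double gmax = 0;
    for (int i = 0; i < ns; ++i) {
      grad1[i] = (gp1[i] - gm1[i]) / (2 * h);
      H11[i] = (gp1[i] - 2 * g0[i] + gm1[i]) / (h * h);
      if (d == 2) {
        grad2[i] = (gp2[i] - gm2[i]) / (2 * h);
        H22[i] = (gp2[i] - 2 * g0[i] + gm2[i]) / (h * h);
        H12[i] = (gpp[i] - gpm[i] - gmp[i] + gmm[i]) / (4 * h * h);
      } else {
        grad2[i] = 0; H22[i] = 0; H12[i] = 0;
      }
      double gi = std::fabs(grad1[i]);
      if (d == 2 && std::fabs(grad2[i]) > gi) gi = std::fabs(grad2[i]);
      if (gi > gmax) gmax = gi;
    }
    if (gmax < grad_tol) break;
    // damped Newton step per subject
    work = etas;
    for (int i = 0; i < ns; ++i) {
      double d1v, d2v = 0;
      if (d == 2) {
        double tr2 = (H11[i] + H22[i]) / 2;
        double off = (H11[i] - H22[i]) / 2;
        double min_eig = tr2 - std::sqrt(off * off + H12[i] * H12[i]);
        double ridge = lam[i] - min_eig;
        if (ridge < 0) ridge = 0;
        double a = H11[i] + ridge, b = H22[i] + ridge;
        double det = a * b - H12[i] * H12[i];
        d1v = -(b * grad1[i] - H12[i] * grad2[i]) / det;
        d2v = -(a * grad2[i] - H12[i] * grad1[i]) / det;
      } else {
        double a = H11[i] > lam[i] ? H11[i] : lam[i];
        d1v = -grad1[i] / a;
      }
      double x = etas[i] + d1v;
      work[i] = x > 20 ? 20 : (x < -20 ? -20 : x);
      if (d == 2) {
        double y = etas[i + ns] + d2v;
        work[i + ns] = y > 20 ? 20 : (y < -20 ? -20 : y);
      }
    }
    G(work, gn);
    for (int i = 0; i < ns; ++i) {
      bool ok = std::isfinite(gn[i]) && gn[i] <= g0[i] + 1e-12;
      if (ok) {
        lam[i] *= 0.25;
        if (lam[i] < 1e-10) lam[i] = 1e-10;
        etas[i] = work[i];
        if (d == 2) etas[i + ns] = work[i + ns];
      } else {
        lam[i] *= 10;
        if (lam[i] > 1e10) lam[i] = 1e10;
      }
    }
  }
  G(etas, g0);
  NumericMatrix eout(ns, d);
  std::copy(etas.begin(), etas.end(), eout.begin());
  return List::create(_["etas"] = eout, _["g"] = NumericVector(g0.begin(), g0.end()),
                      _["H11"] = NumericVector(H11.begin(), H11.end()),
                      _["H22"] = NumericVector(H22.begin(), H22.end()),
                      _["H12"] = NumericVector(H12.begin(), H12.end()),
                      _["d"] = d);
}

namespace {

// one full damped-Newton (Levenberg) mode search; etas in/out, fills g and
// Hessian components at the final iterate
void lm_search(const Panel& p, const double* tCL, const double* tVc,
               const double* tVp, const double* tQ, bool two_cpt,
               const double* om, const int* bsv_idx, int d,
               double sigma_add, double sigma_prop, bool log_ls,
               std::vector<double>& etas, int max_iter, double grad_tol,
               double h, std::vector<double>& g0, std::vector<double>& H11,
               std::vector<double>& H22, std::vector<double>& H12) {
  int ns = p.ns;
  std::vector<double> gp1(ns), gm1(ns), gp2(ns), gm2(ns);
  std::vector<double> gpp(ns), gmm(ns), gpm(ns), gmp(ns), gn(ns);
  std::vector<double> grad1(ns), grad2(ns), work(ns * d), lam(ns, 1e-4);
  auto G = [&](const std::vector<double>& e, std::vector<double>& out) {
    eval_g(p, tCL, tVc, tVp, tQ, two_cpt, om, bsv_idx, d, sigma_add,
           sigma_prop, log_ls, e.data(), out.data());
  };
  auto shifted = [&](int k1, double d1v, int k2, double d2v) {
    work = etas;
    if (k1 >= 0) for (int i = 0; i < ns; ++i) work[i + k1 * ns] += d1v;
    if (k2 >= 0) for (int i = 0; i < ns; ++i) work[i + k2 * ns] += d2v;
  };
  for (int iter = 0; iter < max_iter; ++iter) {
    G(etas, g0);
    shifted(0, h, -1, 0); G(work, gp1);
    shifted(0, -h, -1, 0); G(work, gm1);
    if (d == 2) {
      shifted(1, h, -1, 0); G(work, gp2);
      shifted(1, -h, -1, 0); G(work, gm2);
      shifted(0, h, 1, h); G(work, gpp);
      shifted(0, -h, 1, -h); G(work, gmm);
      shifted(0, h, 1, -h); G(work, gpm);
      shifted(0, -h, 1, h); G(work, gmp);
    }
    double gmax = 0;
    for (int i = 0; i < ns; ++i) {
      grad1[i] = (gp1[i] - gm1[i]) / (2 * h);
      H11[i] = (gp1[i] - 2 * g0[i] + gm1[i]) / (h * h);
      if (d == 2) {
        grad2[i] = (gp2[i] - gm2[i]) / (2 * h);
        H22[i] = (gp2[i] - 2 * g0[i] + gm2[i]) / (h * h);
        H12[i] = (gpp[i] - gpm[i] - gmp[i] + gmm[i]) / (4 * h * h);
      } else {
        grad2[i] = 0; H22[i] = 0; H12[i] = 0;
      }
      double gi = std::fabs(grad1[i]);
      if (d == 2 && std::fabs(grad2[i]) > gi) gi = std::fabs(grad2[i]);
      if (gi > gmax) gmax = gi;
    }
    if (gmax < grad_tol) break;
    work = etas;
    for (int i = 0; i < ns; ++i) {
      double d1v, d2v = 0;
      if (d == 2) {
        double tr2 = (H11[i] + H22[i]) / 2;
        double off = (H11[i] - H22[i]) / 2;
        double min_eig = tr2 - std::sqrt(off * off + H12[i] * H12[i]);
        double ridge = lam[i] - min_eig;
        if (ridge < 0) ridge = 0;
        double a = H11[i] + ridge, b = H22[i] + ridge;
        double det = a * b - H12[i] * H12[i];
        d1v = -(b * grad1[i] - H12[i] * grad2[i]) / det;
        d2v = -(a * grad2[i] - H12[i] * grad1[i]) / det;
      } else {
        double a = H11[i] > lam[i] ? H11[i] : lam[i];
        d1v = -grad1[i] / a;
      }
      double x = etas[i] + d1v;
      work[i] = x > 20 ? 20 : (x < -20 ? -20 : x);
      if (d == 2) {
        double y = etas[i + ns] + d2v;
        work[i + ns] = y > 20 ? 20 : (y < -20 ? -20 : y);
      }
    }
    G(work, gn);
    for (int i = 0; i < ns; ++i) {
      bool ok = std::isfinite(gn[i]) && gn[i] <= g0[i] + 1e-12;
      if (ok) {
        lam[i] = lam[i] * 0.25 < 1e-10 ? 1e-10 : lam[i] * 0.25;
        etas[i] = work[i];
        if (d == 2) etas[i + ns] = work[i + ns];
      } else {
        lam[i] = lam[i] * 10 > 1e10 ? 1e10 : lam[i] * 10;
      }
    }
  }
  G(etas, g0);
}

double mode_contrib(double g, double h11, double h22, double h12, int d) {
  const double LOG2PI = 1.8378770664093453;
  double det = d == 2 ? h11 * h22 - h12 * h12 : h11;
  // a non-positive-definite Hessian means the search did not end at a true
  // interior mode; such a contribution is invalid, not infinitely good
  if (!(det > 1e-12) || h11 <= 0 || !std::isfinite(det) || !std::isfinite(g))
    return 1e10;
  return 2 * g - d * LOG2PI + std::log(det);
}

}  // namespace

// Full cold evaluation: seed from the log-least-squares inversion and a
// coarse omega-scaled eta grid, run the mode search from the best and the
// best well-separated runner-up start per subject, and combine the two
// Laplace masses (sparse subjects are not rarely bimodal).
// [[Rcpp::export]]
List cpp_laplace_cold(List panel, NumericVector tCL, NumericVector tVc,
                      NumericVector tVp, NumericVector tQ, bool two_cpt,
                      NumericVector om, IntegerVector bsv_idx,
                      double sigma_add, double sigma_prop,
                      int max_iter, double grad_tol, double h) {
  Panel p = make_panel(panel);
  int ns = p.ns, d = om.size();
  std::vector<double> g0(ns), H11(ns), H22(ns), H12(ns);
  // (a) log-scale inversion seed
  std::vector<double> inv(ns * d, 0.0);
  lm_search(p, tCL.begin(), tVc.begin(), tVp.begin(), tQ.begin(), two_cpt,
            om.begin(), bsv_idx.begin(), d, sigma_add, sigma_prop, true,
            inv, 30, 1e-6, h, g0, H11, H22, H12);
  for (int i = 0; i < ns * d; ++i)
    inv[i] = inv[i] > 6 ? 6 : (inv[i] < -6 ? -6 : inv[i]);
  // (b) candidate starts: grid + inversion
  const double offs[5] = {-3, -1.5, 0, 1.5, 3};
  std::vector<std::vector<double>> cands;
  if (d == 2) {
    for (int a = 0; a < 5; ++a)
      for (int b = 0; b < 5; ++b) {
        std::vector<double> c(ns * d);
        for (int i = 0; i < ns; ++i) {
          c[i] = offs[a] * std::sqrt(om[0]);
          c[i + ns] = offs[b] * std::sqrt(om[1]);
        }
        cands.push_back(std::move(c));
      }
  } else {
    for (int a = 0; a < 5; ++a) {
      std::vector<double> c(ns);
      for (int i = 0; i < ns; ++i) c[i] = offs[a] * std::sqrt(om[0]);
      cands.push_back(std::move(c));
    }
  }
  cands.push_back(inv);
  std::vector<double> best_g(ns, R_PosInf), second_g(ns, R_PosInf);
  std::vector<double> start1(ns * d, 0.0), start2(ns * d, 0.0);
  std::vector<double> gk(ns);
  for (auto& c : cands) {
    eval_g(p, tCL.begin(), tVc.begin(), tVp.begin(), tQ.begin(), two_cpt,
           om.begin(), bsv_idx.begin(), d, sigma_add, sigma_prop, false,
           c.data(), gk.data());
    for (int i = 0; i < ns; ++i) {
      if (!std::isfinite(gk[i])) continue;
      double dist1 = 0;
      for (int k = 0; k < d; ++k)
        dist1 += std::fabs(c[i + k * ns] - start1[i + k * ns]);
      if (gk[i] < best_g[i]) {
        if (std::isfinite(best_g[i]) && dist1 > 0.5 && best_g[i] < second_g[i]) {
          second_g[i] = best_g[i];
          for (int k = 0; k < d; ++k)
            start2[i + k * ns] = start1[i + k * ns];
        }
        best_g[i] = gk[i];
        for (int k = 0; k < d; ++k) start1[i + k * ns] = c[i + k * ns];
      } else if (gk[i] < second_g[i] && dist1 > 0.5) {
        second_g[i] = gk[i];
        for (int k = 0; k < d; ++k) start2[i + k * ns] = c[i + k * ns];
      }
    }
  }
  // (c) two mode searches
  std::vector<double> e1 = start1, e2 = start2;
  std::vector<double> g1(ns), h11a(ns), h22a(ns), h12a(ns);
  std::vector<double> g2(ns), h11b(ns), h22b(ns), h12b(ns);
  lm_search(p, tCL.begin(), tVc.begin(), tVp.begin(), tQ.begin(), two_cpt,
            om.begin(), bsv_idx.begin(), d, sigma_add, sigma_prop, false,
            e1, max_iter, grad_tol, h, g1, h11a, h22a, h12a);
  lm_search(p, tCL.begin(), tVc.begin(), tVp.begin(), tQ.begin(), two_cpt,
            om.begin(), bsv_idx.begin(), d, sigma_add, sigma_prop, false,
            e2, max_iter, grad_tol, h, g2, h11b, h22b, h12b);
  // (d) combine
  NumericVector by_subject(ns);
  NumericMatrix etas(ns, d);
  for (int i = 0; i < ns; ++i) {
    double n1 = mode_contrib(g1[i], h11a[i], h22a[i], h12a[i], d);
    double n2 = mode_contrib(g2[i], h11b[i], h22b[i], h12b[i], d);
    double dist = 0;
    for (int k = 0; k < d; ++k)
      dist += std::fabs(e1[i + k * ns] - e2[i + k * ns]);
    double lo = n1 < n2 ? n1 : n2, hi = n1 < n2 ? n2 : n1;
    by_subject[i] = dist < 0.5 ? lo : lo - 2 * std::log1p(std::exp(-(hi - lo) / 2));
    const std::vector<double>& win = n1 <= n2 ? e1 : e2;
    for (int k = 0; k < d; ++k) etas(i, k) = win[i + k * ns];
  }
  return List::create(_["by_subject"] = by_subject, _["etas"] = etas);
}
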