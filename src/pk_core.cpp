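// Closed-form two-compartment kinetics and the Laplace marginal likelihood.
//
// Parameter vector convention (per kg): Vc, Vt [L/kg], Cl, Cld [L/kg/h],
// ka [1/h], Fdrop, Finf [fraction, 0-1].
// Dose matrix columns: time [h], route (1 iv bolus, 2 depot bolus,
// 3 zero-order infusion), amt [ug/kg], dur [h] and, inside the likelihood,
// a fifth occasion column; doses only act on observations of the same
// occasion (crossover design with full washout between occasions).
// Observation matrix columns: time, dv, bql, loq, occ.
// Eta order (matches the estimated omega diagonal): Vc, Cl, Vt, Cld,
// logitF_drop, logitF_inf.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double REL_DEGEN = 1e-8; // repeated-root switch, relative scale

// f(lambda) = (k21 - lambda) * exp(-lambda * s) and derivatives, the residue
// kernel of the depot solution. Divided differences over {ka, alpha, beta}
// give the triple-exponential coefficients; confluent forms take over when
// two rates nearly coincide (ka close to alpha is a real possibility here:
// absorption half-life 0.117 h vs alpha half-life 0.077 h).
static inline double fker(double lam, double k21, double s) {
  return (k21 - lam) * std::exp(-lam * s);
}
static inline double fker1(double lam, double k21, double s) {
  return -std::exp(-lam * s) * (1.0 + s * (k21 - lam));
}
static inline double fker2(double lam, double k21, double s) {
  return std::exp(-lam * s) * s * (2.0 + s * (k21 - lam));
}

static inline double divdiff2(double x, double y, double k21, double s) {
  double scale = std::max(std::abs(x), std::abs(y));
  if (std::abs(x - y) < REL_DEGEN * scale)
    return fker1(0.5 * (x + y), k21, s);
  return (fker(x, k21, s) - fker(y, k21, s)) / (x - y);
}

static double divdiff3(double x0, double x1, double x2, double k21, double s) {
  double scale = std::max({std::abs(x0), std::abs(x1), std::abs(x2)});
  if (std::abs(x0 - x2) < REL_DEGEN * scale)
    return 0.5 * fker2((x0 + x1 + x2) / 3.0, k21, s);
  return (divdiff2(x0, x1, k21, s) - divdiff2(x1, x2, k21, s)) / (x0 - x2);
}

// Central-compartment concentration at `times` for one individual.
// [[Rcpp::export]]
NumericVector cpp_conc(NumericVector par, NumericMatrix doses,
                       NumericVector times) {
  double Vc = par[0], Vt = par[1], Cl = par[2], Cld = par[3], ka = par[4];
  double Fdrop = par[5], Finf = par[6];
  if (!(Vc > 0 && Vt > 0 && Cl > 0 && Cld > 0 && ka > 0) ||
      !std::isfinite(Fdrop) || !std::isfinite(Finf))
    stop("structural parameters must be positive and finite");

  double k10 = Cl / Vc, k12 = Cld / Vc, k21 = Cld / Vt;
  double sum = k10 + k12 + k21;
  double disc = std::sqrt(std::max(sum * sum - 4.0 * k10 * k21, 0.0));
  double alpha = 0.5 * (sum + disc), beta = 0.5 * (sum - disc);
  // unit-dose iv coefficients
  double A = (alpha - k21) / (Vc * (alpha - beta));
  double B = (k21 - beta) / (Vc * (alpha - beta));

  int nt = times.size(), nd = doses.nrow();
  NumericVector out(nt);
  for (int i = 0; i < nt; ++i) {
    double t = times[i], c = 0.0;
    for (int d = 0; d < nd; ++d) {
      double s = t - doses(d, 0);
      if (s <= 0) continue;
      int route = (int)doses(d, 1);
      double amt = doses(d, 2);
      if (route == 1) { // iv bolus
        c += amt * (A * std::exp(-alpha * s) + B * std::exp(-beta * s));
      } else if (route == 2) { // depot bolus via first-order absorption
        c += Fdrop * amt * ka / Vc * divdiff3(ka, alpha, beta, k21, s);
      } else if (route == 3) { // zero-order ocular infusion
        double dur = doses(d, 3);
        double rate = Finf * amt / dur;
        double se = std::min(s, dur);
        c += rate * (A / alpha * (1.0 - std::exp(-alpha * se)) *
                         std::exp(-alpha * std::max(s - dur, 0.0)) +
                     B / beta * (1.0 - std::exp(-beta * se)) *
                         std::exp(-beta * std::max(s - dur, 0.0)));
      } else {
        stop("unknown route code");
      }
    }
    out[i] = c < 0 ? 0.0 : c;
  }
  return out;
}

static inline double ilogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct SubjData {
  arma::mat doses; // time, route, amt, dur
  arma::mat obs;   // time, dv, bql, loq
};

// -log p(y | theta, eta): Gaussian density for quantified points, normal
// lower-tail mass below the LOQ (M3) for censored ones.
static double subj_nll(const arma::vec& theta, const arma::vec& eta,
                       double sp, double sa, const SubjData& sd) {
  double par[7];
  par[0] = theta[0] * std::exp(eta[0]);           // Vc
  par[1] = theta[1] * std::exp(eta[2]);           // Vt
  par[2] = theta[2] * std::exp(eta[1]);           // Cl
  par[3] = theta[3] * std::exp(eta[3]);           // Cld
  par[4] = theta[4];                              // ka (no IIV)
  par[5] = ilogit(theta[5] * std::exp(eta[4]));   // Fdrop
  par[6] = ilogit(theta[6] * std::exp(eta[5]));   // Finf

  double Vc = par[0], Vt = par[1], Cl = par[2], Cld = par[3], ka = par[4];
  double k10 = Cl / Vc, k12 = Cld / Vc, k21 = Cld / Vt;
  double sum = k10 + k12 + k21;
  double disc = std::sqrt(std::max(sum * sum - 4.0 * k10 * k21, 0.0));
  double alpha = 0.5 * (sum + disc), beta = 0.5 * (sum - disc);
  double A = (alpha - k21) / (Vc * (alpha - beta));
  double B = (k21 - beta) / (Vc * (alpha - beta));

  double nll = 0.0;
  int nobs = sd.obs.n_rows, nd = sd.doses.n_rows;
  for (int i = 0; i < nobs; ++i) {
    double t = sd.obs(i, 0), c = 0.0;
    for (int d = 0; d < nd; ++d) {
      if (sd.doses(d, 4) != sd.obs(i, 4)) continue;
      double s = t - sd.doses(d, 0);
      if (s <= 0) continue;
      int route = (int)sd.doses(d, 1);
      double amt = sd.doses(d, 2);
      if (route == 1) {
        c += amt * (A * std::exp(-alpha * s) + B * std::exp(-beta * s));
      } else if (route == 2) {
        c += par[5] * amt * ka / Vc * divdiff3(ka, alpha, beta, k21, s);
      } else {
        double dur = sd.doses(d, 3);
        double rate = par[6] * amt / dur;
        double se = std::min(s, dur);
        c += rate * (A / alpha * (1.0 - std::exp(-alpha * se)) *
                         std::exp(-alpha * std::max(s - dur, 0.0)) +
                     B / beta * (1.0 - std::exp(-beta * se)) *
                         std::exp(-beta * std::max(s - dur, 0.0)));
      }
    }
    if (c < 0) c = 0.0;
    double v = std::sqrt(sp * sp * c * c + sa * sa);
    if (sd.obs(i, 2) > 0.5) { // BQL: censored below loq
      nll -= R::pnorm(sd.obs(i, 3), c, v, 1, 1);
    } else {
      nll -= R::dnorm(sd.obs(i, 1), c, v, 1);
    }
  }
  return nll;
}

// Penalized objective g(eta) = nll + sum eta_k^2/(2 w2_k) + 0.5 log(2 pi w2_k)
// over active (w2 > 0) components; inactive etas are pinned at zero.
static double g_obj(const arma::vec& theta, const arma::vec& eta_act,
                    const arma::uvec& act, const arma::vec& w2, double sp,
                    double sa, const SubjData& sd) {
  arma::vec eta(6, arma::fill::zeros);
  for (arma::uword k = 0; k < act.n_elem; ++k) eta[act[k]] = eta_act[k];
  double g = subj_nll(theta, eta, sp, sa, sd);
  for (arma::uword k = 0; k < act.n_elem; ++k)
    g += eta_act[k] * eta_act[k] / (2.0 * w2[act[k]]) +
         0.5 * std::log(2.0 * M_PI * w2[act[k]]);
  return g;
}

static void g_grad_hess(const arma::vec& theta, const arma::vec& e,
                        const arma::uvec& act, const arma::vec& w2, double sp,
                        double sa, const SubjData& sd, arma::vec& gr,
                        arma::mat& H) {
  int d = e.n_elem;
  const double h = 1e-4;
  gr.set_size(d);
  H.set_size(d, d);
  double g0 = g_obj(theta, e, act, w2, sp, sa, sd);
  arma::vec gp(d), gm(d);
  for (int i = 0; i < d; ++i) {
    arma::vec ep = e, em = e;
    ep[i] += h; em[i] -= h;
    gp[i] = g_obj(theta, ep, act, w2, sp, sa, sd);
    gm[i] = g_obj(theta, em, act, w2, sp, sa, sd);
    gr[i] = (gp[i] - gm[i]) / (2.0 * h);
    H(i, i) = (gp[i] - 2.0 * g0 + gm[i]) / (h * h);
  }
  for (int i = 0; i < d; ++i) {
    for (int j = i + 1; j < d; ++j) {
      arma::vec epp = e, epm = e, emp = e, emm = e;
      epp[i] += h; epp[j] += h;
      epm[i] += h; epm[j] -= h;
      emp[i] -= h; emp[j] += h;
      emm[i] -= h; emm[j] -= h;
      double v = (g_obj(theta, epp, act, w2, sp, sa, sd) -
                  g_obj(theta, epm, act, w2, sp, sa, sd) -
                  g_obj(theta, emp, act, w2, sp, sa, sd) +
                  g_obj(theta, emm, act, w2, sp, sa, sd)) /
                 (4.0 * h * h);
      H(i, j) = H(j, i) = v;
    }
  }
}

// Damped-Newton search for the conditional mode of one subject's etas.
static bool inner_mode(const arma::vec& theta, const arma::uvec& act,
                       const arma::vec& w2, double sp, double sa,
                       const SubjData& sd, arma::vec& e, double& gval,
                       arma::mat& Hout) {
  int d = e.n_elem;
  double g0 = g_obj(theta, e, act, w2, sp, sa, sd);
  arma::vec gr(d);
  arma::mat H(d, d);
  bool conv = false;
  for (int it = 0; it < 100; ++it) {
    g_grad_hess(theta, e, act, w2, sp, sa, sd, gr, H);
    if (arma::norm(gr, "inf") < 1e-9) { conv = true; break; }
    double lambda = 0.0;
    bool stepped = false;
    for (int tries = 0; tries < 12; ++tries) {
      arma::mat Hd = H + lambda * arma::eye(d, d);
      arma::vec step;
      bool ok = arma::solve(step, Hd, -gr, arma::solve_opts::no_approx);
      if (ok && step.is_finite()) {
        arma::vec enew = e + step;
        double gnew = g_obj(theta, enew, act, w2, sp, sa, sd);
        if (std::isfinite(gnew) && gnew <= g0 + 1e-14) {
          if (std::abs(g0 - gnew) < 1e-13 && arma::norm(step, "inf") < 1e-10) {
            e = enew; g0 = gnew; conv = true;
          } else {
            e = enew; g0 = gnew;
          }
          stepped = true;
          break;
        }
      }
      lambda = (lambda == 0.0) ? 1e-4 : lambda * 10.0;
    }
    if (conv || !stepped) break;
  }
  g_grad_hess(theta, e, act, w2, sp, sa, sd, gr, H);
  if (!conv) conv = arma::norm(gr, "inf") < 1e-4; // loose secondary check
  gval = g_obj(theta, e, act, w2, sp, sa, sd);
  Hout = H;
  return conv;
}

// Population -2 log marginal likelihood by subject-wise Laplace approximation.
// eta_start warm-starts each subject's inner search (one row per subject,
// 6 columns); the returned etas are the conditional modes (post-hoc values).
// [[Rcpp::export]]
List cpp_m2ll(NumericVector theta_, NumericVector omega2_, double sigma_prop,
              double sigma_add, List subjects, NumericMatrix eta_start) {
  arma::vec theta = as<arma::vec>(theta_);
  arma::vec w2 = as<arma::vec>(omega2_);
  int n = subjects.size();
  arma::uvec act = arma::find(w2 > 0.0);
  int d = act.n_elem;

  std::vector<SubjData> dat(n);
  for (int i = 0; i < n; ++i) {
    List si = subjects[i];
    dat[i].doses = as<arma::mat>(si["doses"]);
    dat[i].obs = as<arma::mat>(si["obs"]);
  }

  NumericMatrix etas(n, 6);
  LogicalVector conv(n);
  double m2ll = 0.0;
  for (int i = 0; i < n; ++i) {
    if (d == 0) { // no random effects: Laplace is exact, nothing to integrate
      arma::vec e0(6, arma::fill::zeros);
      m2ll += 2.0 * subj_nll(theta, e0, sigma_prop, sigma_add, dat[i]);
      conv[i] = true;
      continue;
    }
    arma::vec e(d);
    for (int k = 0; k < d; ++k) e[k] = eta_start(i, act[k]);
    double gv; arma::mat H;
    bool ok = inner_mode(theta, act, w2, sigma_prop, sigma_add, dat[i], e, gv, H);
    if (!ok) { // restart from the prior mean, keep the better point
      arma::vec ez(d, arma::fill::zeros);
      double gz; arma::mat Hz;
      bool okz = inner_mode(theta, act, w2, sigma_prop, sigma_add, dat[i], ez, gz, Hz);
      if (okz || gz < gv) { e = ez; gv = gz; H = Hz; ok = okz; }
    }
    conv[i] = ok;
    // log det H via Cholesky, ridging if needed
    double ld = 0.0;
    arma::mat L;
    double ridge = 0.0;
    for (int tries = 0; tries < 10; ++tries) {
      if (arma::chol(L, H + ridge * arma::eye(d, d), "lower")) {
        ld = 2.0 * arma::accu(arma::log(L.diag()));
        break;
      }
      ridge = (ridge == 0.0) ? 1e-8 : ridge * 100.0;
      if (tries == 9) return List::create(_["m2ll"] = R_PosInf,
                                          _["etas"] = etas, _["conv"] = conv);
    }
    m2ll += 2.0 * gv - d * std::log(2.0 * M_PI) + ld;
    for (int k = 0; k < d; ++k) etas(i, act[k]) = e[k];
  }
  return List::create(_["m2ll"] = m2ll, _["etas"] = etas, _["conv"] = conv);
}
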