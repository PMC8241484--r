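#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Per-detector logit-scale baseline for season t:
// county intercept + detector-covariate slopes. Individual terms added later.
static void det_base(int t, int J, int T, int P, const IntegerVector &county,
                     const NumericVector &p0int, const NumericVector &detcov,
                     const NumericVector &slopes, std::vector<double> &baseJ) {
  for (int j = 0; j < J; ++j) {
    double lp = p0int[county[j] - 1];
    for (int p = 0; p < P; ++p) lp += slopes[p] * detcov[j + (size_t)J * (t + (size_t)T * p)];
    baseJ[j] = lp;
  }
}

// Binomial log-likelihood of the subdetector counts of individual i in season t
// given AC cell c (0-based), assuming the individual is alive.  Detectors with
// y == 0 farther than sqrt(localR2) from the cell centre are skipped (local
// evaluation); positive counts are always evaluated exactly.
static double row_obs_ll(int i, int t, int c, int M, int J, int T,
                         const NumericMatrix &d2cd, const int *yflat,
                         const IntegerVector &K, const std::vector<double> &baseJ,
                         double indEff, double inv2s2, double localR2) {
  double ll = 0.0;
  for (int j = 0; j < J; ++j) {
    int yy = yflat[i + (size_t)M * (j + (size_t)J * t)];
    double d2 = d2cd(c, j);
    if (yy == 0 && d2 > localR2) continue;
    double p = inv_logit(baseJ[j] + indEff) * std::exp(-d2 * inv2s2);
    if (yy > 0) {
      if (p <= 0.0) return R_NegInf;
      ll += R::lchoose((double)K[j], (double)yy) + yy * std::log(p) +
            (double)(K[j] - yy) * std::log1p(-p);
    } else if (p > 0.0) {
      ll += (double)K[j] * std::log1p(-p);
    }
  }
  return ll;
}

// Alive-state emission matrix E2[i, t]: observation log-likelihood of row
// (i, t) given z[i,t] = 2 and the current AC cell ac[i,t] (1-based).
// [[Rcpp::export]]
NumericMatrix emission_alive_cpp(IntegerMatrix ac, NumericMatrix d2cd,
                                 IntegerVector yflat, IntegerVector K,
                                 IntegerVector county, NumericVector p0int,
                                 NumericVector detcov, NumericVector slopes,
                                 double betaPrev, double betaGps,
                                 IntegerMatrix gps, IntegerMatrix prev,
                                 double sigma, double localR2) {
  int M = ac.nrow(), T = ac.ncol(), J = d2cd.ncol(), P = slopes.size();
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  NumericMatrix E2(M, T);
  std::vector<double> baseJ(J);
  const int *yp = INTEGER(yflat);
  for (int t = 0; t < T; ++t) {
    det_base(t, J, T, P, county, p0int, detcov, slopes, baseJ);
    for (int i = 0; i < M; ++i) {
      double indEff = betaGps * gps(i, t) + betaPrev * prev(i, t);
      E2(i, t) = row_obs_ll(i, t, ac(i, t) - 1, M, J, T, d2cd, yp, K, baseJ,
                            indEff, inv2s2, localR2);
    }
  }
  return E2;
}

// Total observation log-likelihood over (i, t) cells flagged alive.
// [[Rcpp::export]]
double obs_ll_cpp(IntegerMatrix ac, IntegerMatrix alive, NumericMatrix d2cd,
                  IntegerVector yflat, IntegerVector K, IntegerVector county,
                  NumericVector p0int, NumericVector detcov, NumericVector slopes,
                  double betaPrev, double betaGps,
                  IntegerMatrix gps, IntegerMatrix prev,
                  double sigma, double localR2) {
  int M = ac.nrow(), T = ac.ncol(), J = d2cd.ncol(), P = slopes.size();
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double total = 0.0;
  std::vector<double> baseJ(J);
  const int *yp = INTEGER(yflat);
  for (int t = 0; t < T; ++t) {
    det_base(t, J, T, P, county, p0int, detcov, slopes, baseJ);
    for (int i = 0; i < M; ++i) {
      if (!alive(i, t)) continue;
      double indEff = betaGps * gps(i, t) + betaPrev * prev(i, t);
      total += row_obs_ll(i, t, ac(i, t) - 1, M, J, T, d2cd, yp, K, baseJ,
                          indEff, inv2s2, localR2);
      if (!R_FINITE(total)) return R_NegInf;
    }
  }
  return total;
}

// Categorical transition row of the four-state demographic chain.
// States (0-based): 0 unborn, 1 alive, 2 dead-legal, 3 dead-other/absorbing.
static void trans_row(int s, double gam, double h, double w, double *out) {
  switch (s) {
    case 0: out[0] = 1.0 - gam; out[1] = gam; out[2] = 0.0; out[3] = 0.0; break;
    case 1: {
      double phi = 1.0 - h - w;
      if (phi < 0.0) phi = 0.0;
      out[0] = 0.0; out[1] = phi; out[2] = h; out[3] = w;
      break;
    }
    default: out[0] = 0.0; out[1] = 0.0; out[2] = 0.0; out[3] = 1.0;
  }
}

// Forward filter for one individual; fills filt (4 x T, normalized) and
// returns the marginal log-likelihood.  conMask is the flat M*T*4 allowed-
// state mask.  Sets ok = false when no legal state path has positive mass.
static double forward_ind(int i, int M, int T, const NumericMatrix &E2,
                          const IntegerMatrix &anyY, const int *conMask,
                          const IntegerMatrix &gps, int g,
                          const NumericVector &psi, const NumericMatrix &gam,
                          const NumericMatrix &h0, const NumericMatrix &w0,
                          double bh, double bw, std::vector<double> &filt,
                          bool &ok) {
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    double lem[4];
    bool any = anyY(i, t) > 0;
    for (int s = 0; s < 4; ++s) {
      double e = (s == 1) ? E2(i, t) : (any ? R_NegInf : 0.0);
      if (!conMask[i + (size_t)M * (t + (size_t)T * s)]) e = R_NegInf;
      lem[s] = e;
    }
    double pred[4];
    if (t == 0) {
      pred[0] = 1.0 - psi[g]; pred[1] = psi[g]; pred[2] = 0.0; pred[3] = 0.0;
    } else {
      int gv = gps(i, t);
      double h = inv_logit(h0(g, t) + bh * gv);
      double w = inv_logit(w0(g, t) + bw * gv);
      double gm = gam(g, t);
      for (int sp = 0; sp < 4; ++sp) pred[sp] = 0.0;
      double tr[4];
      for (int s = 0; s < 4; ++s) {
        double f = filt[s + 4 * (t - 1)];
        if (f <= 0.0) continue;
        trans_row(s, gm, h, w, tr);
        for (int sp = 0; sp < 4; ++sp) pred[sp] += f * tr[sp];
      }
    }
    double mx = R_NegInf;
    for (int s = 0; s < 4; ++s)
      if (pred[s] > 0.0 && lem[s] > mx) mx = lem[s];
    if (!R_FINITE(mx)) { ok = false; return R_NegInf; }
    double tot = 0.0, w4[4];
    for (int s = 0; s < 4; ++s) {
      double v = (pred[s] > 0.0 && R_FINITE(lem[s]))
                     ? pred[s] * std::exp(lem[s] - mx)
                     : 0.0;
      w4[s] = v;
      tot += v;
    }
    if (tot <= 0.0) { ok = false; return R_NegInf; }
    for (int s = 0; s < 4; ++s) filt[s + 4 * t] = w4[s] / tot;
    ll += mx + std::log(tot);
  }
  ok = true;
  return ll;
}

// Forward-algorithm marginal log-likelihood of the state sequences, one value
// per individual, with z marginalized out.
// [[Rcpp::export]]
NumericVector forward_ll_cpp(NumericMatrix E2, IntegerMatrix anyY,
                             IntegerVector conMask, IntegerMatrix gps,
                             IntegerVector group, NumericVector psi,
                             NumericMatrix gam, NumericMatrix h0,
                             NumericMatrix w0, double bh, double bw) {
  int M = E2.nrow(), T = E2.ncol();
  NumericVector out(M);
  std::vector<double> filt(4 * T);
  const int *cm = INTEGER(conMask);
  for (int i = 0; i < M; ++i) {
    bool ok;
    out[i] = forward_ind(i, M, T, E2, anyY, cm, gps, group[i] - 1, psi, gam,
                         h0, w0, bh, bw, filt, ok);
    if (!ok) out[i] = R_NegInf;
  }
  return out;
}

// Forward-filtering backward-sampling draw of the latent state matrix z.
// [[Rcpp::export]]
IntegerMatrix ffbs_cpp(NumericMatrix E2, IntegerMatrix anyY,
                       IntegerVector conMask, IntegerMatrix gps,
                       IntegerVector group, NumericVector psi,
                       NumericMatrix gam, NumericMatrix h0, NumericMatrix w0,
                       double bh, double bw) {
  int M = E2.nrow(), T = E2.ncol();
  IntegerMatrix z(M, T);
  std::vector<double> filt(4 * T);
  const int *cm = INTEGER(conMask);
  for (int i = 0; i < M; ++i) {
    bool ok;
    int g = group[i] - 1;
    forward_ind(i, M, T, E2, anyY, cm, gps, g, psi, gam, h0, w0, bh, bw, filt, ok);
    if (!ok)
      stop("state filtering found no legal path for individual %d "
           "(inconsistent evidence or infeasible hazards)", i + 1);
    // sample z_T
    double u = unif_rand(), cum = 0.0;
    int zt = 3;
    for (int s = 0; s < 4; ++s) {
      cum += filt[s + 4 * (T - 1)];
      if (u <= cum) { zt = s; break; }
    }
    z(i, T - 1) = zt + 1;
    for (int t = T - 2; t >= 0; --t) {
      int gv = gps(i, t + 1);
      double h = inv_logit(h0(g, t + 1) + bh * gv);
      double w = inv_logit(w0(g, t + 1) + bw * gv);
      double gm = gam(g, t + 1);
      double pr[4], tr[4], tot = 0.0;
      for (int s = 0; s < 4; ++s) {
        trans_row(s, gm, h, w, tr);
        pr[s] = filt[s + 4 * t] * tr[zt];
        tot += pr[s];
      }
      if (tot <= 0.0)
        stop("backward sampling failed for individual %d at season %d", i + 1, t + 1);
      u = unif_rand() * tot;
      cum = 0.0;
      int zs = 3;
      for (int s = 0; s < 4; ++s) {
        cum += pr[s];
        if (u <= cum) { zs = s; break; }
      }
      z(i, t) = zs + 1;
      zt = zs;
    }
  }
  return z;
}

// Movement normalizers: for every habitat cell c,
//   lognorm[c] = log sum_{c' in region(c)} exp(-d2(c,c')/(2 tau^2) + bdens X[c'])
//   loginit[c] = bdens X[c] - log sum_{c' in region(c)} exp(bdens X[c'])
// [[Rcpp::export]]
List move_norms_cpp(double tau, double bdens, NumericVector X,
                    NumericMatrix d2cc, List regionCells) {
  int n = X.size();
  NumericVector lognorm(n), loginit(n);
  double inv2t2 = 1.0 / (2.0 * tau * tau);
  for (int r = 0; r < regionCells.size(); ++r) {
    IntegerVector cells = regionCells[r];
    int nr = cells.size();
    // log-sum-exp of the intensity over the region
    double mx0 = R_NegInf;
    for (int a = 0; a < nr; ++a) {
      double v = bdens * X[cells[a] - 1];
      if (v > mx0) mx0 = v;
    }
    double s0 = 0.0;
    for (int a = 0; a < nr; ++a) s0 += std::exp(bdens * X[cells[a] - 1] - mx0);
    double lse0 = mx0 + std::log(s0);
    for (int a = 0; a < nr; ++a) {
      int c = cells[a] - 1;
      loginit[c] = bdens * X[c] - lse0;
      double mx = R_NegInf;
      for (int b = 0; b < nr; ++b) {
        int c2 = cells[b] - 1;
        double v = -d2cc(c, c2) * inv2t2 + bdens * X[c2];
        if (v > mx) mx = v;
      }
      double s = 0.0;
      for (int b = 0; b < nr; ++b) {
        int c2 = cells[b] - 1;
        s += std::exp(-d2cc(c, c2) * inv2t2 + bdens * X[c2] - mx);
      }
      lognorm[c] = mx + std::log(s);
    }
  }
  return List::create(_["lognorm"] = lognorm, _["loginit"] = loginit);
}

// Total movement log-likelihood of the AC paths of the individuals in
// `rows` (1-based; typically those ever alive -- paths of never-recruited
// pseudo-individuals integrate to one and can be marginalized out).
// [[Rcpp::export]]
double movement_ll_cpp(IntegerMatrix ac, IntegerVector rows, double tau,
                       double bdens, NumericVector X, NumericMatrix d2cc,
                       NumericVector lognorm, NumericVector loginit) {
  int T = ac.ncol();
  double inv2t2 = 1.0 / (2.0 * tau * tau);
  double ll = 0.0;
  for (int r = 0; r < rows.size(); ++r) {
    int i = rows[r] - 1;
    int cp = ac(i, 0) - 1;
    ll += loginit[cp];
    for (int t = 1; t < T; ++t) {
      int c = ac(i, t) - 1;
      ll += -d2cc(cp, c) * inv2t2 + bdens * X[c] - lognorm[cp];
      cp = c;
    }
  }
  return ll;
}

// Redraw the full AC paths of the individuals in `rows` (1-based) forward
// from the movement prior; used for pseudo-individuals whose paths carry no
// likelihood so their exact conditional is the prior.
// [[Rcpp::export]]
IntegerMatrix ac_prior_redraw_cpp(IntegerMatrix ac, IntegerVector rows,
                                  IntegerVector indRegion, List regionCells,
                                  double tau, double bdens, NumericVector X,
                                  NumericMatrix d2cc) {
  int T = ac.ncol();
  double inv2t2 = 1.0 / (2.0 * tau * tau);
  std::vector<std::vector<int> > rc(regionCells.size());
  for (int r = 0; r < regionCells.size(); ++r) {
    IntegerVector cells = regionCells[r];
    rc[r].assign(cells.begin(), cells.end());
  }
  std::vector<double> w;
  for (int r = 0; r < rows.size(); ++r) {
    int i = rows[r] - 1;
    const std::vector<int> &cells = rc[indRegion[i] - 1];
    int nr = (int)cells.size();
    w.resize(nr);
    int cp = -1;
    for (int t = 0; t < T; ++t) {
      double mx = R_NegInf;
      for (int a = 0; a < nr; ++a) {
        int c = cells[a] - 1;
        double v = bdens * X[c];
        if (t > 0) v += -d2cc(cp, c) * inv2t2;
        w[a] = v;
        if (v > mx) mx = v;
      }
      double tot = 0.0;
      for (int a = 0; a < nr; ++a) { w[a] = std::exp(w[a] - mx); tot += w[a]; }
      double u = unif_rand() * tot, cum = 0.0;
      int pick = nr - 1;
      for (int a = 0; a < nr; ++a) {
        cum += w[a];
        if (u <= cum) { pick = a; break; }
      }
      ac(i, t) = cells[pick];
      cp = cells[pick] - 1;
    }
  }
  return ac;
}

// One Gibbs sweep over all (individual, season) activity-centre cells.
// The categorical full conditional is evaluated on a numerically truncated
// support: cells whose movement log-weight is within `window` of the maximum,
// plus (for alive individuals) every cell within sqrt(localR2) of a detector
// with a positive count that season.  Cells outside carry negligible mass.
// [[Rcpp::export]]
IntegerMatrix ac_gibbs_cpp(IntegerMatrix ac, IntegerMatrix z,
                           NumericMatrix d2cc, NumericVector X,
                           IntegerVector indRegion, List regionCells,
                           NumericVector lognorm, NumericVector loginit,
                           double tau, double bdens, NumericMatrix d2cd,
                           IntegerVector yflat, IntegerVector K,
                           IntegerVector county, NumericVector p0int,
                           NumericVector detcov, NumericVector slopes,
                           double betaPrev, double betaGps, IntegerMatrix gps,
                           IntegerMatrix prev, double sigma, double localR2,
                           IntegerVector posOff, IntegerVector posDet,
                           double window) {
  int M = ac.nrow(), T = ac.ncol(), J = d2cd.ncol(), P = slopes.size();
  int ncell = X.size();
  double inv2t2 = 1.0 / (2.0 * tau * tau);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const int *yp = INTEGER(yflat);

  std::vector<std::vector<int> > rc(regionCells.size());
  for (int r = 0; r < regionCells.size(); ++r) {
    IntegerVector cells = regionCells[r];
    rc[r].assign(cells.begin(), cells.end());
  }
  // season-specific detector baselines, precomputed once
  std::vector<std::vector<double> > baseT(T, std::vector<double>(J));
  for (int t = 0; t < T; ++t)
    det_base(t, J, T, P, county, p0int, detcov, slopes, baseT[t]);

  std::vector<double> mw(ncell), wgt(ncell);
  std::vector<int> cand(ncell);

  for (int i = 0; i < M; ++i) {
    const std::vector<int> &cells = rc[indRegion[i] - 1];
    int nr = (int)cells.size();
    for (int t = 0; t < T; ++t) {
      int cp = (t > 0) ? ac(i, t - 1) - 1 : -1;
      int cn = (t < T - 1) ? ac(i, t + 1) - 1 : -1;
      double mx = R_NegInf;
      for (int a = 0; a < nr; ++a) {
        int c = cells[a] - 1;
        double v = (cp >= 0) ? (-d2cc(cp, c) * inv2t2 + bdens * X[c]) : loginit[c];
        if (cn >= 0) v += -d2cc(c, cn) * inv2t2 - lognorm[c];
        mw[a] = v;
        if (v > mx) mx = v;
      }
      bool alive = z(i, t) == 2;
      int off0 = posOff[i + M * t], off1 = posOff[i + M * t + 1];
      int ncand = 0;
      for (int a = 0; a < nr; ++a) {
        bool keep = mw[a] >= mx - window;
        if (!keep && alive) {
          int c = cells[a] - 1;
          for (int q = off0; q < off1 && !keep; ++q)
            if (d2cd(c, posDet[q]) <= localR2) keep = true;
        }
        if (keep) cand[ncand++] = a;
      }
      double mx2 = R_NegInf;
      for (int k = 0; k < ncand; ++k) {
        int a = cand[k];
        double v = mw[a];
        if (alive) {
          int c = cells[a] - 1;
          double indEff = betaGps * gps(i, t) + betaPrev * prev(i, t);
          v += row_obs_ll(i, t, c, M, J, T, d2cd, yp, K, baseT[t], indEff,
                          inv2s2, localR2);
        }
        wgt[k] = v;
        if (v > mx2) mx2 = v;
      }
      if (!R_FINITE(mx2))
        stop("activity-centre update found no admissible cell for individual %d, season %d",
             i + 1, t + 1);
      double tot = 0.0;
      for (int k = 0; k < ncand; ++k) {
        wgt[k] = std::exp(wgt[k] - mx2);
        tot += wgt[k];
      }
      double u = unif_rand() * tot, cum = 0.0;
      int pick = ncand - 1;
      for (int k = 0; k < ncand; ++k) {
        cum += wgt[k];
        if (u <= cum) { pick = k; break; }
      }
      ac(i, t) = cells[cand[pick]];
    }
  }
  return ac;
}
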