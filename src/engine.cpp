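// Monte-Carlo rupture engines.
//
// Units throughout: nm, pN, s.  All random numbers come from R's RNG
// (RNGScope via Rcpp attributes), so set.seed() at the R level makes every
// engine call bit-for-bit reproducible and lets the fitter use common
// random numbers across objective evaluations.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// chains within this fraction of the contour length are treated as
// overstretched (censoring boundary); keep in sync with the R constant
static const double OVERSTRETCH = 1e-6;

static inline double wlc_f(double L, double P, double L0, double kBT) {
  double l = L / L0;
  double om = 1.0 - l;
  return kBT / P * (0.25 / (om * om) - 0.25 + l);
}

// anchor separation: Normal(mean, sd) truncated to (0.1, 0.95) * L0
static double draw_anchor(double mean, double sd, double L0) {
  double lo = 0.1 * L0, hi = 0.95 * L0;
  if (sd <= 0.0) {
    if (mean <= lo || mean >= hi) {
      stop("fixed anchor distance %g nm outside (0.1, 0.95) of the contour length", mean);
    }
    return mean;
  }
  for (int i = 0; i < 100000; ++i) {
    double D = R::rnorm(mean, sd);
    if (D > lo && D < hi) return D;
  }
  stop("anchor-distance sampling failed: Normal(%g, %g) nm never inside (0.1, 0.95) L0", mean, sd);
  return NA_REAL; // unreachable
}

// [[Rcpp::export]]
List mc_single_cpp(int n, double k0, double delta, double P, double L0,
                   double kBT, double v, double dt, double D_mean,
                   double D_sd, double x0) {
  NumericVector force(n), time(n), Dv(n), xv(n);
  IntegerVector cens(n);
  const double Lc = L0 * (1.0 - OVERSTRETCH);
  for (int i = 0; i < n; ++i) {
    if ((i & 255) == 0) Rcpp::checkUserInterrupt();
    double D = draw_anchor(D_mean, D_sd, L0);
    // censoring boundary in displacement: L(x) = sqrt(D^2 + 4 x^2) = Lc
    double xmax = 0.5 * std::sqrt(Lc * Lc - D * D);
    double x = x0, t = 0.0, F = 0.0;
    bool rupt = false;
    while (true) {
      x += v * dt;
      t += dt;
      if (x >= xmax) break; // censored: overstretched without rupture
      double L = std::sqrt(D * D + 4.0 * x * x); // = 2 sqrt((D/2)^2 + x^2)
      double sina = 2.0 * x / L;                 // sin(atan(2x/D))
      F = 2.0 * wlc_f(L, P, L0, kBT) * sina;
      double k = k0 * std::exp(delta * F / kBT);
      double r = unif_rand();
      // -log(1 - r) >= r, so r > k dt already rules the step out; the
      // exact draw-and-compare test only runs when rupture is possible
      if (r <= k * dt && -std::log(1.0 - r) / k <= dt) { rupt = true; break; }
    }
    force[i] = rupt ? F : NA_REAL;
    time[i] = t;
    Dv[i] = D;
    xv[i] = x;
    cens[i] = rupt ? 0 : 1;
  }
  return List::create(_["force_pN"] = force, _["time_s"] = time,
                      _["D_nm"] = Dv, _["x_nm"] = xv,
                      _["censored"] = cens);
}

// reduced two-DNA balance: g(L1) = WLC1(L1) - 2 WLC2(L2) sin(alpha) with
// y = x - L1, L2 = sqrt(D^2 + 4 y^2), sin(alpha) = 2 y / L2.
// g is strictly increasing in L1 on the physical bracket.
static inline double g_two(double L1, double x, double D, double P1,
                           double L01, double P2, double L02, double kBT,
                           double* F1out) {
  double y = x - L1;
  double L2 = std::sqrt(D * D + 4.0 * y * y);
  double sina = 2.0 * y / L2;
  double F1 = wlc_f(L1, P1, L01, kBT);
  double F2 = wlc_f(L2, P2, L02, kBT);
  if (F1out) *F1out = F1;
  return F1 - 2.0 * F2 * sina;
}

// safeguarded secant/bisection on [lo, hi] with g(lo) <= 0 <= g(hi);
// returns L1 and (through F1out) the bead-side tension.
static double solve_two(double x, double D, double P1, double L01,
                        double P2, double L02, double kBT, double lo,
                        double hi, double glo, double ghi, double* F1out) {
  double a = lo, b = hi, fa = glo, fb = ghi;
  double c = 0.5 * (a + b), fc;
  for (int it = 0; it < 200; ++it) {
    fc = g_two(c, x, D, P1, L01, P2, L02, kBT, F1out);
    if (std::fabs(fc) <= 1e-12 * (1.0 + std::fabs(*F1out)) || b - a < 1e-9) {
      return c;
    }
    if (fc < 0.0) { a = c; fa = fc; } else { b = c; fb = fc; }
    // secant proposal, clipped away from the bracket edges
    double denom = fb - fa;
    double s = (denom != 0.0) ? (a - fa * (b - a) / denom) : 0.5 * (a + b);
    double w = b - a;
    if (!(s > a + 1e-3 * w && s < b - 1e-3 * w)) s = 0.5 * (a + b);
    c = s;
  }
  return c;
}

// [[Rcpp::export]]
List mc_two_cpp(int n, double k0, NumericVector delta_vals,
                NumericVector delta_cumprob, double P1, double L01,
                double P2, double L02, double kBT, double v, double dt,
                double D_mean, double D_sd, double x0) {
  NumericVector force(n), time(n), Dv(n), xv(n), dv(n);
  IntegerVector cens(n);
  const double Lc1 = L01 * (1.0 - OVERSTRETCH);
  const double Lc2 = L02 * (1.0 - OVERSTRETCH);
  const int nd = delta_vals.size();
  for (int i = 0; i < n; ++i) {
    if ((i & 63) == 0) Rcpp::checkUserInterrupt();
    // per-event ring orientation: delta drawn from the supplied mixture
    double u = unif_rand();
    double delta = delta_vals[nd - 1];
    for (int j = 0; j < nd; ++j) {
      if (u < delta_cumprob[j]) { delta = delta_vals[j]; break; }
    }
    double D = draw_anchor(D_mean, D_sd, L02);
    double ymax = 0.5 * std::sqrt(Lc2 * Lc2 - D * D);
    double x = x0, t = 0.0, F1 = 0.0, L1prev = 0.0;
    bool rupt = false;
    while (true) {
      x += v * dt;
      t += dt;
      double lo = x - ymax; if (lo < 0.0) lo = 0.0;
      double hi = (x < Lc1) ? x : Lc1;
      if (lo >= hi) break; // both chains at their limits: censored
      double glo = g_two(lo, x, D, P1, L01, P2, L02, kBT, NULL);
      double ghi = g_two(hi, x, D, P1, L01, P2, L02, kBT, NULL);
      double L1;
      if (glo >= 0.0) {
        L1 = lo;
        F1 = wlc_f(L1, P1, L01, kBT);
      } else if (ghi <= 0.0) {
        L1 = hi;
        F1 = wlc_f(L1, P1, L01, kBT);
      } else {
        // warm-start bracket around the previous step's solution
        double wl = L1prev - 50.0, wh = L1prev + 50.0 + v * dt;
        if (wl > lo && wh < hi) {
          double gwl = g_two(wl, x, D, P1, L01, P2, L02, kBT, NULL);
          double gwh = g_two(wh, x, D, P1, L01, P2, L02, kBT, NULL);
          if (gwl <= 0.0 && gwh >= 0.0) {
            lo = wl; glo = gwl; hi = wh; ghi = gwh;
          } else if (gwl > 0.0) {
            hi = wl; ghi = gwl;
          } else if (gwh < 0.0) {
            lo = wh; glo = gwh;
          }
        }
        L1 = solve_two(x, D, P1, L01, P2, L02, kBT, lo, hi, glo, ghi, &F1);
      }
      L1prev = L1;
      double k = k0 * std::exp(delta * F1 / kBT);
      double r = unif_rand();
      if (r <= k * dt && -std::log(1.0 - r) / k <= dt) { rupt = true; break; }
    }
    force[i] = rupt ? F1 : NA_REAL;
    time[i] = t;
    Dv[i] = D;
    xv[i] = x;
    dv[i] = delta;
    cens[i] = rupt ? 0 : 1;
  }
  return List::create(_["force_pN"] = force, _["time_s"] = time,
                      _["D_nm"] = Dv, _["x_nm"] = xv,
                      _["delta_nm"] = dv, _["censored"] = cens);
}

// deterministic helper: bead-side tension of the two-DNA system at a given
// displacement; same internal solver as mc_two_cpp, exposed for
// cross-checking against the R-level solve_two_dna()
// [[Rcpp::export]]
NumericVector two_dna_force_cpp(NumericVector x, double D, double P1,
                                double L01, double P2, double L02,
                                double kBT) {
  const double Lc1 = L01 * (1.0 - OVERSTRETCH);
  const double Lc2 = L02 * (1.0 - OVERSTRETCH);
  double ymax = 0.5 * std::sqrt(Lc2 * Lc2 - D * D);
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    if (xi <= 0.0) { out[i] = 0.0; continue; }
    double lo = xi - ymax; if (lo < 0.0) lo = 0.0;
    double hi = (xi < Lc1) ? xi : Lc1;
    if (lo >= hi) { out[i] = NA_REAL; continue; }
    double glo = g_two(lo, xi, D, P1, L01, P2, L02, kBT, NULL);
    double ghi = g_two(hi, xi, D, P1, L01, P2, L02, kBT, NULL);
    double F1 = 0.0;
    if (glo >= 0.0) {
      F1 = wlc_f(lo, P1, L01, kBT);
    } else if (ghi <= 0.0) {
      F1 = wlc_f(hi, P1, L01, kBT);
    } else {
      solve_two(xi, D, P1, L01, P2, L02, kBT, lo, hi, glo, ghi, &F1);
    }
    out[i] = F1;
  }
  return out;
}

// constant-force-ramp mode: F(t) = fdot * t, no tether geometry.  Used to
// check the engine's rupture kinetics against the Bell-Evans closed form
// for the most probable rupture force.
// [[Rcpp::export]]
NumericVector mc_ramp_cpp(int n, double k0, double delta, double kBT,
                          double fdot, double dt, double fmax) {
  NumericVector force(n);
  for (int i = 0; i < n; ++i) {
    if ((i & 255) == 0) Rcpp::checkUserInterrupt();
    double t = 0.0, F = 0.0;
    bool rupt = false;
    while (F < fmax) {
      t += dt;
      F = fdot * t;
      double k = k0 * std::exp(delta * F / kBT);
      double r = unif_rand();
      if (r <= k * dt && -std::log(1.0 - r) / k <= dt) { rupt = true; break; }
    }
    force[i] = rupt ? F : NA_REAL;
  }
  return force;
}
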