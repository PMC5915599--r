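// Exact stochastic simulation (Gillespie direct method) of the solution-mode
// branching/capping network. Propensities are the deterministic rate laws
// scaled to molecule counts through nav = 602.214 * volume_um3 (molecules per
// uM); net elongation is split into polymerization (k_elong * G * B) and
// depolymerization (k_elong * c_crit * B, gated on P > 0) so that the ODE's
// net law is the exact mean-field limit. Uses R's RNG (seed with set.seed).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector ssa_run_cpp(NumericVector y0, List pars, double nav,
                          NumericVector t_out, int n_runs) {
  enum { G = 0, P, Arp, CPf, VCAf, VCAg, VCAs, Astar, Bb, Bcap, Aused, NSP };
  const double k1 = pars["k_bind_VG"], k2 = pars["k_act"],
               ks = pars["k_seed"], kb = pars["k_branch_bulk"],
               ke = pars["k_elong"], kc = pars["k_cap"],
               kr = pars["k_regen"], cc = pars["c_crit"];
  const int nt = t_out.size();
  if (nt < 1) stop("ssa_run_cpp: empty output grid");
  NumericVector out(Dimension(n_runs, nt, (int)NSP));
  RNGScope scope;

  for (int run = 0; run < n_runs; ++run) {
    double n[NSP];
    for (int i = 0; i < NSP; ++i) n[i] = y0[i];
    double t = 0.0;
    int it = 0;
    for (;;) {
      double a[8];
      double gd = n[G] - cc * nav;
      if (gd < 0) gd = 0;
      a[0] = k1 / nav * n[G] * n[VCAf];
      a[1] = k2 / nav * n[Arp] * n[VCAg];
      a[2] = ks * n[Astar];
      double mf = n[P] - n[Astar];  // mother filaments: F-actin, not bare nuclei
      if (mf < 0) mf = 0;
      a[3] = kb / (nav * nav) * gd * n[Astar] * mf;
      a[4] = ke / nav * n[G] * n[Bb];
      a[5] = (n[P] > 0) ? ke * cc * n[Bb] : 0.0;
      a[6] = kc / nav * n[CPf] * n[Bb];
      a[7] = kr * n[VCAs];
      double a0 = 0;
      for (int i = 0; i < 8; ++i) a0 += a[i];
      double tnext = (a0 > 0) ? t + R::rexp(1.0 / a0) : R_PosInf;
      while (it < nt && t_out[it] <= tnext) {
        for (int i = 0; i < NSP; ++i)
          out[run + (R_xlen_t)n_runs * (it + (R_xlen_t)nt * i)] = n[i];
        ++it;
      }
      if (it >= nt || !R_FINITE(tnext)) break;
      t = tnext;
      double u = unif_rand() * a0, c = 0.0;
      int r = 7;
      for (int i = 0; i < 8; ++i) {
        c += a[i];
        if (u <= c) { r = i; break; }
      }
      switch (r) {
      case 0: n[G]--; n[VCAf]--; n[VCAg]++; break;
      case 1: n[Arp]--; n[VCAg]--; n[VCAs]++; n[Astar]++; n[P]++; break;
      case 2: n[Astar]--; n[Bb]++; n[Aused]++; break;
      case 3: n[Astar]--; n[Bb]++; n[Aused]++; break;
      case 4: n[G]--; n[P]++; break;
      case 5: n[P]--; n[G]++; break;
      case 6: n[CPf]--; n[Bb]--; n[Bcap]++; break;
      case 7: n[VCAs]--; n[VCAf]++; break;
      }
    }
  }
  return out;
}
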