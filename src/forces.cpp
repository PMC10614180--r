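#include "fqcmd.h"
using namespace Rcpp;

WaterParams parse_water_params(const List& params) {
  WaterParams p;
  p.req     = as<double>(params["r_eq"]);
  p.Dr      = as<double>(params["D_r"]);
  p.ar      = as<double>(params["a_r"]);
  p.ktheta  = as<double>(params["k_theta"]);
  p.thetaeq = as<double>(params["theta_eq"]);
  p.sigma   = as<double>(params["sigma_OO"]);
  p.eps     = as<double>(params["eps_OO"]);
  p.qH      = as<double>(params["q_H"]);
  p.gammaM  = as<double>(params["gamma_M"]);
  p.mO      = as<double>(params["m_O"]);
  p.mH      = as<double>(params["m_H"]);
  p.rcut    = as<double>(params["r_cut"]);
  p.alpha   = as<double>(params["dsf_alpha"]);
  p.dsf     = as<bool>(params["dsf"]);
  return p;
}

static PairTable parse_table(const List& tab) {
  PairTable t;
  if (tab.size() == 0) return t;
  t.present = true;
  t.rmin = as<double>(tab["r_min"]);
  t.dr   = as<double>(tab["dr"]);
  t.V    = as<std::vector<double> >(tab["V"]);
  t.D    = as<std::vector<double> >(tab["dV"]);
  t.rmax = t.rmin + t.dr * (t.V.size() - 1);
  return t;
}

Corrections parse_corrections(const List& corr, const WaterParams&) {
  Corrections c;
  if (corr.size() == 0) return c;
  if (corr.containsElementNamed("dv_r")) {
    c.dvr = as<std::vector<double> >(corr["dv_r"]);
    if (!c.dvr.empty()) c.any_intra = true;
  }
  if (corr.containsElementNamed("dv_theta")) {
    c.dvth = as<std::vector<double> >(corr["dv_theta"]);
    if (!c.dvth.empty()) c.any_intra = true;
  }
  if (corr.containsElementNamed("dv_r_range")) {
    NumericVector rg = corr["dv_r_range"];
    c.dvr_lo = rg[0]; c.dvr_hi = rg[1];
  }
  if (corr.containsElementNamed("dv_theta_range")) {
    NumericVector rg = corr["dv_theta_range"];
    c.dvth_lo = rg[0]; c.dvth_hi = rg[1];
  }
  if (corr.containsElementNamed("pair_OO")) c.oo = parse_table(corr["pair_OO"]);
  if (corr.containsElementNamed("pair_OH")) c.oh = parse_table(corr["pair_OH"]);
  if (corr.containsElementNamed("pair_HH")) c.hh = parse_table(corr["pair_HH"]);
  c.any_pair = c.oo.present || c.oh.present || c.hh.present;
  return c;
}

static inline void poly_eval(const std::vector<double>& c, double x,
                             double& v, double& d) {
  v = 0.0; d = 0.0;
  for (int k = (int)c.size() - 1; k >= 0; --k) {
    d = d * x + v;
    v = v * x + c[k];
  }
}

// polynomial on [lo, hi], linear (constant-force) continuation outside
static inline void poly_eval_clamped(const std::vector<double>& c, double x,
                                     double lo, double hi,
                                     double& v, double& d) {
  double xc = x < lo ? lo : (x > hi ? hi : x);
  poly_eval(c, xc, v, d);
  if (x != xc) v += d * (x - xc);
}

double water_forces(const double* pos, int nmol, const double* cell,
                    const WaterParams& wp, Corrections& co,
                    bool do_intra, bool do_inter,
                    double* frc, double* comps) {
  const double Lx = cell[0], Ly = cell[1], Lz = cell[2];
  const int nat = 3 * nmol;
  for (int k = 0; k < 5; ++k) comps[k] = 0.0;

  // ---- intramolecular: quartic-expanded Morse stretch + harmonic bend ----
  if (do_intra) {
    const double a2 = wp.ar * wp.ar;
    const double a3 = a2 * wp.ar, a4 = a2 * a2;
    for (int m = 0; m < nmol; ++m) {
      const int iO = 3 * m, iH1 = 3 * m + 1, iH2 = 3 * m + 2;
      double d1[3], d2[3];
      for (int k = 0; k < 3; ++k) {
        double L = cell[k];
        d1[k] = min_image(pos[3 * iH1 + k] - pos[3 * iO + k], L);
        d2[k] = min_image(pos[3 * iH2 + k] - pos[3 * iO + k], L);
      }
      double r1 = std::sqrt(d1[0] * d1[0] + d1[1] * d1[1] + d1[2] * d1[2]);
      double r2 = std::sqrt(d2[0] * d2[0] + d2[1] * d2[1] + d2[2] * d2[2]);
      double u1[3], u2[3];
      for (int k = 0; k < 3; ++k) { u1[k] = d1[k] / r1; u2[k] = d2[k] / r2; }

      // stretches
      for (int b = 0; b < 2; ++b) {
        double r = b == 0 ? r1 : r2;
        const double* u = b == 0 ? u1 : u2;
        int iH = b == 0 ? iH1 : iH2;
        double del = r - wp.req;
        double v = wp.Dr * (a2 * del * del - a3 * del * del * del +
                            (7.0 / 12.0) * a4 * del * del * del * del);
        double dv = wp.Dr * (2.0 * a2 * del - 3.0 * a3 * del * del +
                             (7.0 / 3.0) * a4 * del * del * del);
        comps[0] += v;
        if (!co.dvr.empty()) {
          double vc, dc;
          poly_eval_clamped(co.dvr, del, co.dvr_lo, co.dvr_hi, vc, dc);
          comps[1] += vc;
          dv += dc;
        }
        for (int k = 0; k < 3; ++k) {
          frc[3 * iH + k] -= dv * u[k];
          frc[3 * iO + k] += dv * u[k];
        }
      }

      // bend
      double ct = u1[0] * u2[0] + u1[1] * u2[1] + u1[2] * u2[2];
      if (ct > 1.0) ct = 1.0;
      if (ct < -1.0) ct = -1.0;
      double th = std::acos(ct);
      double st = std::sqrt(1.0 - ct * ct);
      if (st < 1e-8) st = 1e-8;
      double dth = th - wp.thetaeq;
      comps[0] += 0.5 * wp.ktheta * dth * dth;
      double dv = wp.ktheta * dth;
      if (!co.dvth.empty()) {
        double vc, dc;
        poly_eval_clamped(co.dvth, dth, co.dvth_lo, co.dvth_hi, vc, dc);
        comps[1] += vc;
        dv += dc;
      }
      for (int k = 0; k < 3; ++k) {
        double g1 = (ct * u1[k] - u2[k]) / (r1 * st);
        double g2 = (ct * u2[k] - u1[k]) / (r2 * st);
        frc[3 * iH1 + k] -= dv * g1;
        frc[3 * iH2 + k] -= dv * g2;
        frc[3 * iO + k] += dv * (g1 + g2);
      }
    }
  }

  // ---- intermolecular: shifted-force LJ (O-O) + DSF Coulomb (H,H,M) ----
  if (do_inter && nmol > 1) {
    const double rc = wp.rcut, rc2 = rc * rc;
    const double qH = wp.qH, qM = -2.0 * wp.qH;
    const double gm = wp.gammaM, w = 0.5 * (1.0 - gm);

    // LJ shift constants at cutoff
    double s6c = std::pow(wp.sigma / rc, 6), s12c = s6c * s6c;
    double vljc = 4.0 * wp.eps * (s12c - s6c);
    double fljc = 24.0 * wp.eps * (2.0 * s12c - s6c) / rc;  // -dV/dr at rc

    // DSF constants
    const double al = wp.alpha;
    const double twoosqpi = 2.0 / std::sqrt(M_PI);
    double erc = 0.0, frc_c = 0.0;
    if (wp.dsf) {
      erc = std::erfc(al * rc) / rc;
      frc_c = std::erfc(al * rc) / rc2 +
              twoosqpi * al * std::exp(-al * al * rc2) / rc;
    }

    // per-molecule sites: O, H1, H2, M (displacements kept molecule-local)
    std::vector<double> site(nmol * 12);
    std::vector<double> fM(nmol * 3, 0.0);
    for (int m = 0; m < nmol; ++m) {
      const int iO = 3 * m, iH1 = iO + 1, iH2 = iO + 2;
      double d1[3], d2[3];
      for (int k = 0; k < 3; ++k) {
        double L = cell[k];
        d1[k] = min_image(pos[3 * iH1 + k] - pos[3 * iO + k], L);
        d2[k] = min_image(pos[3 * iH2 + k] - pos[3 * iO + k], L);
        site[12 * m + k]     = pos[3 * iO + k];
        site[12 * m + 3 + k] = pos[3 * iO + k] + d1[k];
        site[12 * m + 6 + k] = pos[3 * iO + k] + d2[k];
        site[12 * m + 9 + k] = pos[3 * iO + k] + w * (d1[k] + d2[k]);
      }
    }
    const double qs[3] = { qH, qH, qM };
    // prescreen margin: a site can sit up to ~3 a0 from its O even with a
    // transiently stretched bond, on both molecules
    const double screen = rc + 6.5;

    for (int i = 0; i < nmol - 1; ++i) {
      for (int j = i + 1; j < nmol; ++j) {
        double dOO[3];
        for (int k = 0; k < 3; ++k)
          dOO[k] = min_image(site[12 * j + k] - site[12 * i + k],
                             k == 0 ? Lx : (k == 1 ? Ly : Lz));
        double rOO2 = dOO[0] * dOO[0] + dOO[1] * dOO[1] + dOO[2] * dOO[2];
        if (rOO2 > screen * screen) continue;
        double rOO = std::sqrt(rOO2);

        if (rOO2 < rc2) {
          // LJ O-O, shifted force
          double s6 = std::pow(wp.sigma * wp.sigma / rOO2, 3), s12 = s6 * s6;
          double v = 4.0 * wp.eps * (s12 - s6) - vljc + fljc * (rOO - rc);
          double fmag = 24.0 * wp.eps * (2.0 * s12 - s6) / rOO - fljc; // -dV/dr
          comps[2] += v;
          for (int k = 0; k < 3; ++k) {
            double f = fmag * dOO[k] / rOO;
            frc[3 * (3 * j) + k] += f;
            frc[3 * (3 * i) + k] -= f;
          }
          // OO pair correction
          if (co.oo.present) {
            double vc, dc;
            co.oo.eval(rOO, vc, dc);
            comps[4] += vc;
            for (int k = 0; k < 3; ++k) {
              double f = -dc * dOO[k] / rOO;
              frc[3 * (3 * j) + k] += f;
              frc[3 * (3 * i) + k] -= f;
            }
          }
        }

        // Coulomb between charged sites (H1,H2,M) of i and j, each pair
        // with its own minimum image: every term is then continuous in the
        // coordinates because the DSF potential vanishes at the cutoff.
        for (int a = 0; a < 3; ++a) {
          for (int b = 0; b < 3; ++b) {
            double d[3];
            for (int k = 0; k < 3; ++k)
              d[k] = min_image(site[12 * j + 3 * (b + 1) + k] -
                                   site[12 * i + 3 * (a + 1) + k],
                               cell[k]);
            double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
            if (r2 >= rc2) continue;
            double r = std::sqrt(r2);
            double qq = qs[a] * qs[b];
            double v, fmag;  // fmag = -dV/dr
            if (wp.dsf) {
              double er = std::erfc(al * r) / r;
              double fr = std::erfc(al * r) / r2 +
                          twoosqpi * al * std::exp(-al * al * r2) / r;
              v = qq * (er - erc + frc_c * (r - rc));
              fmag = qq * (fr - frc_c);
              // quintic taper over the last 1 a0 makes the pair term C2 at
              // the cutoff, which keeps long NVE runs drift-free
              if (r > rc - 1.0) {
                double t = (r - (rc - 1.0));  // in [0,1]
                double s = 1.0 - t * t * t * (10.0 - 15.0 * t + 6.0 * t * t);
                double ds = -t * t * (30.0 - 60.0 * t + 30.0 * t * t);
                fmag = fmag * s + v * (-ds);
                v *= s;
              }
            } else {
              v = qq / r;
              fmag = qq / r2;
            }
            comps[3] += v;
            double* fia = (a == 2) ? &fM[3 * i] : &frc[3 * (3 * i + a + 1)];
            double* fjb = (b == 2) ? &fM[3 * j] : &frc[3 * (3 * j + b + 1)];
            for (int k = 0; k < 3; ++k) {
              double f = fmag * d[k] / r;
              fjb[k] += f;
              fia[k] -= f;
            }
          }
        }

        // OH and HH pair corrections (intermolecular)
        if (co.oh.present || co.hh.present) {
          for (int a = 0; a < 3; ++a) {
            for (int b = 0; b < 3; ++b) {
              if (a == 0 && b == 0) continue;  // OO handled above
              PairTable* tab = 0;
              if (a > 0 && b > 0) {
                if (co.hh.present) tab = &co.hh;
              } else {
                if (co.oh.present) tab = &co.oh;
              }
              if (!tab) continue;
              double d[3];
              for (int k = 0; k < 3; ++k)
                d[k] = min_image(site[12 * j + 3 * b + k] -
                                     site[12 * i + 3 * a + k],
                                 cell[k]);
              double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
              double vc, dc;
              tab->eval(r, vc, dc);
              if (vc == 0.0 && dc == 0.0) continue;
              comps[4] += vc;
              int ia = 3 * i + a, jb = 3 * j + b;  // a,b in {0,1,2}=O,H1,H2
              for (int k = 0; k < 3; ++k) {
                double f = -dc * d[k] / r;
                frc[3 * jb + k] += f;
                frc[3 * ia + k] -= f;
              }
            }
          }
        }
      }
    }

    // redistribute M-site forces: r_M = gm*r_O + (1-gm)/2*(r_H1 + r_H2)
    for (int m = 0; m < nmol; ++m) {
      for (int k = 0; k < 3; ++k) {
        frc[3 * (3 * m) + k]     += gm * fM[3 * m + k];
        frc[3 * (3 * m + 1) + k] += w * fM[3 * m + k];
        frc[3 * (3 * m + 2) + k] += w * fM[3 * m + k];
      }
    }
  }

  (void)nat;
  return comps[0] + comps[1] + comps[2] + comps[3] + comps[4];
}

void water_dipole(const double* pos, const double* vel, int nmol,
                  const double* cell, const WaterParams& wp,
                  double* mu, double* mudot) {
  // per molecule: mu = qH*gamma_M*(d1 + d2) with d_i the min-image O->H_i
  // displacement (the O terms cancel by neutrality).
  for (int k = 0; k < 3; ++k) { mu[k] = 0.0; if (mudot) mudot[k] = 0.0; }
  for (int m = 0; m < nmol; ++m) {
    const int iO = 3 * m, iH1 = iO + 1, iH2 = iO + 2;
    for (int k = 0; k < 3; ++k) {
      double L = cell[k];
      double d1 = min_image(pos[3 * iH1 + k] - pos[3 * iO + k], L);
      double d2 = min_image(pos[3 * iH2 + k] - pos[3 * iO + k], L);
      mu[k] += wp.qH * wp.gammaM * (d1 + d2);
      if (mudot && vel) {
        double v = vel[3 * iH1 + k] + vel[3 * iH2 + k] - 2.0 * vel[3 * iO + k];
        mudot[k] += wp.qH * wp.gammaM * v;
      }
    }
  }
}

double lj_forces(const double* pos, int n, const double* cell,
                 double eps, double sigma, double rcut, PairTable& tab,
                 double* frc) {
  double e = 0.0;
  double rc2 = rcut * rcut;
  double s6c = std::pow(sigma / rcut, 6), s12c = s6c * s6c;
  double vljc = 4.0 * eps * (s12c - s6c);
  double fljc = 24.0 * eps * (2.0 * s12c - s6c) / rcut;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d[3];
      for (int k = 0; k < 3; ++k)
        d[k] = min_image(pos[3 * j + k] - pos[3 * i + k], cell[k]);
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (r2 >= rc2) continue;
      double r = std::sqrt(r2);
      double s6 = std::pow(sigma * sigma / r2, 3), s12 = s6 * s6;
      e += 4.0 * eps * (s12 - s6) - vljc + fljc * (r - rcut);
      double fmag = 24.0 * eps * (2.0 * s12 - s6) / r - fljc;
      if (tab.present) {
        double vc, dc;
        tab.eval(r, vc, dc);
        e += vc;
        fmag -= dc;
      }
      for (int k = 0; k < 3; ++k) {
        double f = fmag * d[k] / r;
        frc[3 * j + k] += f;
        frc[3 * i + k] -= f;
      }
    }
  }
  return e;
}

// [[Rcpp::export]]
List water_energy_forces_cpp(NumericMatrix pos, NumericVector cell,
                             List params, List corr,
                             bool do_intra, bool do_inter) {
  WaterParams wp = parse_water_params(params);
  Corrections co = parse_corrections(corr, wp);
  int nat = pos.nrow();
  int nmol = nat / 3;
  std::vector<double> p(nat * 3), f(nat * 3, 0.0);
  for (int i = 0; i < nat; ++i)
    for (int k = 0; k < 3; ++k) p[3 * i + k] = pos(i, k);
  double comps[5];
  double e = water_forces(&p[0], nmol, &cell[0], wp, co, do_intra, do_inter,
                          &f[0], comps);
  NumericMatrix fr(nat, 3);
  for (int i = 0; i < nat; ++i)
    for (int k = 0; k < 3; ++k) fr(i, k) = f[3 * i + k];
  long extrap = co.oo.extrap + co.oh.extrap + co.hh.extrap;
  return List::create(_["energy"] = e, _["forces"] = fr,
                      _["components"] = NumericVector::create(
                          _["intra"] = comps[0], _["intra_corr"] = comps[1],
                          _["lj"] = comps[2], _["coulomb"] = comps[3],
                          _["pair_corr"] = comps[4]),
                      _["n_extrapolated"] = (double)extrap);
}

// [[Rcpp::export]]
List water_dipole_cpp(NumericMatrix pos, Nullable<NumericMatrix> vel,
                      NumericVector cell, List params) {
  WaterParams wp = parse_water_params(params);
  int nat = pos.nrow(), nmol = nat / 3;
  std::vector<double> p(nat * 3), v;
  for (int i = 0; i < nat; ++i)
    for (int k = 0; k < 3; ++k) p[3 * i + k] = pos(i, k);
  double mu[3], mudot[3];
  bool hasv = vel.isNotNull();
  if (hasv) {
    NumericMatrix vm(vel);
    v.resize(nat * 3);
    for (int i = 0; i < nat; ++i)
      for (int k = 0; k < 3; ++k) v[3 * i + k] = vm(i, k);
  }
  water_dipole(&p[0], hasv ? &v[0] : (double*)0, nmol, &cell[0], wp, mu,
               hasv ? mudot : (double*)0);
  List out = List::create(_["mu"] = NumericVector::create(mu[0], mu[1], mu[2]));
  if (hasv)
    out["mudot"] = NumericVector::create(mudot[0], mudot[1], mudot[2]);
  return out;
}

// [[Rcpp::export]]
List lj_energy_forces_cpp(NumericMatrix pos, NumericVector cell, double eps,
                          double sigma, double rcut, List table) {
  int n = pos.nrow();
  std::vector<double> p(n * 3), f(n * 3, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) p[3 * i + k] = pos(i, k);
  PairTable tab = parse_corrections(
      List::create(_["pair_OO"] = table), WaterParams()).oo;
  double e = lj_forces(&p[0], n, &cell[0], eps, sigma, rcut, tab, &f[0]);
  NumericMatrix fr(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) fr(i, k) = f[3 * i + k];
  return List::create(_["energy"] = e, _["forces"] = fr);
}
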