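#include "fqcmd.h"
using namespace Rcpp;

// All engines work in atomic units internally (positions a0, energies
// hartree, masses m_e, time in atomic time units). Conversion to fs and K
// happens at the R interface.

// ---------------------------------------------------------------------------
// Classical water MD: BAOAB Langevin (thermostat = 1) or velocity Verlet
// (thermostat = 0). Records energies, dipole and dipole derivative every
// record_stride steps and full configurations every frame_stride steps.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List run_water_md_cpp(NumericMatrix pos0, NumericMatrix vel0,
                      NumericVector cell, List params, List corr,
                      double dt, int nsteps, double kT, double gamma,
                      int thermostat, int seed,
                      int record_stride, int frame_stride) {
  WaterParams wp = parse_water_params(params);
  Corrections co = parse_corrections(corr, wp);
  const int nat = pos0.nrow(), nmol = nat / 3;
  std::vector<double> x(nat * 3), v(nat * 3), f(nat * 3, 0.0), mass(nat);
  for (int i = 0; i < nat; ++i) {
    mass[i] = (i % 3 == 0) ? wp.mO : wp.mH;
    for (int k = 0; k < 3; ++k) {
      x[3 * i + k] = pos0(i, k);
      v[3 * i + k] = vel0(i, k);
    }
  }
  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);

  double comps[5];
  double pe = water_forces(&x[0], nmol, &cell[0], wp, co, true, true, &f[0],
                           comps);

  int nrec = nsteps / record_stride;
  NumericVector r_time(nrec), r_pe(nrec), r_ke(nrec);
  NumericMatrix r_mu(nrec, 3), r_mudot(nrec, 3);
  int nfr = frame_stride > 0 ? nsteps / frame_stride : 0;
  NumericVector frames(nfr > 0 ? nat * 3 * nfr : 0);
  NumericVector frame_time(nfr);
  int irec = 0, ifr = 0;

  for (int step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < nat * 3; ++i) v[i] += 0.5 * dt * f[i] / mass[i / 3];
    for (int i = 0; i < nat * 3; ++i) x[i] += 0.5 * dt * v[i];
    if (thermostat) {
      for (int i = 0; i < nat * 3; ++i) {
        double s = std::sqrt(kT / mass[i / 3]);
        v[i] = c1 * v[i] + c2 * s * gauss(rng);
      }
    }
    for (int i = 0; i < nat * 3; ++i) x[i] += 0.5 * dt * v[i];
    std::fill(f.begin(), f.end(), 0.0);
    pe = water_forces(&x[0], nmol, &cell[0], wp, co, true, true, &f[0], comps);
    if (!std::isfinite(pe))
      stop("non-finite potential energy at step %d", step);
    for (int i = 0; i < nat * 3; ++i) v[i] += 0.5 * dt * f[i] / mass[i / 3];

    if (step % record_stride == 0 && irec < nrec) {
      double ke = 0.0;
      for (int i = 0; i < nat * 3; ++i)
        ke += 0.5 * mass[i / 3] * v[i] * v[i];
      double mu[3], mudot[3];
      water_dipole(&x[0], &v[0], nmol, &cell[0], wp, mu, mudot);
      r_time[irec] = step * dt;
      r_pe[irec] = pe;
      r_ke[irec] = ke;
      for (int k = 0; k < 3; ++k) {
        r_mu(irec, k) = mu[k];
        r_mudot(irec, k) = mudot[k];
      }
      ++irec;
    }
    if (frame_stride > 0 && step % frame_stride == 0 && ifr < nfr) {
      for (int i = 0; i < nat; ++i)
        for (int k = 0; k < 3; ++k)
          frames[ifr * nat * 3 + k * nat + i] = x[3 * i + k];
      frame_time[ifr] = step * dt;
      ++ifr;
    }
  }

  NumericMatrix xf(nat, 3), vf(nat, 3);
  for (int i = 0; i < nat; ++i)
    for (int k = 0; k < 3; ++k) {
      xf(i, k) = x[3 * i + k];
      vf(i, k) = v[3 * i + k];
    }
  if (nfr > 0) frames.attr("dim") = IntegerVector::create(nat, 3, nfr);
  return List::create(
      _["time"] = r_time, _["pe"] = r_pe, _["ke"] = r_ke, _["mu"] = r_mu,
      _["mudot"] = r_mudot, _["frames"] = frames, _["frame_time"] = frame_time,
      _["positions"] = xf, _["velocities"] = vf,
      _["n_extrapolated"] =
          (double)(co.oo.extrap + co.oh.extrap + co.hh.extrap));
}

// ---------------------------------------------------------------------------
// PIMD on the ring-polymer system, OBABO splitting with a per-normal-mode
// stochastic (PILE) thermostat and exact free-ring-polymer evolution.
// Convention: every bead feels the full physical potential; the composite
// system is sampled at inverse temperature beta_P = beta/P with spring
// frequency omega_P = P/(beta*hbar) (hbar = 1).
// beads: dim (nat, 3, P); Cnm: P x P orthonormal transform (rows = modes);
// omegak: free-ring-polymer normal-mode frequencies, length P.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List run_water_pimd_cpp(NumericVector beads_pos, NumericVector beads_vel,
                        int P, NumericVector cell, List params, List corr,
                        NumericMatrix Cnm, NumericVector omegak,
                        double dt, int nsteps, double beta, double gamma0,
                        int thermostat, int seed,
                        int record_stride, int frame_stride) {
  WaterParams wp = parse_water_params(params);
  Corrections co = parse_corrections(corr, wp);
  IntegerVector dims = beads_pos.attr("dim");
  const int nat = dims[0], nmol = nat / 3, nd = nat * 3;
  const double betaP = beta / P;
  const double kTP = 1.0 / betaP;
  const double omegaP = 1.0 / betaP;  // hbar = 1
  std::vector<double> mass(nat);
  for (int i = 0; i < nat; ++i) mass[i] = (i % 3 == 0) ? wp.mO : wp.mH;

  // layout: x[j][3*i+k] for bead j
  std::vector<std::vector<double> > x(P, std::vector<double>(nd)),
      v(P, std::vector<double>(nd)), f(P, std::vector<double>(nd, 0.0));
  for (int j = 0; j < P; ++j)
    for (int i = 0; i < nat; ++i)
      for (int k = 0; k < 3; ++k) {
        x[j][3 * i + k] = beads_pos[i + nat * k + nat * 3 * j];
        v[j][3 * i + k] = beads_vel[i + nat * k + nat * 3 * j];
      }

  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  // thermostat constants per mode (half step)
  std::vector<double> tc1(P), tc2(P);
  for (int k = 0; k < P; ++k) {
    double g = (k == 0) ? gamma0 : 2.0 * omegak[k];
    tc1[k] = std::exp(-0.5 * g * dt);
    tc2[k] = std::sqrt(1.0 - tc1[k] * tc1[k]);
  }
  // free-RP evolution constants
  std::vector<double> ec(P), es(P);  // cos(w dt), sin(w dt)
  for (int k = 0; k < P; ++k) {
    ec[k] = std::cos(omegak[k] * dt);
    es[k] = std::sin(omegak[k] * dt);
  }

  std::vector<double> nmbuf(P), nmbuf2(P);
  double comps[5];
  double pe_sum = 0.0;
  for (int j = 0; j < P; ++j) {
    std::fill(f[j].begin(), f[j].end(), 0.0);
    pe_sum += water_forces(&x[j][0], nmol, &cell[0], wp, co, true, true,
                           &f[j][0], comps);
  }

  int nrec = nsteps / record_stride;
  NumericVector r_time(nrec), r_pe(nrec), r_ke(nrec), r_spring(nrec),
      r_keprim(nrec), r_kevir(nrec);
  int nfr = frame_stride > 0 ? nsteps / frame_stride : 0;
  NumericVector frames(nfr > 0 ? (double)nd * P * nfr : 0);
  NumericVector frame_time(nfr);
  int irec = 0, ifr = 0;

  auto thermo_half = [&](void) {
    for (int i = 0; i < nd; ++i) {
      double m = mass[i / 3];
      double s = std::sqrt(kTP / m);
      for (int k = 0; k < P; ++k) {
        double acc = 0.0;
        for (int j = 0; j < P; ++j) acc += Cnm(k, j) * v[j][i];
        nmbuf[k] = tc1[k] * acc + tc2[k] * s * gauss(rng);
      }
      for (int j = 0; j < P; ++j) {
        double acc = 0.0;
        for (int k = 0; k < P; ++k) acc += Cnm(k, j) * nmbuf[k];
        v[j][i] = acc;
      }
    }
  };

  for (int step = 1; step <= nsteps; ++step) {
    if (thermostat) thermo_half();
    for (int j = 0; j < P; ++j)
      for (int i = 0; i < nd; ++i)
        v[j][i] += 0.5 * dt * f[j][i] / mass[i / 3];
    // exact free-ring-polymer evolution in normal modes
    for (int i = 0; i < nd; ++i) {
      for (int k = 0; k < P; ++k) {
        double qx = 0.0, qv = 0.0;
        for (int j = 0; j < P; ++j) {
          qx += Cnm(k, j) * x[j][i];
          qv += Cnm(k, j) * v[j][i];
        }
        if (omegak[k] == 0.0) {
          nmbuf[k] = qx + dt * qv;
          nmbuf2[k] = qv;
        } else {
          nmbuf[k] = ec[k] * qx + es[k] / omegak[k] * qv;
          nmbuf2[k] = -omegak[k] * es[k] * qx + ec[k] * qv;
        }
      }
      for (int j = 0; j < P; ++j) {
        double ax = 0.0, av = 0.0;
        for (int k = 0; k < P; ++k) {
          ax += Cnm(k, j) * nmbuf[k];
          av += Cnm(k, j) * nmbuf2[k];
        }
        x[j][i] = ax;
        v[j][i] = av;
      }
    }
    pe_sum = 0.0;
    for (int j = 0; j < P; ++j) {
      std::fill(f[j].begin(), f[j].end(), 0.0);
      pe_sum += water_forces(&x[j][0], nmol, &cell[0], wp, co, true, true,
                             &f[j][0], comps);
    }
    if (!std::isfinite(pe_sum))
      stop("non-finite potential energy at step %d", step);
    for (int j = 0; j < P; ++j)
      for (int i = 0; i < nd; ++i)
        v[j][i] += 0.5 * dt * f[j][i] / mass[i / 3];
    if (thermostat) thermo_half();

    if (step % record_stride == 0 && irec < nrec) {
      double ke = 0.0, spring = 0.0, vir = 0.0;
      for (int j = 0; j < P; ++j) {
        int jn = (j + 1) % P;
        for (int i = 0; i < nd; ++i) {
          double m = mass[i / 3];
          ke += 0.5 * m * v[j][i] * v[j][i];
          double dx = x[j][i] - x[jn][i];
          spring += 0.5 * m * omegaP * omegaP * dx * dx;
        }
      }
      // centroid-virial estimator
      for (int i = 0; i < nd; ++i) {
        double xc = 0.0;
        for (int j = 0; j < P; ++j) xc += x[j][i];
        xc /= P;
        for (int j = 0; j < P; ++j) vir += (x[j][i] - xc) * (-f[j][i]);
      }
      r_time[irec] = step * dt;
      r_pe[irec] = pe_sum;
      r_ke[irec] = ke;
      r_spring[irec] = spring;
      r_keprim[irec] = (3.0 * nat * P) / (2.0 * beta) - spring / P;
      r_kevir[irec] = (3.0 * nat) / (2.0 * beta) + vir / (2.0 * P);
      ++irec;
    }
    if (frame_stride > 0 && step % frame_stride == 0 && ifr < nfr) {
      for (int j = 0; j < P; ++j)
        for (int i = 0; i < nat; ++i)
          for (int k = 0; k < 3; ++k)
            frames[(R_xlen_t)ifr * nd * P + (R_xlen_t)j * nd +
                   (R_xlen_t)k * nat + i] = x[j][3 * i + k];
      frame_time[ifr] = step * dt;
      ++ifr;
    }
  }

  NumericVector xp((double)nd * P), vp((double)nd * P);
  for (int j = 0; j < P; ++j)
    for (int i = 0; i < nat; ++i)
      for (int k = 0; k < 3; ++k) {
        xp[i + nat * k + nat * 3 * j] = x[j][3 * i + k];
        vp[i + nat * k + nat * 3 * j] = v[j][3 * i + k];
      }
  xp.attr("dim") = IntegerVector::create(nat, 3, P);
  vp.attr("dim") = IntegerVector::create(nat, 3, P);
  if (nfr > 0)
    frames.attr("dim") = IntegerVector::create(nat, 3, P, nfr);
  return List::create(
      _["time"] = r_time, _["pe"] = r_pe, _["ke"] = r_ke,
      _["spring"] = r_spring, _["ke_primitive"] = r_keprim,
      _["ke_virial"] = r_kevir, _["frames"] = frames,
      _["frame_time"] = frame_time, _["positions"] = xp,
      _["velocities"] = vp);
}

// ---------------------------------------------------------------------------
// Monatomic Lennard-Jones fluid with an optional tabulated pair correction;
// used as the analytically controllable substrate for IBI recovery tests.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List run_lj_md_cpp(NumericMatrix pos0, NumericMatrix vel0, NumericVector cell,
                   double eps, double sigma, double rcut, double mass,
                   List table, double dt, int nsteps, double kT, double gamma,
                   int thermostat, int seed, int record_stride,
                   int frame_stride) {
  const int n = pos0.nrow();
  std::vector<double> x(n * 3), v(n * 3), f(n * 3, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      x[3 * i + k] = pos0(i, k);
      v[3 * i + k] = vel0(i, k);
    }
  PairTable tab;
  if (table.size() > 0) {
    tab.present = true;
    tab.rmin = as<double>(table["r_min"]);
    tab.dr = as<double>(table["dr"]);
    tab.V = as<std::vector<double> >(table["V"]);
    tab.D = as<std::vector<double> >(table["dV"]);
    tab.rmax = tab.rmin + tab.dr * (tab.V.size() - 1);
  }
  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  const double c1 = std::exp(-gamma * dt), c2 = std::sqrt(1.0 - c1 * c1);
  double pe = lj_forces(&x[0], n, &cell[0], eps, sigma, rcut, tab, &f[0]);

  int nrec = nsteps / record_stride;
  NumericVector r_time(nrec), r_pe(nrec), r_ke(nrec);
  int nfr = frame_stride > 0 ? nsteps / frame_stride : 0;
  NumericVector frames(nfr > 0 ? n * 3 * nfr : 0);
  int irec = 0, ifr = 0;

  for (int step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < n * 3; ++i) v[i] += 0.5 * dt * f[i] / mass;
    for (int i = 0; i < n * 3; ++i) x[i] += 0.5 * dt * v[i];
    if (thermostat) {
      double s = std::sqrt(kT / mass);
      for (int i = 0; i < n * 3; ++i) v[i] = c1 * v[i] + c2 * s * gauss(rng);
    }
    for (int i = 0; i < n * 3; ++i) x[i] += 0.5 * dt * v[i];
    std::fill(f.begin(), f.end(), 0.0);
    pe = lj_forces(&x[0], n, &cell[0], eps, sigma, rcut, tab, &f[0]);
    if (!std::isfinite(pe))
      stop("non-finite potential energy at step %d", step);
    for (int i = 0; i < n * 3; ++i) v[i] += 0.5 * dt * f[i] / mass;

    if (step % record_stride == 0 && irec < nrec) {
      double ke = 0.0;
      for (int i = 0; i < n * 3; ++i) ke += 0.5 * mass * v[i] * v[i];
      r_time[irec] = step * dt;
      r_pe[irec] = pe;
      r_ke[irec] = ke;
      ++irec;
    }
    if (frame_stride > 0 && step % frame_stride == 0 && ifr < nfr) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          frames[ifr * n * 3 + k * n + i] = x[3 * i + k];
      ++ifr;
    }
  }
  NumericMatrix xf(n, 3), vf(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      xf(i, k) = x[3 * i + k];
      vf(i, k) = v[3 * i + k];
    }
  if (nfr > 0) frames.attr("dim") = IntegerVector::create(n, 3, nfr);
  return List::create(_["time"] = r_time, _["pe"] = r_pe, _["ke"] = r_ke,
                      _["frames"] = frames, _["positions"] = xf,
                      _["velocities"] = vf);
}
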