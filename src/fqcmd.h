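#pragma once
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>

// Uniform-grid cubic-Hermite pair table with nodal derivatives.
// Below rmin: linear continuation at constant force (counted, never thrown).
// At and beyond rmax: identically zero (tables are built pre-switched).
struct PairTable {
  bool present = false;
  double rmin = 0.0, dr = 1.0, rmax = 0.0;
  std::vector<double> V, D;
  long extrap = 0;

  inline void eval(double r, double& v, double& dvdr) {
    if (!present || r >= rmax) { v = 0.0; dvdr = 0.0; return; }
    if (r < rmin) {
      ++extrap;
      v = V[0] + D[0] * (r - rmin);
      dvdr = D[0];
      return;
    }
    double t = (r - rmin) / dr;
    int i = (int)t;
    int n = (int)V.size();
    if (i >= n - 1) { v = 0.0; dvdr = 0.0; return; }
    double s = t - i;
    double s2 = s * s, s3 = s2 * s;
    double h00 = 2 * s3 - 3 * s2 + 1, h10 = s3 - 2 * s2 + s;
    double h01 = -2 * s3 + 3 * s2, h11 = s3 - s2;
    v = h00 * V[i] + h10 * dr * D[i] + h01 * V[i + 1] + h11 * dr * D[i + 1];
    double g00 = 6 * s2 - 6 * s, g10 = 3 * s2 - 4 * s + 1;
    double g01 = -6 * s2 + 6 * s, g11 = 3 * s2 - 2 * s;
    dvdr = (g00 * V[i] + g01 * V[i + 1]) / dr + g10 * D[i] + g11 * D[i + 1];
  }
};

struct WaterParams {
  double req, Dr, ar, ktheta, thetaeq;
  double sigma, eps, qH, gammaM;
  double mO, mH;
  double rcut, alpha;
  bool dsf;  // damped-shifted-force Coulomb; false = bare 1/r within cutoff
};

struct Corrections {
  std::vector<double> dvr;   // poly coeffs in powers of (r - req), c0..c4
  std::vector<double> dvth;  // poly coeffs in powers of (theta - thetaeq), c0..c2
  // polynomials are trusted only on the interval that informed the fit;
  // outside it they continue linearly (constant force), like the tables
  double dvr_lo = -1e30, dvr_hi = 1e30;
  double dvth_lo = -1e30, dvth_hi = 1e30;
  PairTable oo, oh, hh;
  bool any_intra = false, any_pair = false;
};

WaterParams parse_water_params(const Rcpp::List& params);
Corrections parse_corrections(const Rcpp::List& corr, const WaterParams& wp);

// comps: [0] intra classical, [1] intra correction, [2] LJ, [3] Coulomb,
// [4] pair correction. Returns total energy; adds forces into frc (must be
// zero-initialised by the caller).
double water_forces(const double* pos, int nmol, const double* cell,
                    const WaterParams& wp, Corrections& co,
                    bool do_intra, bool do_inter,
                    double* frc, double* comps);

void water_dipole(const double* pos, const double* vel, int nmol,
                  const double* cell, const WaterParams& wp,
                  double* mu, double* mudot);

double lj_forces(const double* pos, int n, const double* cell,
                 double eps, double sigma, double rcut, PairTable& tab,
                 double* frc);

inline double min_image(double d, double L) { return d - L * std::round(d / L); }
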