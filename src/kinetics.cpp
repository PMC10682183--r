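// Amyloid kinetics kernel: rate functions for the two mechanism variants,
// and the fixed-step fine-clock integrator (modified-midpoint reaction step,
// exact-amount dilution for changing volumes, explicit first-order partition
// while a mother/bud link is open).
//
// State layout (molar): [0] C_M, [1] C_A1, [2] C_MA1, [3] C_A2, [4] C_MA2.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double POS_FLOOR = 1e-30;  // number-concentration positivity floor

struct Kin {
  int mech;  // 0 = standard_breakage, 1 = munching
  double fM, bM, fN, fG, bG, fA1, bA1, fA2, bA2;
  double caa_basal, psi, omega;
  bool fM_on;
};

static Kin kin_from_list(const List& k, bool fM_on = true) {
  Kin p;
  std::string mech = as<std::string>(k["mechanism"]);
  p.mech = (mech == "munching") ? 1 : 0;
  p.fM = k["f_M"]; p.bM = k["b_M"]; p.fN = k["f_N"];
  p.fG = k["f_G"]; p.bG = k["b_G"];
  p.fA1 = k["f_A1"]; p.bA1 = k["b_A1"];
  p.fA2 = k["f_A2"]; p.bA2 = k["b_A2"];
  p.caa_basal = k["C_AA_basal"]; p.psi = k["psi"]; p.omega = k["Omega"];
  p.fM_on = fM_on;
  return p;
}

static inline double amino_pool(const Kin& p, double cma1, double cma2) {
  double s = cma1 + cma2;
  return p.caa_basal * (1.0 - p.psi * s / (p.omega + s));
}

// the five time derivatives (M/s); b_N is aliased to b_G throughout
static void rates(const Kin& p, const double* y, double* dy) {
  const double cm = y[0], ca1 = y[1], cma1 = y[2], ca2 = y[3], cma2 = y[4];
  const double caa = amino_pool(p, cma1, cma2);
  const double prod = p.fM_on ? p.fM * caa : 0.0;
  if (p.mech == 0) {
    // standard breakage / clumping
    const double i1 = (ca1 > POS_FLOOR) ? cma1 / ca1 : 0.0;
    const double i2 = (ca2 > POS_FLOOR) ? cma2 / ca2 : 0.0;
    dy[0] = prod - p.bM * cm - 2.0 * p.fN * cm * cm + 2.0 * p.bG * ca1
            - p.fG * ca1 * cm - 2.0 * p.fG * ca2 * cm;
    dy[1] = p.fN * cm * cm + p.bG * (cma1 - 3.0 * ca1)
            - 2.0 * p.fA1 * ca1 * ca1 - 2.0 * p.fA2 * ca1 * ca1
            + 2.0 * p.bA2 * ca2;
    dy[2] = 2.0 * p.fN * cm * cm + p.fG * ca1 * cm - 2.0 * p.bG * ca1
            - 2.0 * p.fA2 * ca1 * ca1 * i1 + p.bA2 * ca2 * i2;
    dy[3] = p.fA2 * ca1 * ca1 - p.bA2 * ca2;
    dy[4] = 2.0 * p.fG * ca2 * cm + 2.0 * p.fA2 * ca1 * ca1 * i1
            - p.bA2 * ca2 * i2;
  } else {
    // position-dependent breakage ('munching'); single filaments only
    double c2 = 0.0;
    if (ca1 > POS_FLOOR) {
      const double i1 = cma1 / ca1;
      if (i1 <= 2.0 + 1e-9) {
        c2 = ca1;  // all fibrils are dimers
      } else {
        const double kq = 1.0 / (i1 - 2.0);
        // exponential length distribution, geometric sum in closed form
        c2 = ca1 * (1.0 - std::exp(-kq));
      }
    }
    dy[0] = prod - p.bM * cm - 2.0 * p.fN * cm * cm + 2.0 * p.bG * ca1
            - p.fG * ca1 * cm;
    dy[1] = p.fN * cm * cm + c2 * (p.bA1 - p.bG) + p.bA1 * cma1
            - 3.0 * p.bA1 * ca1 - p.fA1 * ca1 * ca1;
    dy[2] = 2.0 * p.fN * cm * cm - 2.0 * p.bG * ca1 + p.fG * ca1 * cm;
    dy[3] = 0.0;
    dy[4] = 0.0;
  }
}

static inline void clamp_state(double* y) {
  for (int s = 0; s < 5; ++s) {
    if (y[s] < 0.0) y[s] = 0.0;
    if (!R_finite(y[s]))
      stop("non-finite concentration (species %d) during integration", s + 1);
  }
}

// one modified-midpoint (RK2) reaction step of length dt
static inline void rk2_step(const Kin& p, double* y, double dt) {
  double k1[5], ymid[5], k2[5];
  rates(p, y, k1);
  for (int s = 0; s < 5; ++s) ymid[s] = y[s] + 0.5 * dt * k1[s];
  rates(p, ymid, k2);
  for (int s = 0; s < 5; ++s) y[s] += dt * k2[s];
  clamp_state(y);
}

// [[Rcpp::export]]
NumericVector chem_rates_cpp(NumericVector state, List kin) {
  if (is_true(any(state < 0))) stop("negative concentrations are not allowed");
  Kin p = kin_from_list(kin);
  double dy[5];
  rates(p, REAL(state), dy);
  return NumericVector(dy, dy + 5);
}

// Integrate one cell for n steps of length dt (seconds).  Volume follows a
// linear path V1 -> V2 (dilution applied before the reaction step, exactly
// conserving amounts when rates are zero).  If n_record > 0 the state is
// sampled n_record times, evenly spaced, plus the initial point.
// [[Rcpp::export]]
List chem_integrate_cpp(NumericVector state, List kin, double dt, int n,
                        double V1, double V2, int n_record = 0) {
  Kin p = kin_from_list(kin);
  double y[5];
  for (int s = 0; s < 5; ++s) y[s] = state[s];
  const bool vol_change = (V1 != V2);

  int nrec = n_record > 0 ? n_record + 1 : 0;
  NumericMatrix samples(nrec, 7);  // t, 5 species, volume
  int rec_every = n_record > 0 ? std::max(1, n / n_record) : 0;
  int ri = 0;
  if (nrec > 0) {
    samples(0, 0) = 0.0;
    for (int s = 0; s < 5; ++s) samples(0, s + 1) = y[s];
    samples(0, 6) = V1;
    ri = 1;
  }

  for (int m = 0; m < n; ++m) {
    if (vol_change) {
      double Vc = V1 + (V2 - V1) * (double)m / n;
      double Vn = V1 + (V2 - V1) * (double)(m + 1) / n;
      double f = Vc / Vn;
      for (int s = 0; s < 5; ++s) y[s] *= f;
    }
    rk2_step(p, y, dt);
    if (nrec > 0 && ((m + 1) % rec_every == 0 || m == n - 1) && ri < nrec) {
      samples(ri, 0) = (m + 1) * dt;
      for (int s = 0; s < 5; ++s) samples(ri, s + 1) = y[s];
      samples(ri, 6) = V1 + (V2 - V1) * (double)(m + 1) / n;
      ++ri;
    }
  }
  NumericVector out(y, y + 5);
  out.names() = state.names();
  if (nrec > 0 && ri < nrec) samples = samples(Range(0, ri - 1), _);
  return List::create(_["state"] = out, _["samples"] = samples);
}

// Integrate a mother (alpha, fixed volume Valpha) / bud (beta, volume growing
// linearly Vb1 -> Vb2) pair with first-order partition while the septum is
// open.  Monomer production (f_M) can be disabled in the bud.  Partition
// constants are per species class: kab/kba = (M, A1, A2).
// [[Rcpp::export]]
List chem_integrate_pair_cpp(NumericVector stateA, NumericVector stateB,
                             List kin, NumericVector kab, NumericVector kba,
                             double dt, int n, double Valpha,
                             double Vb1, double Vb2,
                             bool beta_fM_off = true, int n_record = 0) {
  Kin pa = kin_from_list(kin, true);
  Kin pb = kin_from_list(kin, !beta_fM_off);
  double a[5], b[5];
  for (int s = 0; s < 5; ++s) { a[s] = stateA[s]; b[s] = stateB[s]; }
  // species class per state slot: M, A1, A1, A2, A2
  const int cls[5] = {0, 1, 1, 2, 2};

  int nrec = n_record > 0 ? n_record + 1 : 0;
  NumericMatrix sampA(nrec, 7), sampB(nrec, 7);
  int rec_every = n_record > 0 ? std::max(1, n / n_record) : 0;
  int ri = 0;
  if (nrec > 0) {
    sampA(0, 0) = sampB(0, 0) = 0.0;
    for (int s = 0; s < 5; ++s) { sampA(0, s + 1) = a[s]; sampB(0, s + 1) = b[s]; }
    sampA(0, 6) = Valpha; sampB(0, 6) = Vb1;
    ri = 1;
  }

  for (int m = 0; m < n; ++m) {
    double Vc = Vb1 + (Vb2 - Vb1) * (double)m / n;
    double Vn = Vb1 + (Vb2 - Vb1) * (double)(m + 1) / n;
    // (1) dilution of the growing bud
    if (Vn != Vc) { double f = Vc / Vn; for (int s = 0; s < 5; ++s) b[s] *= f; }
    // (2) reaction in each compartment
    rk2_step(pa, a, dt);
    rk2_step(pb, b, dt);
    // (3) explicit partition exchange; alpha side carries the volume factor
    double r = Vn / Valpha;
    double fa[5], fb[5];
    for (int s = 0; s < 5; ++s) {
      int c = cls[s];
      fa[s] = r * (-kab[c] * a[s] + kba[c] * b[s]);
      fb[s] = -kba[c] * b[s] + kab[c] * a[s];
    }
    for (int s = 0; s < 5; ++s) { a[s] += dt * fa[s]; b[s] += dt * fb[s]; }
    clamp_state(a);
    clamp_state(b);
    if (nrec > 0 && ((m + 1) % rec_every == 0 || m == n - 1) && ri < nrec) {
      sampA(ri, 0) = sampB(ri, 0) = (m + 1) * dt;
      for (int s = 0; s < 5; ++s) { sampA(ri, s + 1) = a[s]; sampB(ri, s + 1) = b[s]; }
      sampA(ri, 6) = Valpha; sampB(ri, 6) = Vn;
      ++ri;
    }
  }
  NumericVector outA(a, a + 5), outB(b, b + 5);
  outA.names() = stateA.names(); outB.names() = stateB.names();
  if (nrec > 0 && ri < nrec) {
    sampA = sampA(Range(0, ri - 1), _);
    sampB = sampB(Range(0, ri - 1), _);
  }
  return List::create(_["state_alpha"] = outA, _["state_beta"] = outB,
                      _["samples_alpha"] = sampA, _["samples_beta"] = sampB);
}
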