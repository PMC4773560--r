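#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// State layout (35 entries, concentrations in nmol/L):
//   0 CHOL  medium cholesterol
//   1 CHOS  stored cholesterol esters          (intracellular)
//   2 CHOC  intracellular free cholesterol
//   3 CHOM  mitochondrial free cholesterol
//   4 CHOR  mitochondrial cholesterol remote from CYP11A1
//   5 CHON  mitochondrial cholesterol proximal to CYP11A1
//   6 OXY   oxysterol sink                     (intracellular)
//   7..20   14 steroids, intracellular
//  21..34   14 steroids, culture medium
// Steroid order: PREG HPREG DHEA PROG HPROG DIONE TESTO DCORTICO DCORT
//                CORTICO CORT ALDO E1 E2

#define N_STATE 35
#define N_STEROID 14
#define IDX_INTRA(i) (7 + (i))
#define IDX_MED(i) (21 + (i))

enum Steroid { PREG = 0, HPREG, DHEA, PROG, HPROG, DIONE, TESTO,
               DCORTICO, DCORT, CORTICO, CORT, ALDO, E1, E2 };

// kinetic inventory, items 1-42 (0-based here)
enum Kin {
  K_CT = 0, K_CEH, K_F_MTR, K_B_MTR, K_F_ACC, K_B_ACC, K_F_LOC, K_B_LOC,
  K_OXY,
  KM_11A1, VM_11A1,
  KMA_17H, KMB_17H, VMA_17H, VMB_17H,
  KMA_17L, KMB_17L, VMA_17L, VMB_17L,
  KMA_3B2, KMB_3B2, KMC_3B2, VMA_3B2, VMB_3B2, VMC_3B2,
  KMA_21A2, KMB_21A2, VMA_21A2, VMB_21A2,
  KMA_11B1, KMB_11B1, VMA_11B1, VMB_11B1,
  K_11B2,
  KMA_17B3, KMB_17B3, VMA_17B3, VMB_17B3,
  KMA_19A1, KMB_19A1, VMA_19A1, VMB_19A1
};

// enzyme activity multipliers
enum Enz { E_11A1 = 0, E_17H, E_17L, E_3B2, E_21A2, E_11B1, E_11B2,
           E_17B3, E_19A1 };

struct ModelPars {
  const double *kin;      // 42 kinetic inventory values
  const double *act;      // 9 enzyme activity multipliers
  const double *diff_f;   // 14 medium -> cell diffusion constants (1/h)
  const double *diff_b;   // 14 cell -> medium diffusion constants (1/h)
  double kdist_f, kdist_b; // CHOM <-> CHOR exchange (1/h)
  double n0, g_n, v0, g_v; // cell count / single-cell volume exponentials
  double v_med;            // medium volume (mL)
  bool dilution;           // dilute intracellular pools by volume growth
};

static inline double pos(double s) { return s > 0.0 ? s : 0.0; }

// Competing-substrate rapid-equilibrium kinetics for one enzyme:
// v_i = act * Vmax_i * (S_i/Km_i) / (1 + sum_j S_j/Km_j)
static void enzyme_block(const double *x, double *dx, double act,
                         const int *sub, const int *prod,
                         const double *Km, const double *Vm, int n,
                         double &maxrate) {
  double denom = 1.0;
  for (int i = 0; i < n; ++i) denom += pos(x[IDX_INTRA(sub[i])]) / Km[i];
  for (int i = 0; i < n; ++i) {
    double v = act * Vm[i] * (pos(x[IDX_INTRA(sub[i])]) / Km[i]) / denom;
    dx[IDX_INTRA(sub[i])] -= v;
    dx[IDX_INTRA(prod[i])] += v;
    if (std::fabs(v) > maxrate) maxrate = std::fabs(v);
  }
}

// Full RHS. Returns the maximum absolute flux velocity (used for the
// adaptive time step), with cross-compartment fluxes considered in both
// compartments' concentration units.
static double rhs(double t, const double *x, double *dx,
                  const ModelPars &P) {
  for (int i = 0; i < N_STATE; ++i) dx[i] = 0.0;
  double maxrate = 0.0;
  const double *k = P.kin;

  double v_cell = P.n0 * P.v0 * std::exp((P.g_n + P.g_v) * t); // mL
  double med_to_cell = P.v_med / v_cell;  // concentration conversion
  double cell_to_med = v_cell / P.v_med;

  // cholesterol uptake: CHOL (medium) -> CHOC
  {
    double v = k[K_CT] * pos(x[0]);
    dx[0] -= v;
    dx[2] += v * med_to_cell;
    double m = std::max(v, v * med_to_cell);
    if (m > maxrate) maxrate = m;
  }
  // ester storage CHOC -> CHOS and release/hydrolysis CHOS -> CHOC
  {
    double vf = k[K_F_ACC] * pos(x[2]);
    double vb = (k[K_B_ACC] + k[K_CEH]) * pos(x[1]);
    dx[2] += vb - vf;
    dx[1] += vf - vb;
    if (vf > maxrate) maxrate = vf;
    if (vb > maxrate) maxrate = vb;
  }
  // cytosol <-> mitochondria: CHOC <-> CHOM
  {
    double vf = k[K_F_MTR] * pos(x[2]);
    double vb = k[K_B_MTR] * pos(x[3]);
    dx[2] += vb - vf;
    dx[3] += vf - vb;
    if (vf > maxrate) maxrate = vf;
    if (vb > maxrate) maxrate = vb;
  }
  // intramitochondrial distribution: CHOM <-> CHOR
  {
    double vf = P.kdist_f * pos(x[3]);
    double vb = P.kdist_b * pos(x[4]);
    dx[3] += vb - vf;
    dx[4] += vf - vb;
    if (vf > maxrate) maxrate = vf;
    if (vb > maxrate) maxrate = vb;
  }
  // StAR-mediated localization: CHOR <-> CHON
  {
    double vf = k[K_F_LOC] * pos(x[4]);
    double vb = k[K_B_LOC] * pos(x[5]);
    dx[4] += vb - vf;
    dx[5] += vf - vb;
    if (vf > maxrate) maxrate = vf;
    if (vb > maxrate) maxrate = vb;
  }
  // oxysterol bypass: CHOC -> OXY (pure sink)
  {
    double v = k[K_OXY] * pos(x[2]);
    dx[2] -= v;
    dx[6] += v;
    if (v > maxrate) maxrate = v;
  }

  // 17 enzymatic reactions, all intracellular
  {
    // CYP11A1: CHON -> PREG (single substrate; CHON is state 5, handled
    // directly because it is not in the steroid block)
    double s = pos(x[5]);
    double v = P.act[E_11A1] * k[VM_11A1] * (s / k[KM_11A1]) /
               (1.0 + s / k[KM_11A1]);
    dx[5] -= v;
    dx[IDX_INTRA(PREG)] += v;
    if (v > maxrate) maxrate = v;
  }
  {
    const int sub[2] = {PREG, PROG}, prod[2] = {HPREG, HPROG};
    const double Km[2] = {k[KMA_17H], k[KMB_17H]};
    const double Vm[2] = {k[VMA_17H], k[VMB_17H]};
    enzyme_block(x, dx, P.act[E_17H], sub, prod, Km, Vm, 2, maxrate);
  }
  {
    const int sub[2] = {HPREG, HPROG}, prod[2] = {DHEA, DIONE};
    const double Km[2] = {k[KMA_17L], k[KMB_17L]};
    const double Vm[2] = {k[VMA_17L], k[VMB_17L]};
    enzyme_block(x, dx, P.act[E_17L], sub, prod, Km, Vm, 2, maxrate);
  }
  {
    const int sub[3] = {PREG, HPREG, DHEA}, prod[3] = {PROG, HPROG, DIONE};
    const double Km[3] = {k[KMA_3B2], k[KMB_3B2], k[KMC_3B2]};
    const double Vm[3] = {k[VMA_3B2], k[VMB_3B2], k[VMC_3B2]};
    enzyme_block(x, dx, P.act[E_3B2], sub, prod, Km, Vm, 3, maxrate);
  }
  {
    const int sub[2] = {PROG, HPROG}, prod[2] = {DCORTICO, DCORT};
    const double Km[2] = {k[KMA_21A2], k[KMB_21A2]};
    const double Vm[2] = {k[VMA_21A2], k[VMB_21A2]};
    enzyme_block(x, dx, P.act[E_21A2], sub, prod, Km, Vm, 2, maxrate);
  }
  {
    const int sub[2] = {DCORTICO, DCORT}, prod[2] = {CORTICO, CORT};
    const double Km[2] = {k[KMA_11B1], k[KMB_11B1]};
    const double Vm[2] = {k[VMA_11B1], k[VMB_11B1]};
    enzyme_block(x, dx, P.act[E_11B1], sub, prod, Km, Vm, 2, maxrate);
  }
  {
    // CYP11B2: CORTICO -> ALDO, first-order
    double v = P.act[E_11B2] * k[K_11B2] * pos(x[IDX_INTRA(CORTICO)]);
    dx[IDX_INTRA(CORTICO)] -= v;
    dx[IDX_INTRA(ALDO)] += v;
    if (v > maxrate) maxrate = v;
  }
  {
    const int sub[2] = {DIONE, E1}, prod[2] = {TESTO, E2};
    const double Km[2] = {k[KMA_17B3], k[KMB_17B3]};
    const double Vm[2] = {k[VMA_17B3], k[VMB_17B3]};
    enzyme_block(x, dx, P.act[E_17B3], sub, prod, Km, Vm, 2, maxrate);
  }
  {
    const int sub[2] = {DIONE, TESTO}, prod[2] = {E1, E2};
    const double Km[2] = {k[KMA_19A1], k[KMB_19A1]};
    const double Vm[2] = {k[VMA_19A1], k[VMB_19A1]};
    enzyme_block(x, dx, P.act[E_19A1], sub, prod, Km, Vm, 2, maxrate);
  }

  // passive diffusion of steroids between medium and intracellular space
  for (int i = 0; i < N_STEROID; ++i) {
    double f = P.diff_f[i] * pos(x[IDX_MED(i)]) -
               P.diff_b[i] * pos(x[IDX_INTRA(i)]);
    dx[IDX_INTRA(i)] += f;
    dx[IDX_MED(i)] -= f * cell_to_med;
    double m = std::max(std::fabs(f), std::fabs(f) * cell_to_med);
    if (m > maxrate) maxrate = m;
  }

  // dilution of intracellular concentrations by cell-volume growth
  if (P.dilution) {
    double g = P.g_n + P.g_v;
    for (int i = 1; i <= 20; ++i) dx[i] -= g * x[i];
  }
  return maxrate;
}

static ModelPars unpack(const List &pars) {
  ModelPars P;
  P.kin = REAL(as<NumericVector>(pars["kin"]));
  P.act = REAL(as<NumericVector>(pars["act"]));
  P.diff_f = REAL(as<NumericVector>(pars["diff_f"]));
  P.diff_b = REAL(as<NumericVector>(pars["diff_b"]));
  P.kdist_f = as<double>(pars["kdist_f"]);
  P.kdist_b = as<double>(pars["kdist_b"]);
  P.n0 = as<double>(pars["n0"]);
  P.g_n = as<double>(pars["g_n"]);
  P.v0 = as<double>(pars["v0"]);
  P.g_v = as<double>(pars["g_v"]);
  P.v_med = as<double>(pars["v_med"]);
  P.dilution = as<bool>(pars["dilution"]);
  return P;
}

// [[Rcpp::export]]
List cpp_rhs(double t, NumericVector state, List pars) {
  if (state.size() != N_STATE) stop("state must have length %d", N_STATE);
  ModelPars P = unpack(pars);
  NumericVector dx(N_STATE);
  double maxrate = rhs(t, REAL(state), REAL(dx), P);
  return List::create(_["deriv"] = dx, _["max_rate"] = maxrate);
}

// [[Rcpp::export]]
List cpp_simulate(NumericVector state0, NumericVector record_times,
                  List pars, double dt_min, double dt_max, double c_step,
                  double fixed_dt, bool keep_dt_log) {
  if (state0.size() != N_STATE) stop("state must have length %d", N_STATE);
  ModelPars P = unpack(pars);
  int nrec = record_times.size();
  NumericMatrix out(nrec, N_STATE);
  std::vector<double> dt_log;

  double x[N_STATE], xt[N_STATE];
  double k1[N_STATE], k2[N_STATE], k3[N_STATE], k4[N_STATE];
  for (int i = 0; i < N_STATE; ++i) x[i] = state0[i];
  double t = record_times[0];
  for (int i = 0; i < N_STATE; ++i) out(0, i) = x[i];

  long nsteps = 0;
  double dt_used_min = R_PosInf, dt_used_max = 0.0;
  const double eps = 1e-12;

  for (int r = 1; r < nrec; ++r) {
    double T = record_times[r];
    if (T <= t) stop("record times must be strictly increasing");
    while (t < T - eps) {
      double maxrate = rhs(t, x, k1, P);
      double dt;
      if (fixed_dt > 0.0) {
        dt = fixed_dt;
      } else if (maxrate <= 0.0) {
        dt = dt_max;
      } else {
        dt = c_step / maxrate;
        if (dt < dt_min) dt = dt_min;
        if (dt > dt_max) dt = dt_max;
      }
      bool landing = false;
      if (t + dt >= T - eps) { dt = T - t; landing = true; }
      // classic RK4 step
      for (int i = 0; i < N_STATE; ++i) xt[i] = x[i] + 0.5 * dt * k1[i];
      rhs(t + 0.5 * dt, xt, k2, P);
      for (int i = 0; i < N_STATE; ++i) xt[i] = x[i] + 0.5 * dt * k2[i];
      rhs(t + 0.5 * dt, xt, k3, P);
      for (int i = 0; i < N_STATE; ++i) xt[i] = x[i] + dt * k3[i];
      rhs(t + dt, xt, k4, P);
      for (int i = 0; i < N_STATE; ++i) {
        x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
        if (!std::isfinite(x[i]))
          stop("non-finite state at t = %g (state index %d, dt = %g)",
               t + dt, i + 1, dt);
      }
      t = landing ? T : t + dt;
      ++nsteps;
      if (dt < dt_used_min) dt_used_min = dt;
      if (dt > dt_used_max) dt_used_max = dt;
      if (keep_dt_log) dt_log.push_back(dt);
      if (nsteps % 1048576 == 0) checkUserInterrupt();
    }
    t = T;
    for (int i = 0; i < N_STATE; ++i) out(r, i) = x[i];
  }

  List res = List::create(
      _["states"] = out, _["n_steps"] = (double)nsteps,
      _["dt_used_min"] = dt_used_min, _["dt_used_max"] = dt_used_max);
  if (keep_dt_log) res["dt_log"] = NumericVector(dt_log.begin(), dt_log.end());
  return res;
}
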