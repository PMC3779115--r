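// Human atrial myocyte model and monodomain tissue stepper.
//
// The cell model is a CRN-family formulation: Luo-Rudy style INa, CRN
// ICaL/IKr/IKs/IK1/pumps/exchanger, Nygren/Maleckar-style Ito and IKur
// kinetics, and a two-compartment sarcoplasmic-reticulum Ca2+ handling
// system (one uptake pool, one release pool) with the cytosol split into
// a peripheral (subsarcolemmal) and an interior compartment.
//
// Units: mV, ms, pA/pF, mM. Volumes in um^3, F in C/mmol (so that
// pA / (F * um^3) = mM/ms after the Cm scaling used below).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NSTATE = 23;

// state layout
enum {
  iV = 0, im, ih, ij, id_, if1, if2, ifca, itoa, itoi, ikura, ikuri, ixr, ixs,
  iu, iv_, iw, iNai, iKi, iCasub, iCacen, iCaup, iCarel
};

// parameter layout (must match R side channel_params())
enum {
  pgNa = 0, pgCaL, pgto, pgKur, pgKr, pgKs, pgK1,
  pkNaCa, piNaK, pipCa, pgbNa, pgbCa,
  pserca, pryr, pleak,
  pshiftto, ptauCaL, pCm,
  NPAR
};

// fixed physical constants
static const double Rgas = 8.3143, Temp = 310.0, Frdy = 96.4867;
static const double Nao = 140.0, Ko = 5.4, Cao = 1.8;
static const double Vcell = 20100.0;
static const double Vi = 13668.0;          // total cytosol
static const double frac_sub = 0.10;       // peripheral fraction of cytosol
static const double Vsub = frac_sub * Vi, Vcen = (1.0 - frac_sub) * Vi;
static const double Vup = 1109.52, Vrel = 96.48;
static const double tau_diff = 2.0;        // sub <-> interior Ca exchange (ms)
static const double CMDN = 0.05, KmCMDN = 0.00238;
static const double SLB = 0.15, KmSLB = 0.0013;  // sarcolemmal sites, peripheral
static const double TRPN = 0.07, KmTRPN = 0.0005;
static const double CSQN = 10.0, KmCSQN = 0.8;
static const double Iup_max = 0.005, Kup = 0.00092, Caup_max = 15.0;
static const double tau_tr = 180.0, krel = 30.0;
static const double KmNai = 10.0, KmKo = 1.5;
static const double KmNa = 87.5, KmCa = 1.38, ksat = 0.1, gam = 0.35;

struct Rates {
  // per-gate steady state and time constant (for Rush-Larsen) indexed as
  // gates m..w (15 gates: indices im..iw in state space)
  double inf[NSTATE];
  double tau[NSTATE];
};

// purely voltage-dependent quantities (tabulated for the tissue solver):
// gate steady states / time constants for the 13 HH gates plus the IK1
// rectification factor, INaK voltage factor, NaCa exponentials and IKr
// rectification
static const int NVG = 13;  // m h j d f1 f2 toa toi kura kuri xr xs w
static const int vg_state[NVG] = { im, ih, ij, id_, if1, if2, itoa, itoi,
                                   ikura, ikuri, ixr, ixs, iw };
struct VDep {
  double inf[NVG], tau[NVG];
  double k1f, fnak, eg, egm, krr;
};

struct VTab {
  double vmin, vmax, dv;
  int n;
  std::vector<VDep> t;
  void build(const double *p);
  inline void get(double V, VDep &out) const {
    double x = (V - vmin) / dv;
    if (x < 0) x = 0;
    if (x > n - 2) x = n - 2;
    int i = (int)x;
    double f = x - i;
    const VDep &a = t[i], &b = t[i + 1];
    for (int k = 0; k < NVG; ++k) {
      out.inf[k] = a.inf[k] + f * (b.inf[k] - a.inf[k]);
      out.tau[k] = a.tau[k] + f * (b.tau[k] - a.tau[k]);
    }
    out.k1f = a.k1f + f * (b.k1f - a.k1f);
    out.fnak = a.fnak + f * (b.fnak - a.fnak);
    out.eg = a.eg + f * (b.eg - a.eg);
    out.egm = a.egm + f * (b.egm - a.egm);
    out.krr = a.krr + f * (b.krr - a.krr);
  }
};

struct Currents {
  double INa, ICaL, Ito, IKur, IKr, IKs, IK1, INaCa, INaK, IpCa, IbNa, IbCa;
  double total;
};

static inline double safe_div(double num, double den, double lim) {
  // removable singularities of the form x/(1-exp(-x)) etc.
  return std::fabs(den) < 1e-10 ? lim : num / den;
}

// analytic voltage-dependent rates and factors
static void voltage_dep(double V, const double *p, VDep &vd) {
  const double RTF = Rgas * Temp / Frdy;
  // --- INa (Luo-Rudy kinetics as in CRN) ---
  double am = safe_div(0.32 * (V + 47.13), 1.0 - std::exp(-0.1 * (V + 47.13)), 3.2);
  double bm = 0.08 * std::exp(-V / 11.0);
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.135 * std::exp(-(V + 80.0) / 6.8);
    bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  vd.inf[0] = am / (am + bm); vd.tau[0] = 1.0 / (am + bm);
  vd.inf[1] = ah / (ah + bh); vd.tau[1] = 1.0 / (ah + bh);
  vd.inf[2] = aj / (aj + bj); vd.tau[2] = 1.0 / (aj + bj);

  // --- ICaL: CRN activation, fast + slow voltage inactivation gates ---
  double dinf = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
  double e1 = std::exp(-(V + 10.0) / 6.24);
  double taud = safe_div(1.0 - e1, 0.035 * (V + 10.0) * (1.0 + e1), 1.0 / (0.035 * 6.24 * 2.0));
  double finf = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  double zf1 = (V + 40.0) / 14.4;
  double tauf1 = 161.0 * std::exp(-zf1 * zf1) + 10.0;
  double zf2 = (V + 40.0) / 14.2;
  double tauf2 = 1332.3 * std::exp(-zf2 * zf2) + 62.6;
  vd.inf[3] = dinf;  vd.tau[3] = taud * p[ptauCaL];
  vd.inf[4] = finf;  vd.tau[4] = tauf1 * p[ptauCaL];
  vd.inf[5] = finf;  vd.tau[5] = tauf2 * p[ptauCaL];

  // --- Ito (Nygren/Maleckar-style kinetics) ---
  double sh = p[pshiftto];
  vd.inf[6] = 1.0 / (1.0 + std::exp(-(V + 1.0) / 11.0));
  vd.tau[6] = 3.5 * std::exp(-(V / 30.0) * (V / 30.0)) + 1.5;
  vd.inf[7] = 1.0 / (1.0 + std::exp((V + 40.5 - sh) / 11.5));
  {
    double z = (V + 52.45 - sh) / 15.95;
    vd.tau[7] = 25.635 * std::exp(-z * z) + 14.14;
  }

  // --- IKur (sustained outward, Nygren/Maleckar-style) ---
  vd.inf[8] = 1.0 / (1.0 + std::exp(-(V + 15.0) / 8.6));
  vd.tau[8] = 9.0 / (1.0 + std::exp((V + 5.0) / 12.0)) + 0.5;
  vd.inf[9] = 0.4 / (1.0 + std::exp((V + 20.0) / 10.0)) + 0.6;
  vd.tau[9] = 47.0 / (1.0 + std::exp((V + 60.0) / 10.0)) + 300.0;

  // --- IKr ---
  double axr = safe_div(0.0003 * (V + 14.1), 1.0 - std::exp(-(V + 14.1) / 5.0), 0.0015);
  double bxr = safe_div(7.3898e-5 * (V - 3.3328),
                        std::exp((V - 3.3328) / 5.1237) - 1.0, 7.3898e-5 * 5.1237);
  vd.inf[10] = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
  vd.tau[10] = 1.5 / (axr + bxr);
  vd.krr = 1.0 / (1.0 + std::exp((V + 15.0) / 22.4));

  // --- IKs ---
  double axs = safe_div(4e-5 * (V - 19.9), 1.0 - std::exp(-(V - 19.9) / 17.0), 4e-5 * 17.0);
  double bxs = safe_div(3.5e-5 * (V - 19.9), std::exp((V - 19.9) / 9.0) - 1.0, 3.5e-5 * 9.0);
  vd.inf[11] = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));
  vd.tau[11] = 1.0 / (axs + bxs);  // slow accumulation: IKs engages in long APs

  // --- IK1 rectification (steep, Nygren-family shape) ---
  vd.k1f = 1.0 / (1.0 + std::exp(0.09 * (V + 82.0)));

  // --- pump / exchanger voltage factors ---
  double sig = (std::exp(Nao / 67.3) - 1.0) / 7.0;
  vd.fnak = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTF) +
                   0.0365 * sig * std::exp(-V / RTF));
  vd.eg = std::exp(gam * V / RTF);
  vd.egm = std::exp((gam - 1.0) * V / RTF);

  // --- RyR voltage gate w ---
  vd.inf[12] = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
  {
    double e2 = std::exp(-(V - 7.9) / 5.0);
    vd.tau[12] = safe_div(6.0 * (1.0 - e2), (1.0 + 0.3 * e2) * (V - 7.9),
                          6.0 * 0.2 / 1.3);
  }
}

void VTab::build(const double *p) {
  vmin = -120.0; vmax = 80.0; dv = 0.05;
  n = (int)((vmax - vmin) / dv) + 1;
  t.resize(n);
  for (int i = 0; i < n; ++i) voltage_dep(vmin + i * dv, p, t[i]);
}

// Evaluate all currents, gate rates and concentration derivatives.
// derivs may be NULL when only currents are wanted; tab, when given,
// replaces the analytic voltage-dependent terms by table lookup.
static void cell_eval(const double *s, const double *p,
                      Currents &cur, Rates &rt, double *derivs,
                      double i_stim /* pA/pF, >0 depolarising */,
                      const VTab *tab = 0) {
  const double V = s[iV];
  const double RTF = Rgas * Temp / Frdy;
  const double ENa = RTF * std::log(Nao / s[iNai]);
  const double EK  = RTF * std::log(Ko / s[iKi]);
  const double ECa = 0.5 * RTF * std::log(Cao / s[iCasub]);

  VDep vd;
  if (tab) tab->get(V, vd); else voltage_dep(V, p, vd);
  for (int k = 0; k < NVG; ++k) {
    rt.inf[vg_state[k]] = vd.inf[k];
    rt.tau[vg_state[k]] = vd.tau[k];
  }

  cur.INa = p[pgNa] * s[im] * s[im] * s[im] * s[ih] * s[ij] * (V - ENa);

  // Ca-dependent inactivation senses peripheral Ca; half-saturation scaled
  // to subsarcolemmal (uM-range) levels
  rt.inf[ifca] = 1.0 / (1.0 + s[iCasub] / 0.0030);
  rt.tau[ifca] = 2.0;
  cur.ICaL = p[pgCaL] * s[id_] * s[if1] * s[if2] * s[ifca] * (V - 65.0);

  cur.Ito = p[pgto] * s[itoa] * s[itoi] * (V - EK);
  cur.IKur = p[pgKur] * s[ikura] * s[ikuri] * (V - EK);
  cur.IKr = p[pgKr] * s[ixr] * (V - EK) * vd.krr;
  cur.IKs = p[pgKs] * s[ixs] * s[ixs] * (V - EK);
  cur.IK1 = p[pgK1] * (V - EK) * vd.k1f;

  {
    double tnai = KmNai / s[iNai];
    cur.INaK = p[piNaK] * vd.fnak * (Ko / (Ko + KmKo)) /
               (1.0 + tnai * std::sqrt(tnai));
  }
  cur.INaCa = p[pkNaCa] *
      (vd.eg * s[iNai] * s[iNai] * s[iNai] * Cao -
       vd.egm * Nao * Nao * Nao * s[iCasub]) /
      ((KmNa * KmNa * KmNa + Nao * Nao * Nao) * (KmCa + Cao) *
       (1.0 + ksat * vd.egm));
  cur.IpCa = p[pipCa] * s[iCasub] / (s[iCasub] + 0.0005);
  cur.IbNa = p[pgbNa] * (V - ENa);
  cur.IbCa = p[pgbCa] * (V - ECa);

  cur.total = cur.INa + cur.ICaL + cur.Ito + cur.IKur + cur.IKr + cur.IKs +
              cur.IK1 + cur.INaCa + cur.INaK + cur.IpCa + cur.IbNa + cur.IbCa;

  // --- SR fluxes ---
  double Iup = p[pserca] * Iup_max / (1.0 + Kup / s[iCacen]);
  double Ileak = p[pleak] * Iup_max * s[iCaup] / Caup_max;
  double Itr = (s[iCaup] - s[iCarel]) / tau_tr;
  double Irel = p[pryr] * krel * s[iu] * s[iu] * s[iv_] * s[iw] *
                (s[iCarel] - s[iCasub]);

  // release-channel (RyR) gating driven by local Ca fluxes
  double Fn = 1e3 * (1e-15 * Vrel * Irel -
                     1e-15 / (2.0 * Frdy) * (0.5 * cur.ICaL - 0.2 * cur.INaCa) * p[pCm]);
  rt.inf[iu] = 1.0 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
  rt.tau[iu] = 8.0;
  rt.inf[iv_] = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
  rt.tau[iv_] = 1.91 + 2.09 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
  if (derivs) {
    const double Cm = p[pCm];
    const double cFVi = Cm / (Frdy * Vi);
    // gates: forward-Euler derivative form (Rush-Larsen applied by caller)
    for (int g = im; g <= iw; ++g)
      derivs[g] = (rt.inf[g] - s[g]) / rt.tau[g];
    // membrane potential (i_stim positive depolarising)
    derivs[iV] = -(cur.total - i_stim);
    // Na+, K+ (stimulus charge carried by K+)
    derivs[iNai] = cFVi * (-3.0 * cur.INaK - 3.0 * cur.INaCa - cur.IbNa - cur.INa);
    derivs[iKi]  = cFVi * (2.0 * cur.INaK - cur.IK1 - cur.Ito - cur.IKur -
                           cur.IKr - cur.IKs + i_stim);
    // Ca compartments with rapid-buffer factors
    double bsub = 1.0 / (1.0 + CMDN * KmCMDN /
                         ((s[iCasub] + KmCMDN) * (s[iCasub] + KmCMDN)) +
                         SLB * KmSLB /
                         ((s[iCasub] + KmSLB) * (s[iCasub] + KmSLB)));
    double bcen = 1.0 / (1.0 + CMDN * KmCMDN /
                         ((s[iCacen] + KmCMDN) * (s[iCacen] + KmCMDN)) +
                         TRPN * KmTRPN /
                         ((s[iCacen] + KmTRPN) * (s[iCacen] + KmTRPN)));
    double brel = 1.0 / (1.0 + CSQN * KmCSQN /
                         ((s[iCarel] + KmCSQN) * (s[iCarel] + KmCSQN)));
    double Jdiff = (s[iCasub] - s[iCacen]) / tau_diff;
    derivs[iCasub] = bsub * (Cm * (2.0 * cur.INaCa - cur.ICaL - cur.IpCa - cur.IbCa) /
                             (2.0 * Frdy * Vsub) +
                             Irel * Vrel / Vsub - Jdiff);
    derivs[iCacen] = bcen * (Jdiff * Vsub / Vcen + Vup * (Ileak - Iup) / Vcen);
    derivs[iCaup]  = Iup - Ileak - Itr * Vrel / Vup;
    derivs[iCarel] = brel * (Itr - Irel);
  }
}

static inline void advance(double *s, const double *p, double dt,
                           double i_stim, bool rush_larsen,
                           Currents &cur, Rates &rt, double *d,
                           const VTab *tab = 0) {
  cell_eval(s, p, cur, rt, d, i_stim, tab);
  s[iV]     += dt * d[iV];
  s[iNai]   += dt * d[iNai];
  s[iKi]    += dt * d[iKi];
  s[iCasub] += dt * d[iCasub];
  s[iCacen] += dt * d[iCacen];
  s[iCaup]  += dt * d[iCaup];
  s[iCarel] += dt * d[iCarel];
  if (rush_larsen) {
    for (int g = im; g <= iw; ++g)
      s[g] = rt.inf[g] + (s[g] - rt.inf[g]) * std::exp(-dt / rt.tau[g]);
  } else {
    for (int g = im; g <= iw; ++g) {
      s[g] += dt * d[g];
      if (s[g] < 0.0) s[g] = 0.0;
      if (s[g] > 1.0) s[g] = 1.0;
    }
  }
}

static const char *state_names_c[NSTATE] = {
  "V", "m", "h", "j", "d", "f_1", "f_2", "f_Ca", "to_act", "to_inact",
  "kur_act", "kur_inact", "x_r", "x_s", "ryr_u", "ryr_v", "ryr_w",
  "Na_i", "K_i", "Ca_sub", "Ca_cen", "Ca_up", "Ca_rel"
};

// [[Rcpp::export(name = ".state_names_cpp")]]
CharacterVector state_names_cpp() {
  return CharacterVector(state_names_c, state_names_c + NSTATE);
}

// [[Rcpp::export(name = ".currents_cpp")]]
NumericVector currents_cpp(NumericVector state, NumericVector params) {
  Currents cur; Rates rt;
  cell_eval(REAL(state), REAL(params), cur, rt, (double *)0, 0.0);
  NumericVector out = NumericVector::create(
      _["I_Na"] = cur.INa, _["I_CaL"] = cur.ICaL, _["I_to"] = cur.Ito,
      _["I_Kur"] = cur.IKur, _["I_Kr"] = cur.IKr, _["I_Ks"] = cur.IKs,
      _["I_K1"] = cur.IK1, _["I_NaCa"] = cur.INaCa, _["I_NaK"] = cur.INaK,
      _["I_pCa"] = cur.IpCa, _["I_bNa"] = cur.IbNa, _["I_bCa"] = cur.IbCa,
      _["total"] = cur.total);
  return out;
}

// Single-cell run with a stimulus train.
// stim_times: onsets (ms); amplitude in pA/pF (>0 depolarising), duration ms.
// record_every <= 0 disables trace recording.
// [[Rcpp::export(name = ".run_cell_cpp")]]
List run_cell_cpp(NumericVector state0, NumericVector params,
                  double dt, double t_end,
                  NumericVector stim_times, double stim_dur, double stim_amp,
                  double record_every, bool rush_larsen) {
  double s[NSTATE];
  for (int k = 0; k < NSTATE; ++k) s[k] = state0[k];
  const double *p = REAL(params);
  long nstep = (long)std::ceil(t_end / dt - 1e-9);

  int nrec = 0;
  if (record_every > 0) nrec = (int)std::floor(t_end / record_every) + 1;
  NumericVector tr_t(nrec), tr_V(nrec), tr_cs(nrec), tr_cc(nrec);
  long rec_stride = record_every > 0 ? (long)std::llround(record_every / dt) : 0;
  int irec = 0;

  Currents cur; Rates rt; double d[NSTATE];
  double max_dvdt = -1e300;
  int nstim = stim_times.size(), next_stim = 0;

  for (long step = 0; step <= nstep; ++step) {
    double t = step * dt;
    if (record_every > 0 && rec_stride > 0 && step % rec_stride == 0 && irec < nrec) {
      tr_t[irec] = t; tr_V[irec] = s[iV];
      tr_cs[irec] = s[iCasub]; tr_cc[irec] = s[iCacen];
      ++irec;
    }
    if (step == nstep) break;
    double ist = 0.0;
    while (next_stim < nstim && t >= stim_times[next_stim] + stim_dur) ++next_stim;
    if (next_stim < nstim && t >= stim_times[next_stim] && t < stim_times[next_stim] + stim_dur)
      ist = stim_amp;
    advance(s, p, dt, ist, rush_larsen, cur, rt, d);
    if (d[iV] > max_dvdt) max_dvdt = d[iV];
    if (!R_finite(s[iV])) {
      int bad = iV;
      for (int k = 0; k < NSTATE; ++k) if (!R_finite(s[k])) { bad = k; break; }
      stop("integration failure (non-finite %s) at t = %.3f ms",
           state_names_c[bad], t);
    }
  }

  NumericVector fin(NSTATE);
  for (int k = 0; k < NSTATE; ++k) fin[k] = s[k];
  fin.attr("names") = state_names_cpp();
  List out = List::create(_["final_state"] = fin, _["max_dvdt"] = max_dvdt);
  if (record_every > 0) {
    out["t"] = tr_t; out["V"] = tr_V;
    out["Ca_sub"] = tr_cs; out["Ca_cen"] = tr_cc;
  }
  return out;
}

// One forward-Euler step applied to each row of a state matrix (property tests).
// [[Rcpp::export(name = ".batch_step_cpp")]]
NumericMatrix batch_step_cpp(NumericMatrix states, NumericVector params, double dt) {
  int n = states.nrow();
  NumericMatrix out(n, NSTATE);
  Currents cur; Rates rt; double d[NSTATE], s[NSTATE];
  const double *p = REAL(params);
  for (int r = 0; r < n; ++r) {
    for (int k = 0; k < NSTATE; ++k) s[k] = states(r, k);
    advance(s, p, dt, 0.0, false, cur, rt, d);
    for (int k = 0; k < NSTATE; ++k) out(r, k) = s[k];
  }
  return out;
}

// Monodomain tissue run.
//   states:      n_nodes x NSTATE matrix (modified copy returned)
//   params_mat:  n_sets x NPAR matrix, node_param: 1-based set index per node
//   Laplacian in CSC (dgCMatrix slots): Lp (col ptr), Li (row idx), Lx,
//     giving dV_diff = L %*% V in mV/ms
//   stimuli: list of list(nodes = 1-based idx, times, dur, amp_pApF)
//   clamp: optional list(nodes, t_on, t_off, value)
//   record_nodes: 1-based node indices whose V is recorded every record_every ms
//   act_threshold: upstroke crossing level for activation-time logging
// [[Rcpp::export(name = ".run_tissue_cpp")]]
List run_tissue_cpp(NumericMatrix states, NumericMatrix params_mat,
                    IntegerVector node_param,
                    IntegerVector Lp, IntegerVector Li, NumericVector Lx,
                    double dt, double t_end,
                    List stimuli, Nullable<List> clamp_,
                    IntegerVector record_nodes, double record_every,
                    double act_threshold, int max_act, bool rush_larsen) {
  const int n = states.nrow();
  if (params_mat.ncol() != NPAR) stop("bad parameter matrix width");
  long nstep = (long)std::ceil(t_end / dt - 1e-9);

  // node-major state storage (cache-friendly inner loop)
  // row-major copy of the parameter sets (params_mat is column-major)
  int nsets = params_mat.nrow();
  std::vector<double> P((size_t)nsets * NPAR);
  for (int r = 0; r < nsets; ++r)
    for (int c = 0; c < NPAR; ++c)
      P[(size_t)r * NPAR + c] = params_mat(r, c);

  std::vector<double> S((size_t)n * NSTATE);
  for (int nd = 0; nd < n; ++nd)
    for (int k = 0; k < NSTATE; ++k)
      S[(size_t)nd * NSTATE + k] = states(nd, k);
  std::vector<double> dV(n);

  // unpack stimuli
  int nstim = stimuli.size();
  std::vector<std::vector<int> > st_nodes(nstim);
  std::vector<std::vector<double> > st_times(nstim);
  std::vector<double> st_dur(nstim), st_amp(nstim);
  for (int q = 0; q < nstim; ++q) {
    List st = stimuli[q];
    IntegerVector nd = st["nodes"];
    NumericVector tm = st["times"];
    st_nodes[q].assign(nd.begin(), nd.end());
    st_times[q].assign(tm.begin(), tm.end());
    st_dur[q] = as<double>(st["dur"]);
    st_amp[q] = as<double>(st["amp"]);
  }
  bool has_clamp = clamp_.isNotNull();
  std::vector<int> cl_nodes; double cl_on = 0, cl_off = 0, cl_val = 0;
  if (has_clamp) {
    List cl(clamp_);
    IntegerVector nd = cl["nodes"];
    cl_nodes.assign(nd.begin(), nd.end());
    cl_on = as<double>(cl["t_on"]); cl_off = as<double>(cl["t_off"]);
    cl_val = as<double>(cl["value"]);
  }

  // recording
  int nrn = record_nodes.size();
  long rec_stride = (record_every > 0 && nrn > 0) ?
      (long)std::llround(record_every / dt) : 0;
  int nframe = rec_stride > 0 ? (int)(nstep / rec_stride) + 1 : 0;
  NumericMatrix Vhist(nrn > 0 ? nrn : 1, nframe > 0 ? nframe : 1);
  NumericVector frame_t(nframe > 0 ? nframe : 1);
  int iframe = 0;

  // activation logging
  NumericMatrix act(n, max_act);
  std::fill(act.begin(), act.end(), NA_REAL);
  IntegerVector nact(n);

  std::vector<double> ist(n, 0.0);
  Currents cur; Rates rt; double d[NSTATE];

  // voltage lookup tables, one per parameter set
  std::vector<VTab> tabs(nsets);
  for (int r = 0; r < nsets; ++r) tabs[r].build(&P[(size_t)r * NPAR]);

  for (long step = 0; step <= nstep; ++step) {
    double t = step * dt;
    if (rec_stride > 0 && step % rec_stride == 0 && iframe < nframe) {
      for (int r = 0; r < nrn; ++r)
        Vhist(r, iframe) = S[(size_t)(record_nodes[r] - 1) * NSTATE + iV];
      frame_t[iframe] = t;
      ++iframe;
    }
    if (step == nstep) break;

    // stimulus currents for this step
    std::fill(ist.begin(), ist.end(), 0.0);
    for (int q = 0; q < nstim; ++q) {
      for (size_t k = 0; k < st_times[q].size(); ++k) {
        double on = st_times[q][k];
        if (t >= on && t < on + st_dur[q]) {
          for (size_t m2 = 0; m2 < st_nodes[q].size(); ++m2)
            ist[(size_t)(st_nodes[q][m2] - 1)] += st_amp[q];
          break;
        }
      }
    }

    // diffusion: dV = L %*% V  (CSC: iterate columns)
    std::fill(dV.begin(), dV.end(), 0.0);
    for (int col = 0; col < n; ++col) {
      double vcol = S[(size_t)col * NSTATE + iV];
      for (int idx = Lp[col]; idx < Lp[col + 1]; ++idx)
        dV[(size_t)Li[idx]] += Lx[idx] * vcol;
    }

    // reaction per node
    for (int nd = 0; nd < n; ++nd) {
      const double *p = &P[(size_t)(node_param[nd] - 1) * NPAR];
      double *sc2 = &S[(size_t)nd * NSTATE];
      double vold = sc2[iV];
      advance(sc2, p, dt, ist[(size_t)nd], rush_larsen, cur, rt, d,
              &tabs[node_param[nd] - 1]);
      sc2[iV] += dt * dV[(size_t)nd];
      if (vold < act_threshold && sc2[iV] >= act_threshold && nact[nd] < max_act) {
        double frac = (act_threshold - vold) / (sc2[iV] - vold);
        act(nd, nact[nd]) = t + frac * dt;
        ++nact[nd];
      }
    }

    if (has_clamp && t >= cl_on && t < cl_off) {
      for (size_t m2 = 0; m2 < cl_nodes.size(); ++m2)
        S[(size_t)(cl_nodes[m2] - 1) * NSTATE + iV] = cl_val;
    }

    if (step % 2000 == 0) {
      for (int nd = 0; nd < n; ++nd)
        if (!R_finite(S[(size_t)nd * NSTATE + iV]))
          stop("tissue integration failure (non-finite V at node %d, t = %.2f ms)",
               nd + 1, t);
      Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix fin(n, NSTATE);
  for (int nd = 0; nd < n; ++nd)
    for (int k = 0; k < NSTATE; ++k)
      fin(nd, k) = S[(size_t)nd * NSTATE + k];
  List out = List::create(_["final_states"] = fin,
                          _["activation_times"] = act,
                          _["n_activations"] = nact);
  if (nframe > 0) {
    out["V_hist"] = Vhist;
    out["frame_t"] = frame_t;
  }
  return out;
}
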