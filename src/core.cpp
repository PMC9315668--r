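// Hybrid stochastic-deterministic core of the bouton model.
//
// Deterministic subsystem (four Ca2+ compartments, IP3/PLC/G, membrane
// voltage) advances by classic RK4 with a fixed step; the discrete
// subsystems (IP3R cluster, VGCC cluster, per-vesicle release machinery)
// advance by a fixed-step Markov-chain update equivalent to the Gillespie
// algorithm in the small-step limit.  Exit probabilities use
// 1 - exp(-k_tot * dt) with the destination drawn proportionally to the
// individual rates, and any block whose total propensity exceeds
// 0.05/step is sub-stepped so the single-transition approximation holds
// even during sharp microdomain transients.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded via splitmix64; (seed, stream) pairs give
// independent substreams so trial k is unchanged when more trials are added.
// ---------------------------------------------------------------------------
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  Xoshiro(uint64_t seed, uint64_t stream) {
    uint64_t x = seed * 0x2545F4914F6CDD1DULL + stream * 0x9E3779B97F4A7C15ULL + 1ULL;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// ---------------------------------------------------------------------------
// Parameter bundles parsed once from the R-side bouton_params list.
// ---------------------------------------------------------------------------
struct IP3RGate {
  double a1, nO, KOd, a2, nA, KAd, a3, nI, KId;
  double j01, j12, j22, j23, j45, jt01, jt45;
  void parse(const List &ip3r) {
    a1 = ip3r["a1"]; nO = ip3r["nO"]; KOd = ip3r["KOd"];
    a2 = ip3r["a2"]; nA = ip3r["nA"]; KAd = ip3r["KAd"];
    a3 = ip3r["a3"]; nI = ip3r["nI"]; KId = ip3r["KId"];
    j01 = ip3r["j01"]; j12 = ip3r["j12"]; j22 = ip3r["j22"];
    j23 = ip3r["j23"]; j45 = ip3r["j45"];
    jt01 = ip3r["jt01"]; jt45 = ip3r["jt45"];
  }
  void occupancy(double ip3, double &KO, double &KA, double &KI) const {
    if (ip3 <= 0) { KO = KA = KI = 0; return; }
    double xo = std::pow(ip3, nO), xa = std::pow(ip3, nA), xi = std::pow(ip3, nI);
    KO = a1 * xo / (xo + std::pow(KOd, nO));
    KA = a2 * xa / (xa + std::pow(KAd, nA));
    KI = a3 * xi / (xi + std::pow(KId, nI));
  }
  // k: kRA kAR kAO kOA kOI kIO kRI kIR
  void rates(double ca, double ip3, double *k) const {
    if (ca <= 1e-12 || ip3 <= 0) { for (int i = 0; i < 8; ++i) k[i] = 0; return; }
    double KO, KA, KI;
    occupancy(ip3, KO, KA, KI);
    double c2 = ca * ca, c3 = c2 * ca, c5 = c2 * c3;
    double s_ra = 1.0 / (j01 * ca) + 1.0 / (j12 * c2);
    double s_oi = 1.0 / (j23 * c3) + 1.0 / (j45 * c5);
    double s_ri = 1.0 / (jt01 * ca) + 1.0 / (jt45 * c5);
    k[0] = 1.0 / s_ra;
    k[1] = (KA > 0) ? 1.0 / (KA * c2 * s_ra) : 0.0;
    k[2] = (KA > 0) ? j22 / KA : 0.0;
    k[3] = (KO > 0) ? j22 / KO : 0.0;
    k[4] = (KO > 0) ? 1.0 / (KO * c2 * s_oi) : 0.0;
    k[5] = (KI > 0) ? 1.0 / (KI * c5 * s_oi) : 0.0;
    k[6] = 1.0 / s_ri;
    k[7] = (KI > 0) ? 1.0 / (KI * c5 * s_ri) : 0.0;
  }
};

struct VGCCPar {
  double alpha0[4], beta0[4], kslope[4];
  double g, ECa, cluster_area, AZ_area, N_AZ, V_eff, z, F;
  int N;
  void parse(const List &v) {
    NumericVector a0 = v["alpha0"], b0 = v["beta0"], kk = v["k"];
    for (int i = 0; i < 4; ++i) { alpha0[i] = a0[i]; beta0[i] = b0[i]; kslope[i] = kk[i]; }
    g = v["g"]; ECa = v["E_Ca"]; cluster_area = v["cluster_area"];
    AZ_area = v["AZ_area"]; N_AZ = v["N_AZ"]; V_eff = v["V_eff"];
    z = v["z"]; F = v["Faraday"]; N = as<int>(v["N_VGCC"]);
  }
  void rates(double V, double *al, double *be) const {
    for (int i = 0; i < 4; ++i) {
      al[i] = alpha0[i] * std::exp(V / kslope[i]);
      be[i] = beta0[i] * std::exp(-V / kslope[i]);
    }
  }
  // bouton-referenced flux (uM/ms) and cluster current (fA) for n open channels
  double cluster_current(double V, int n_open) const {
    double density = (double)N / (AZ_area * N_AZ);
    double frac = density * cluster_area / (double)N; // per open channel
    return n_open * frac * g * (V - ECa);
  }
  double flux_from_current(double ica_fa) const {
    return -ica_fa * 1e-15 / (z * F * V_eff) * 1e3;
  }
};

struct CaPar {
  double Jleak_in, Vleak_in, k_IPR_diff, k_VGCC_diff, k_ER_leak, k_IPR;
  double V_PMCA, K_PMCA, n_P, V_SERCA, K_SERCA, n_S;
  double d1, d2, d3;
  double ca_cyt0, ca_iprn0, ca_az0, ca_total0, ip3_0;
  int N_IPR;
  void parse(const List &c) {
    Jleak_in = c["Jleak_in"]; Vleak_in = c["Vleak_in"];
    k_IPR_diff = c["k_IPR_diff"]; k_VGCC_diff = c["k_VGCC_diff"];
    k_ER_leak = c["k_ER_leak"]; k_IPR = c["k_IPR"];
    V_PMCA = c["V_PMCA"]; K_PMCA = c["K_PMCA"]; n_P = c["n_P"];
    V_SERCA = c["V_SERCA"]; K_SERCA = c["K_SERCA"]; n_S = c["n_S"];
    d1 = c["delta1"]; d2 = c["delta2"]; d3 = c["delta3"];
    ca_cyt0 = c["ca_cyt0"]; ca_iprn0 = c["ca_iprn0"]; ca_az0 = c["ca_az0"];
    ca_total0 = c["ca_total0"]; ip3_0 = c["ip3_0"];
    N_IPR = as<int>(c["N_IPR"]);
  }
};

struct CouplPar {
  double Vc, kbar, Kc, guard;
  bool printed_den;
  void parse(const List &c) {
    Vc = c["Vc"]; kbar = c["kbar"]; Kc = c["Kc"];
    guard = c["guard_band"]; printed_den = as<bool>(c["printed_denominator"]);
  }
  double flux(double ca_az, double ca_iprn) const {
    double num = Vc * (ca_az * ca_az - kbar * ca_iprn * ca_iprn);
    double den;
    if (printed_den) {
      den = ca_az * ca_az - Kc * Kc;
      double a = std::fabs(den);
      if (a < guard) den = (den < 0 ? -guard : guard);
    } else {
      den = ca_az * ca_az + Kc * Kc;
    }
    return num / den;
  }
};

struct IP3Par {
  double V0, VQ, KQ, K_IP3k, K_PLC, k3k, k5p, kf_PLC, kb_PLC, PLC_tot;
  double kf_G, kb_G, delta_G, VR, KR, G_tot, abeta, abeta_r, abeta_t1;
  double abeta_tonic;
  void parse(const List &m) {
    V0 = m["V0"]; VQ = m["VQ"]; KQ = m["KQ"]; K_IP3k = m["K_IP3k"];
    K_PLC = m["K_PLC"]; k3k = m["k3k"]; k5p = m["k5p"];
    kf_PLC = m["kf_PLC"]; kb_PLC = m["kb_PLC"]; PLC_tot = m["PLC_tot"];
    kf_G = m["kf_G"]; kb_G = m["kb_G"]; delta_G = m["delta_G"];
    VR = m["VR"]; KR = m["KR"]; G_tot = m["G_tot"];
    abeta = m["abeta"]; abeta_r = m["abeta_r"]; abeta_t1 = m["abeta_t1"];
    abeta_tonic = m["abeta_tonic"];
  }
};

struct MembPar {
  double Cm, gNa, gK, gNaleak, gKleak, gClleak, phi, gAHP;
  double ENa, EK, ECl, area_cm2, V0;
  void parse(const List &m) {
    Cm = m["Cm"]; gNa = m["gNa"]; gK = m["gK"]; gNaleak = m["gNaleak"];
    gKleak = m["gKleak"]; gClleak = m["gClleak"]; phi = m["phi"];
    gAHP = m["gAHP"]; ENa = m["E_Na"]; EK = m["E_K"]; ECl = m["E_Cl"];
    area_cm2 = m["area_cm2"]; V0 = m["V0"];
  }
};

struct RelPar {
  double kmob, kdemob, kpriming, kunpr, kattach, kdetach, kRF;
  double alpha, beta, lambda, delta, gamma1, gamma2, gamma3, a, b;
  double bpow[5]; // b^(m-1) for m = 1..5
  int N_sites, N_reserve;
  void parse(const List &r, const List &pools) {
    kmob = r["kmob"]; kdemob = r["kdemob"]; kpriming = r["kpriming"];
    kunpr = r["kunpr"]; kattach = r["kattach"]; kdetach = r["kdetach"];
    kRF = r["kRF"]; alpha = r["alpha"]; beta = r["beta"];
    lambda = r["lambda"]; delta = r["delta"];
    gamma1 = r["gamma1"]; gamma2 = r["gamma2"]; a = r["a"]; b = r["b"];
    gamma3 = a * gamma2;
    for (int m = 1; m <= 5; ++m) bpow[m - 1] = std::pow(b, m - 1);
    N_sites = as<int>(pools["N_sites"]);
    N_reserve = as<int>(pools["N_reserve"]);
  }
};

struct AllPar {
  CaPar ca; CouplPar cp; IP3Par ip; IP3RGate gate; VGCCPar vg;
  MembPar mb; RelPar rel;
  void parse(const List &p) {
    ca.parse(p["calcium"]); cp.parse(p["coupling"]); ip.parse(p["ip3"]);
    gate.parse(p["ip3r"]); vg.parse(p["vgcc"]); mb.parse(p["membrane"]);
    rel.parse(p["release"], p["pools"]);
  }
};

// ---------------------------------------------------------------------------
// Hodgkin-Huxley helpers
// ---------------------------------------------------------------------------
static inline double lin_exp(double a, double x, double s) {
  if (std::fabs(x) < 1e-9) return a * s;
  return a * x / (1.0 - std::exp(-x / s));
}
static inline void hh6(double V, double *r) {
  r[0] = lin_exp(0.01, V + 34.0, 10.0);            // alpha_n
  r[1] = 0.125 * std::exp(-(V + 44.0) / 80.0);     // beta_n
  r[2] = 0.07 * std::exp(-(V + 44.0) / 20.0);      // alpha_h
  r[3] = 1.0 / (1.0 + std::exp(-(V + 14.0) / 10.0)); // beta_h
  r[4] = lin_exp(0.1, V + 30.0, 10.0);             // alpha_m
  r[5] = 4.0 * std::exp(-(V + 55.0) / 18.0);       // beta_m
}

// ---------------------------------------------------------------------------
// Deterministic right-hand side.  y = (ca_cyt, ca_iprn, ca_az, ca_total,
// ip3, plc, g, V, n, h).  Channel open counts are frozen during the step.
// ---------------------------------------------------------------------------
static void deriv(double t, const double *y, const AllPar &P,
                  double po_ipr, int n_open_vgcc, double Iapp,
                  bool closed, double *dy) {
  const CaPar &c = P.ca;
  double ca_cyt = y[0], ca_iprn = y[1], ca_az = y[2], ca_tot = y[3];
  double ip3 = y[4], plc = y[5], g = y[6], V = y[7], n = y[8], h = y[9];
  if (ca_cyt < 0) ca_cyt = 0;
  if (ca_iprn < 0) ca_iprn = 0;
  if (ca_az < 0) ca_az = 0;

  double caer = c.d2 * (ca_tot - ca_cyt + ca_iprn / c.d1 - ca_az);
  double c2 = ca_cyt * ca_cyt;

  double Jin = closed ? 0.0 : (c.Jleak_in + c.Vleak_in * ip3);
  double JPMCA = closed ? 0.0
    : c.V_PMCA * c2 / (c2 + c.K_PMCA * c.K_PMCA);
  double csn = std::pow(ca_cyt, c.n_S);
  double JSERCA = c.V_SERCA * csn / (csn + std::pow(c.K_SERCA, c.n_S));
  double JIPR = c.k_IPR * po_ipr * (caer - ca_iprn);
  double JIPR_diff = c.k_IPR_diff * (ca_iprn - ca_cyt);
  double JER_leak = c.k_ER_leak * (caer - ca_cyt);
  double JVGCC_diff = c.k_VGCC_diff * (ca_az - ca_cyt);
  double ica_fa = closed ? 0.0 : P.vg.cluster_current(V, n_open_vgcc);
  double JVGCC = closed ? 0.0 : P.vg.flux_from_current(ica_fa);
  double Jcoup = P.cp.flux(ca_az, ca_iprn);

  dy[0] = Jin + JIPR_diff - JPMCA + JER_leak + JVGCC_diff - JSERCA;
  dy[1] = c.d1 * (JIPR - JIPR_diff) + Jcoup;
  dy[2] = c.d3 * (JVGCC - JVGCC_diff) - Jcoup / c.d1;
  dy[3] = Jin - JPMCA + JVGCC;

  // IP3 metabolism
  const IP3Par &m = P.ip;
  double q = m.abeta_tonic + ((t >= m.abeta_t1 && m.abeta > 0)
    ? m.abeta * std::exp(-m.abeta_r * (t - m.abeta_t1)) : 0.0);
  double VPLC = m.V0 + m.VQ * q * q / (q * q + m.KQ * m.KQ);
  double rho = m.VR * q / (q + m.KR);
  double JPLC = VPLC * plc * c2 / (c2 + m.K_PLC * m.K_PLC);
  double eta = m.k3k / (m.k3k + m.k5p);
  double Jdeg = (eta * c2 / (c2 + m.K_IP3k * m.K_IP3k) + (1.0 - eta)) * ip3;
  double tau = 1.0 / (m.k3k + m.k5p);
  dy[4] = (JPLC - Jdeg) / tau;
  dy[5] = m.kf_PLC * g * (m.PLC_tot - plc) - m.kb_PLC * plc;
  dy[6] = m.kf_G * (rho + m.delta_G) * (m.G_tot - g) - m.kb_G * g;

  // membrane
  const MembPar &mb = P.mb;
  double r[6];
  hh6(V, r);
  double m_inf = r[4] / (r[4] + r[5]);
  double INa = -(mb.gNa * m_inf * m_inf * m_inf * h) * (V - mb.ENa)
    - mb.gNaleak * (V - mb.ENa);
  double IK = -(mb.gK * n * n * n * n + mb.gAHP * ca_cyt / (1.0 + ca_cyt)) *
    (V - mb.EK) - mb.gKleak * (V - mb.EK);
  double ICl = -mb.gClleak * (V - mb.ECl);
  double ica_density = ica_fa * 1e-9 / mb.area_cm2; // fA -> uA/cm^2
  dy[7] = (Iapp + INa + IK + ICl - ica_density) / mb.Cm;
  dy[8] = mb.phi * (r[0] * (1.0 - n) - r[1] * n);
  dy[9] = mb.phi * (r[2] * (1.0 - h) - r[3] * h);
}

static void rk4_step(double t, double *y, double dt, const AllPar &P,
                     double po_ipr, int n_open_vgcc,
                     double Iapp1, double Iapp2, double Iapp3,
                     bool closed) {
  double k1[10], k2[10], k3[10], k4[10], tmp[10];
  deriv(t, y, P, po_ipr, n_open_vgcc, Iapp1, closed, k1);
  for (int i = 0; i < 10; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
  deriv(t + 0.5 * dt, tmp, P, po_ipr, n_open_vgcc, Iapp2, closed, k2);
  for (int i = 0; i < 10; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
  deriv(t + 0.5 * dt, tmp, P, po_ipr, n_open_vgcc, Iapp2, closed, k3);
  for (int i = 0; i < 10; ++i) tmp[i] = y[i] + dt * k3[i];
  deriv(t + dt, tmp, P, po_ipr, n_open_vgcc, Iapp3, closed, k4);
  for (int i = 0; i < 10; ++i)
    y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  // integration guards: concentrations non-negative, gates and scaled
  // activities in [0, 1]
  for (int i = 0; i < 5; ++i) if (y[i] < 0) y[i] = 0;
  for (int i : {5, 6, 8, 9}) { if (y[i] < 0) y[i] = 0; if (y[i] > 1) y[i] = 1; }
}

// ---------------------------------------------------------------------------
// Exchangeable-cluster DTMC: state counts advance one transition per
// (sub)step with p = 1 - exp(-k_tot dt).
// ---------------------------------------------------------------------------
static void cluster_step(int *cnt, int n_states, const double *edge_rate,
                         const int *edge_from, const int *edge_to,
                         int n_edges, double dt, Xoshiro &rng) {
  double tot = 0.0;
  for (int e = 0; e < n_edges; ++e) tot += cnt[edge_from[e]] * edge_rate[e];
  if (tot <= 0) return;
  int nsub = (int)std::ceil(tot * dt / 0.05);
  if (nsub < 1) nsub = 1;
  double dts = dt / nsub;
  for (int s = 0; s < nsub; ++s) {
    tot = 0.0;
    for (int e = 0; e < n_edges; ++e) tot += cnt[edge_from[e]] * edge_rate[e];
    if (tot <= 0) return;
    double p = 1.0 - std::exp(-tot * dts);
    if (rng.unif() < p) {
      double u = rng.unif() * tot, acc = 0.0;
      for (int e = 0; e < n_edges; ++e) {
        acc += cnt[edge_from[e]] * edge_rate[e];
        if (u <= acc) { --cnt[edge_from[e]]; ++cnt[edge_to[e]]; break; }
      }
    }
  }
}

static const int IPR_FROM[8] = {0, 1, 1, 2, 2, 3, 0, 3};
static const int IPR_TO[8]   = {1, 0, 2, 1, 3, 2, 3, 0};

// ---------------------------------------------------------------------------
// Per-vesicle release machinery (stochastic mode)
// ---------------------------------------------------------------------------
struct Release {
  const RelPar *p = nullptr;
  int R_pool = 0, U_pool = 0;
  std::vector<int> status; // 0 free, 1 refractory, 2 occupied
  std::vector<int> pool;   // 0 = V (detached), 1 = W (channel-attached)
  std::vector<int> sm, sn; // sensor occupancies
  double cum_spont = 0, cum_sync = 0, cum_async = 0;
  std::vector<double> ev_time; std::vector<int> ev_mode, ev_pool;

  void init(const RelPar &par, double ca_az0, Xoshiro &rng) {
    p = &par;
    R_pool = par.N_reserve; U_pool = 0;
    status.assign(par.N_sites, 2);
    pool.assign(par.N_sites, 0);
    sm.assign(par.N_sites, 0);
    sn.assign(par.N_sites, 0);
    // resting attach/detach equilibrium sets the initial V/W split
    double wfrac = par.kattach * ca_az0 / (par.kattach * ca_az0 + par.kdetach);
    for (int i = 0; i < par.N_sites; ++i)
      pool[i] = (rng.unif() < wfrac) ? 1 : 0;
    cum_spont = cum_sync = cum_async = 0;
  }

  int n_free() const {
    int f = 0;
    for (size_t i = 0; i < status.size(); ++i) if (status[i] == 0) ++f;
    return f;
  }
  int n_refr() const {
    int f = 0;
    for (size_t i = 0; i < status.size(); ++i) if (status[i] == 1) ++f;
    return f;
  }
  int n_pool(int which) const {
    int f = 0;
    for (size_t i = 0; i < status.size(); ++i)
      if (status[i] == 2 && pool[i] == which) ++f;
    return f;
  }

  double hazard_total() const {
    double hz = 0;
    for (size_t i = 0; i < status.size(); ++i) {
      if (status[i] != 2) continue;
      if (sm[i] == 5) hz += p->gamma2;
      if (sn[i] == 2) hz += p->gamma3;
      if (sm[i] == 0 && sn[i] == 0) hz += p->gamma1;
    }
    return hz;
  }

  // Build the event table; returns total propensity.
  double build(double ca_cyt, double ca_az, double *rates, int *kind,
               int *site, int &n_ev) const {
    n_ev = 0;
    double tot = 0;
    int N = (int)status.size();
    int freeN = n_free();

    if (R_pool > 0 && ca_cyt > 0) {
      rates[n_ev] = p->kmob * ca_cyt * R_pool; kind[n_ev] = 0; site[n_ev] = -1;
      tot += rates[n_ev++];
    }
    if (U_pool > 0) {
      rates[n_ev] = p->kdemob * U_pool; kind[n_ev] = 1; site[n_ev] = -1;
      tot += rates[n_ev++];
    }
    // priming is gated by site availability (any free, non-refractory site)
    if (U_pool > 0 && freeN > 0 && ca_cyt > 0) {
      rates[n_ev] = p->kpriming * ca_cyt * U_pool;
      kind[n_ev] = 2; site[n_ev] = -1;
      tot += rates[n_ev++];
    }
    for (int i = 0; i < N; ++i) {
      if (status[i] == 1) {
        rates[n_ev] = p->kRF; kind[n_ev] = 3; site[n_ev] = i;
        tot += rates[n_ev++];
      } else if (status[i] == 2) {
        double cax = pool[i] == 1 ? ca_az : ca_cyt;
        int m = sm[i], n = sn[i];
        if (m < 5 && cax > 0) { rates[n_ev] = (5 - m) * p->alpha * cax; kind[n_ev] = 4; site[n_ev] = i; tot += rates[n_ev++]; }
        if (m > 0) { rates[n_ev] = m * p->beta * p->bpow[m - 1]; kind[n_ev] = 5; site[n_ev] = i; tot += rates[n_ev++]; }
        if (n < 2 && cax > 0) { rates[n_ev] = (2 - n) * p->lambda * cax; kind[n_ev] = 6; site[n_ev] = i; tot += rates[n_ev++]; }
        if (n > 0) { rates[n_ev] = n * p->delta * p->bpow[n - 1]; kind[n_ev] = 7; site[n_ev] = i; tot += rates[n_ev++]; }
        if (pool[i] == 0) {
          if (ca_az > 0) { rates[n_ev] = p->kattach * ca_az; kind[n_ev] = 8; site[n_ev] = i; tot += rates[n_ev++]; }
          rates[n_ev] = p->kunpr; kind[n_ev] = 10; site[n_ev] = i; tot += rates[n_ev++];
        } else {
          rates[n_ev] = p->kdetach; kind[n_ev] = 9; site[n_ev] = i; tot += rates[n_ev++];
        }
        if (m == 5) { rates[n_ev] = p->gamma2; kind[n_ev] = 11; site[n_ev] = i; tot += rates[n_ev++]; }
        if (n == 2) { rates[n_ev] = p->gamma3; kind[n_ev] = 12; site[n_ev] = i; tot += rates[n_ev++]; }
        if (m == 0 && n == 0) { rates[n_ev] = p->gamma1; kind[n_ev] = 13; site[n_ev] = i; tot += rates[n_ev++]; }
      }
    }
    return tot;
  }

  // Single DTMC update over dts (at most one event).
  void update_once(double t, double ca_cyt, double ca_az, double dts,
                   Xoshiro &rng) {
    double rates[160];
    int kind[160], site[160], n_ev;
    double tot = build(ca_cyt, ca_az, rates, kind, site, n_ev);
    if (tot <= 0) return;
    double pmove = 1.0 - std::exp(-tot * dts);
    if (rng.unif() >= pmove) return;
    double u = rng.unif() * tot, acc = 0;
    int e = 0;
    for (; e < n_ev; ++e) { acc += rates[e]; if (u <= acc) break; }
    if (e >= n_ev) e = n_ev - 1;
    int i = site[e];
    switch (kind[e]) {
      case 0: --R_pool; ++U_pool; break;
      case 1: --U_pool; ++R_pool; break;
      case 2: { // prime onto a uniformly chosen free site
        int freeN = n_free();
        int pick = (int)(rng.unif() * freeN);
        if (pick >= freeN) pick = freeN - 1;
        for (int s2 = 0, c = 0; s2 < (int)status.size(); ++s2) {
          if (status[s2] == 0 && c++ == pick) {
            status[s2] = 2; pool[s2] = 0; sm[s2] = 0; sn[s2] = 0; break;
          }
        }
        --U_pool;
        break;
      }
      case 3: status[i] = 0; break;            // refractory recovers
      case 4: ++sm[i]; break;
      case 5: --sm[i]; break;
      case 6: ++sn[i]; break;
      case 7: --sn[i]; break;
      case 8: pool[i] = 1; break;              // V -> W (sensors kept)
      case 9: pool[i] = 0; break;              // W -> V
      case 10: status[i] = 0; ++U_pool; break; // unprime, site freed
      case 11: case 12: case 13: {             // fusion: sync / async / spont
        int m_out = (kind[e] == 11) ? 2 : (kind[e] == 12 ? 3 : 1);
        if (m_out == 1) cum_spont += 1;
        else if (m_out == 2) cum_sync += 1;
        else cum_async += 1;
        ev_time.push_back(t); ev_mode.push_back(m_out);
        ev_pool.push_back(pool[i]);
        status[i] = 1; // site refractory
        break;
      }
    }
  }

  // DTMC update over dt, sub-stepped so the per-update propensity stays
  // below 0.05.
  void step(double t, double ca_cyt, double ca_az, double dt, Xoshiro &rng) {
    double rates[160];
    int kind[160], site[160], n_ev;
    double tot = build(ca_cyt, ca_az, rates, kind, site, n_ev);
    if (tot <= 0) return;
    int nsub = std::max(1, (int)std::ceil(tot * dt / 0.05));
    double dts = dt / nsub;
    for (int s = 0; s < nsub; ++s)
      update_once(t + (s + 1) * dts, ca_cyt, ca_az, dts, rng);
  }
};

// ---------------------------------------------------------------------------
// Full hybrid simulation of the bouton
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List simulate_bouton_cpp(List params, NumericVector onsets, double amplitude,
                         double width, double t_end, double dt,
                         int record_every, int seed, int trial,
                         bool stochastic_release, bool freeze_channels,
                         bool closed_system) {
  AllPar P;
  P.parse(params);
  Xoshiro rng((uint64_t)seed, (uint64_t)(10000 + trial));

  long n_steps = (long)std::llround(t_end / dt);
  bool record = record_every > 0;
  long n_rec = record ? n_steps / record_every + 2 : 0;

  // deterministic state
  double y[10];
  y[0] = P.ca.ca_cyt0; y[1] = P.ca.ca_iprn0; y[2] = P.ca.ca_az0;
  y[3] = P.ca.ca_total0; y[4] = P.ca.ip3_0;
  { // PLC/G fixed points at the tonic background input
    double rho0 = P.ip.VR * P.ip.abeta_tonic / (P.ip.abeta_tonic + P.ip.KR);
    double g0 = P.ip.kf_G * (rho0 + P.ip.delta_G) * P.ip.G_tot /
      (P.ip.kf_G * (rho0 + P.ip.delta_G) + P.ip.kb_G);
    double plc0 = P.ip.kf_PLC * g0 * P.ip.PLC_tot /
      (P.ip.kf_PLC * g0 + P.ip.kb_PLC);
    y[5] = plc0; y[6] = g0;
  }
  y[7] = P.mb.V0;
  {
    double r[6]; hh6(y[7], r);
    y[8] = r[0] / (r[0] + r[1]);
    y[9] = r[2] / (r[2] + r[3]);
  }

  // channel clusters (exchangeable state counts)
  int ipr_cnt[4] = {P.ca.N_IPR, 0, 0, 0};
  int vg_cnt[5] = {P.vg.N, 0, 0, 0, 0};
  static const int VG_FROM[8] = {0, 1, 2, 3, 1, 2, 3, 4};
  static const int VG_TO[8]   = {1, 2, 3, 4, 0, 1, 2, 3};

  Release rel;
  if (stochastic_release) rel.init(P.rel, y[2], rng);

  int n_cols = 24;
  NumericMatrix trace(record ? n_rec : 0, n_cols);
  std::vector<double> ap;
  double v_prev = y[7];

  // applied-current lookup
  std::vector<double> ons(onsets.begin(), onsets.end());
  std::sort(ons.begin(), ons.end());
  auto iapp_at = [&](double t) -> double {
    for (size_t i = 0; i < ons.size(); ++i) {
      if (t >= ons[i] && t < ons[i] + width) return amplitude;
      if (t < ons[i]) break;
    }
    return 0.0;
  };

  long rec_i = 0;
  auto record_row = [&](long step, double t) {
    if (!record) return;
    if (step % record_every != 0 && step != n_steps) return;
    if (rec_i >= n_rec) return;
    double caer = P.ca.d2 * (y[3] - y[0] + y[1] / P.ca.d1 - y[2]);
    double po_i = (double)ipr_cnt[2] / P.ca.N_IPR;
    double po_v = (double)vg_cnt[4] / std::max(1, P.vg.N);
    double jv = closed_system ? 0.0
      : P.vg.flux_from_current(P.vg.cluster_current(y[7], vg_cnt[4]));
    trace(rec_i, 0) = t;
    trace(rec_i, 1) = y[0];     // ca_cyt
    trace(rec_i, 2) = y[1];     // ca_iprn
    trace(rec_i, 3) = y[2];     // ca_az
    trace(rec_i, 4) = y[3];     // ca_total
    trace(rec_i, 5) = caer;     // ca_er (derived)
    trace(rec_i, 6) = y[4];     // ip3
    trace(rec_i, 7) = y[5];     // plc
    trace(rec_i, 8) = y[6];     // g
    trace(rec_i, 9) = y[7];     // V
    trace(rec_i, 10) = y[8];    // n
    trace(rec_i, 11) = y[9];    // h
    trace(rec_i, 12) = po_i;
    trace(rec_i, 13) = po_v;
    trace(rec_i, 14) = jv;
    if (stochastic_release) {
      trace(rec_i, 15) = rel.hazard_total();
      trace(rec_i, 16) = rel.R_pool;
      trace(rec_i, 17) = rel.U_pool;
      trace(rec_i, 18) = rel.n_pool(0);
      trace(rec_i, 19) = rel.n_pool(1);
      trace(rec_i, 20) = rel.n_refr();
      trace(rec_i, 21) = rel.cum_spont;
      trace(rec_i, 22) = rel.cum_sync;
      trace(rec_i, 23) = rel.cum_async;
    }
    ++rec_i;
  };

  record_row(0, 0.0);

  for (long step = 0; step < n_steps; ++step) {
    double t = step * dt;
    double po_ipr = (double)ipr_cnt[2] / P.ca.N_IPR;
    rk4_step(t, y, dt, P, po_ipr, vg_cnt[4],
             iapp_at(t), iapp_at(t + 0.5 * dt), iapp_at(t + dt),
             closed_system);
    double t1 = t + dt;

    if (!freeze_channels) {
      double kr[8];
      P.gate.rates(y[1], y[4], kr);
      cluster_step(ipr_cnt, 4, kr, IPR_FROM, IPR_TO, 8, dt, rng);
      if (P.vg.N > 0) {
        double al[4], be[4], er[8];
        P.vg.rates(y[7], al, be);
        for (int i = 0; i < 4; ++i) { er[i] = al[i]; er[4 + i] = be[i]; }
        cluster_step(vg_cnt, 5, er, VG_FROM, VG_TO, 8, dt, rng);
      }
    }
    if (stochastic_release) rel.step(t1, y[0], y[2], dt, rng);

    if (y[7] >= 0.0 && v_prev < 0.0) ap.push_back(t1);
    v_prev = y[7];

    if ((step & 0xFFF) == 0) {
      for (int i = 0; i < 10; ++i) {
        if (!std::isfinite(y[i]))
          stop("state became non-finite at t = %f (component %d)", t1, i);
      }
    }
    record_row(step + 1, t1);
  }

  List ev = List::create(
    _["time"] = NumericVector(rel.ev_time.begin(), rel.ev_time.end()),
    _["mode"] = IntegerVector(rel.ev_mode.begin(), rel.ev_mode.end()),
    _["pool"] = IntegerVector(rel.ev_pool.begin(), rel.ev_pool.end()));
  return List::create(
    _["trace"] = trace,
    _["n_rec"] = (double)rec_i,
    _["events"] = ev,
    _["ap_times"] = NumericVector(ap.begin(), ap.end()),
    _["final_state"] = NumericVector(y, y + 10),
    _["cum_release"] = NumericVector::create(
      rel.cum_spont, rel.cum_sync, rel.cum_async),
    _["vesicles_left"] = stochastic_release
      ? (double)(rel.R_pool + rel.U_pool + rel.n_pool(0) + rel.n_pool(1))
      : NA_REAL);
}

// ---------------------------------------------------------------------------
// Single IP3R channel at clamped ligands (sojourn-compressed trajectory)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List ip3r_simulate_cpp(double ca, double ip3, double t_end, double dt,
                       int seed, int state0, List params, int n_batches) {
  IP3RGate g;
  g.parse(params["ip3r"]);
  double k[8];
  g.rates(ca, ip3, k);

  // per-state exit rates and destinations
  double ex[4][2]; int dst[4][2];
  ex[0][0] = k[0]; dst[0][0] = 1; ex[0][1] = k[6]; dst[0][1] = 3; // R->A, R->I
  ex[1][0] = k[1]; dst[1][0] = 0; ex[1][1] = k[2]; dst[1][1] = 2; // A->R, A->O
  ex[2][0] = k[3]; dst[2][0] = 1; ex[2][1] = k[4]; dst[2][1] = 3; // O->A, O->I
  ex[3][0] = k[5]; dst[3][0] = 2; ex[3][1] = k[7]; dst[3][1] = 0; // I->O, I->R

  double ktot_max = 0;
  for (int s = 0; s < 4; ++s) ktot_max = std::max(ktot_max, ex[s][0] + ex[s][1]);
  int nsub = std::max(1, (int)std::ceil(ktot_max * dt / 0.05));
  double dte = dt / nsub;
  long n_steps = (long)std::llround(t_end / dte);

  double pmove[4], split[4];
  for (int s = 0; s < 4; ++s) {
    double tot = ex[s][0] + ex[s][1];
    pmove[s] = tot > 0 ? 1.0 - std::exp(-tot * dte) : 0.0;
    split[s] = tot > 0 ? ex[s][0] / tot : 1.0;
  }

  Xoshiro rng((uint64_t)seed, 1ULL);
  int s = state0;
  std::vector<int> states; std::vector<double> enter, dur;
  states.push_back(s); enter.push_back(0.0);
  long last_change = 0;
  double open_time = 0;
  long batch_len = std::max(1L, n_steps / std::max(1, n_batches));
  NumericVector batch_po(n_batches);
  long bi = 0; double bopen = 0;

  for (long i = 0; i < n_steps; ++i) {
    if (s == 2) { open_time += dte; bopen += dte; }
    if (pmove[s] > 0 && rng.unif() < pmove[s]) {
      int d = (rng.unif() < split[s]) ? dst[s][0] : dst[s][1];
      dur.push_back((i + 1 - last_change) * dte);
      last_change = i + 1;
      s = d;
      states.push_back(s);
      enter.push_back((i + 1) * dte);
    }
    if ((i + 1) % batch_len == 0 && bi < n_batches) {
      batch_po[bi++] = bopen / (batch_len * dte);
      bopen = 0;
    }
  }
  dur.push_back((n_steps - last_change) * dte);

  return List::create(
    _["states"] = IntegerVector(states.begin(), states.end()),
    _["enter"] = NumericVector(enter.begin(), enter.end()),
    _["duration"] = NumericVector(dur.begin(), dur.end()),
    _["po_emp"] = open_time / (n_steps * dte),
    _["batch_po"] = batch_po,
    _["dt_effective"] = dte);
}

// ---------------------------------------------------------------------------
// VGCC cluster driven by a voltage trace
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List vgcc_simulate_cpp(NumericVector V_trace, double dt, int seed,
                       List params) {
  VGCCPar vg;
  vg.parse(params["vgcc"]);
  static const int VG_FROM[8] = {0, 1, 2, 3, 1, 2, 3, 4};
  static const int VG_TO[8]   = {1, 2, 3, 4, 0, 1, 2, 3};
  int cnt[5] = {vg.N, 0, 0, 0, 0};
  Xoshiro rng((uint64_t)seed, 2ULL);
  long n = V_trace.size();
  NumericVector open_frac(n); IntegerVector n_open(n);
  for (long i = 0; i < n; ++i) {
    double al[4], be[4], er[8];
    vg.rates(V_trace[i], al, be);
    for (int j = 0; j < 4; ++j) { er[j] = al[j]; er[4 + j] = be[j]; }
    cluster_step(cnt, 5, er, VG_FROM, VG_TO, 8, dt, rng);
    n_open[i] = cnt[4];
    open_frac[i] = (double)cnt[4] / vg.N;
  }
  return List::create(_["open_fraction"] = open_frac, _["n_open"] = n_open);
}

// ---------------------------------------------------------------------------
// Stochastic release machinery on a prescribed Ca2+ waveform
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List release_simulate_cpp(NumericVector ca_cyt, NumericVector ca_az,
                          double t_end, double dt, List params, int seed,
                          int trial, int record_every) {
  AllPar P;
  P.parse(params);
  Xoshiro rng((uint64_t)seed, (uint64_t)(20000 + trial));
  long n_steps = (long)std::llround(t_end / dt);
  bool var_cyt = ca_cyt.size() > 1, var_az = ca_az.size() > 1;
  if ((var_cyt && ca_cyt.size() < n_steps) || (var_az && ca_az.size() < n_steps))
    stop("Ca waveforms must have length 1 or >= round(t_end/dt)");

  Release rel;
  rel.init(P.rel, var_az ? ca_az[0] : ca_az[0], rng);

  bool record = record_every > 0;
  long n_rec = record ? n_steps / record_every + 2 : 0;
  NumericMatrix trace(record ? n_rec : 0, 10);
  long rec_i = 0;
  auto rec = [&](long step, double t) {
    if (!record || (step % record_every != 0 && step != n_steps)) return;
    if (rec_i >= n_rec) return;
    trace(rec_i, 0) = t;
    trace(rec_i, 1) = rel.hazard_total();
    trace(rec_i, 2) = rel.R_pool;
    trace(rec_i, 3) = rel.U_pool;
    trace(rec_i, 4) = rel.n_pool(0);
    trace(rec_i, 5) = rel.n_pool(1);
    trace(rec_i, 6) = rel.n_refr();
    trace(rec_i, 7) = rel.cum_spont;
    trace(rec_i, 8) = rel.cum_sync;
    trace(rec_i, 9) = rel.cum_async;
    ++rec_i;
  };
  rec(0, 0.0);
  for (long i = 0; i < n_steps; ++i) {
    double cc = var_cyt ? ca_cyt[i] : ca_cyt[0];
    double cz = var_az ? ca_az[i] : ca_az[0];
    rel.step((i + 1) * dt, cc, cz, dt, rng);
    rec(i + 1, (i + 1) * dt);
  }
  List ev = List::create(
    _["time"] = NumericVector(rel.ev_time.begin(), rel.ev_time.end()),
    _["mode"] = IntegerVector(rel.ev_mode.begin(), rel.ev_mode.end()),
    _["pool"] = IntegerVector(rel.ev_pool.begin(), rel.ev_pool.end()));
  return List::create(
    _["trace"] = trace, _["n_rec"] = (double)rec_i, _["events"] = ev,
    _["cum_release"] = NumericVector::create(
      rel.cum_spont, rel.cum_sync, rel.cum_async),
    _["vesicles_left"] = (double)(rel.R_pool + rel.U_pool + rel.n_pool(0) +
                                  rel.n_pool(1)),
    _["n_refractory"] = rel.n_refr());
}
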