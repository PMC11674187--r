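// O'Hara-Rudy 2011 human ventricular myocyte model (endo/epi/mid) with an
// added Nav1.5 blocked-state variable b driven by conformation-specific
// blocking/unblocking rates (modulated receptor hypothesis), plus a 1D
// strand of resistively coupled cells. Fixed-step integration: Rush-Larsen
// for gating variables (and b), forward Euler for concentrations and V.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int NSTATE = 42;

// state indices
enum {
  iV = 0, iNai, iNass, iKi, iKss, iCai, iCass, iCansr, iCajsr,
  iM, iHf, iHs, iJ, iHsp, iJp, iML, iHL, iHLp,
  iA, iIF, iIS, iAp, iIFp, iISp,
  iD, iFf, iFs, iFcaf, iFcas, iJca, iNca, iFfp, iFcafp,
  iXrf, iXrs, iXs1, iXs2, iXk1, iJrelnp, iJrelp, iCaMKt, iB
};

struct CellParams {
  int celltype;           // 0 endo, 1 epi, 2 mid
  // external multipliers (variant recalibration x drug static scaling),
  // applied on top of the cell-type factors
  double mGNa, mGNaL, mPCa, mGKr, mGKs, mGK1, mGto, mGncx, mPnak;
  // dynamic Nav block
  double kob, kob_inv, kib, kib_inv, conc;
  bool b_on_inal;         // also scale late INa by (1-b)
};

struct Currents {
  double INa, INaL, Ito, ICaL, IKr, IKs, IK1, INaCa, INaK, Istim;
};

// physical constants and geometry (as published)
static const double Rgas = 8314.0, Temp = 310.0, Frdy = 96485.0;
static const double Lcell = 0.01, rad = 0.0011;
static const double pi_ = 3.14;
static const double vcell = 1000.0 * pi_ * rad * rad * Lcell;
static const double Ageo = 2.0 * pi_ * rad * rad + 2.0 * pi_ * rad * Lcell;
static const double Acap = 2.0 * Ageo;
static const double vmyo = 0.68 * vcell, vnsr = 0.0552 * vcell,
                    vjsr = 0.0048 * vcell, vss = 0.02 * vcell;
static const double nao = 140.0, cao = 1.8, ko = 5.4;
static const double zna = 1.0, zca = 2.0, zk = 1.0;

static const double KmCaMK = 0.15, aCaMK = 0.05, bCaMK = 0.00068,
                    CaMKo = 0.05, KmCaM = 0.0015;

inline double rl(double x, double xinf, double tau, double dt) {
  return xinf - (xinf - x) * std::exp(-dt / tau);
}

// one forward step; X updated in place, Icoup is an extra (depolarizing
// positive) current density in uA/uF, Ist the stimulus in uA/uF.
static void ord_step(double* X, const CellParams& P, double dt,
                     double Ist, double Icoup, Currents* out) {
  double v = X[iV];
  double nai = X[iNai], nass = X[iNass], ki = X[iKi], kss = X[iKss];
  double cai = X[iCai], cass = X[iCass], cansr = X[iCansr], cajsr = X[iCajsr];

  // CaMK
  double CaMKb = CaMKo * (1.0 - X[iCaMKt]) / (1.0 + KmCaM / cass);
  double CaMKa = CaMKb + X[iCaMKt];
  double dCaMKt = aCaMK * CaMKb * (CaMKb + X[iCaMKt]) - bCaMK * X[iCaMKt];

  double ENa = (Rgas * Temp / Frdy) * std::log(nao / nai);
  double EK = (Rgas * Temp / Frdy) * std::log(ko / ki);
  double EKs = (Rgas * Temp / Frdy) *
    std::log((ko + 0.01833 * nao) / (ki + 0.01833 * nai));
  double vffrt = v * Frdy * Frdy / (Rgas * Temp);
  double vfrt = v * Frdy / (Rgas * Temp);

  // ---- INa (fast) ----
  double mss = 1.0 / (1.0 + std::exp(-(v + 39.57) / 9.871));
  double tm = 1.0 / (6.765 * std::exp((v + 11.64) / 34.77) +
                     8.552 * std::exp(-(v + 77.42) / 5.955));
  double hss = 1.0 / (1.0 + std::exp((v + 82.90) / 6.086));
  double thf = 1.0 / (1.432e-5 * std::exp(-(v + 1.196) / 6.285) +
                      6.149 * std::exp((v + 0.5096) / 20.27));
  double ths = 1.0 / (0.009794 * std::exp(-(v + 17.95) / 28.05) +
                      0.3343 * std::exp((v + 5.730) / 56.66));
  const double Ahf = 0.99, Ahs = 0.01;
  double h = Ahf * X[iHf] + Ahs * X[iHs];
  double jss = hss;
  double tj = 2.038 + 1.0 / (0.02136 * std::exp(-(v + 100.6) / 8.281) +
                             0.3052 * std::exp((v + 0.9941) / 38.45));
  double hssp = 1.0 / (1.0 + std::exp((v + 89.1) / 6.086));
  double thsp = 3.0 * ths;
  double hp = Ahf * X[iHf] + Ahs * X[iHsp];
  double tjp = 1.46 * tj;
  double GNa = 75.0 * P.mGNa;
  double fINap = 1.0 / (1.0 + KmCaMK / CaMKa);
  double m3 = X[iM] * X[iM] * X[iM];
  double avail = (1.0 - fINap) * h * X[iJ] + fINap * hp * X[iJp];
  double INa = (1.0 - X[iB]) * GNa * (v - ENa) * m3 * avail;

  // blocked-state kinetics: open-conformation weight is the m^3-gated
  // available fraction, inactivated weight its m^3-gated complement.
  double w_open = m3 * avail;
  double w_inact = m3 * (1.0 - avail);
  double b_on = (w_open * P.kob + w_inact * P.kib) * P.conc;
  double b_off = w_open * P.kob_inv + w_inact * P.kib_inv;

  // ---- INaL ----
  double mLss = 1.0 / (1.0 + std::exp(-(v + 42.85) / 5.264));
  double tmL = tm;
  double hLss = 1.0 / (1.0 + std::exp((v + 87.61) / 7.488));
  const double thL = 200.0;
  double hLssp = 1.0 / (1.0 + std::exp((v + 93.81) / 7.488));
  double thLp = 3.0 * thL;
  double GNaL = 0.0075 * P.mGNaL;
  if (P.celltype == 1) GNaL *= 0.6;
  double fINaLp = 1.0 / (1.0 + KmCaMK / CaMKa);
  double INaL = GNaL * (v - ENa) * X[iML] *
    ((1.0 - fINaLp) * X[iHL] + fINaLp * X[iHLp]);
  if (P.b_on_inal) INaL *= (1.0 - X[iB]);

  // ---- Ito ----
  double ass = 1.0 / (1.0 + std::exp(-(v - 14.34) / 14.82));
  double ta = 1.0515 / (1.0 / (1.2089 * (1.0 + std::exp(-(v - 18.4099) / 29.3814))) +
                        3.5 / (1.0 + std::exp((v + 100.0) / 29.3814)));
  double iss = 1.0 / (1.0 + std::exp((v + 43.94) / 5.711));
  double delta_epi = (P.celltype == 1)
    ? 1.0 - 0.95 / (1.0 + std::exp((v + 70.0) / 5.0)) : 1.0;
  double tiF = 4.562 + 1.0 / (0.3933 * std::exp(-(v + 100.0) / 100.0) +
                              0.08004 * std::exp((v + 50.0) / 16.59));
  double tiS = 23.62 + 1.0 / (0.001416 * std::exp(-(v + 96.52) / 59.05) +
                              1.780e-8 * std::exp((v + 114.1) / 8.079));
  tiF *= delta_epi; tiS *= delta_epi;
  double AiF = 1.0 / (1.0 + std::exp((v - 213.6) / 151.2));
  double AiS = 1.0 - AiF;
  double i_gate = AiF * X[iIF] + AiS * X[iIS];
  double assp = 1.0 / (1.0 + std::exp(-(v - 24.34) / 14.82));
  double dti_develop = 1.354 + 1.0e-4 /
    (std::exp((v - 167.4) / 15.89) + std::exp(-(v - 12.23) / 0.2154));
  double dti_recover = 1.0 - 0.5 / (1.0 + std::exp((v + 70.0) / 20.0));
  double tiFp = dti_develop * dti_recover * tiF;
  double tiSp = dti_develop * dti_recover * tiS;
  double ip_gate = AiF * X[iIFp] + AiS * X[iISp];
  double Gto = 0.02 * P.mGto;
  if (P.celltype == 1 || P.celltype == 2) Gto *= 4.0;
  double fItop = 1.0 / (1.0 + KmCaMK / CaMKa);
  double Ito = Gto * (v - EK) *
    ((1.0 - fItop) * X[iA] * i_gate + fItop * X[iAp] * ip_gate);

  // ---- ICaL / ICaNa / ICaK ----
  double dss = 1.0 / (1.0 + std::exp(-(v + 3.940) / 4.230));
  double td = 0.6 + 1.0 / (std::exp(-0.05 * (v + 6.0)) +
                           std::exp(0.09 * (v + 14.0)));
  double fss = 1.0 / (1.0 + std::exp((v + 19.58) / 3.696));
  double tff = 7.0 + 1.0 / (0.0045 * std::exp(-(v + 20.0) / 10.0) +
                            0.0045 * std::exp((v + 20.0) / 10.0));
  double tfs = 1000.0 + 1.0 / (0.000035 * std::exp(-(v + 5.0) / 4.0) +
                               0.000035 * std::exp((v + 5.0) / 6.0));
  const double Aff = 0.6, Afs = 0.4;
  double f = Aff * X[iFf] + Afs * X[iFs];
  double fcass = fss;
  double tfcaf = 7.0 + 1.0 / (0.04 * std::exp(-(v - 4.0) / 7.0) +
                              0.04 * std::exp((v - 4.0) / 7.0));
  double tfcas = 100.0 + 1.0 / (0.00012 * std::exp(-v / 3.0) +
                                0.00012 * std::exp(v / 7.0));
  double Afcaf = 0.3 + 0.6 / (1.0 + std::exp((v - 10.0) / 10.0));
  double Afcas = 1.0 - Afcaf;
  double fca = Afcaf * X[iFcaf] + Afcas * X[iFcas];
  const double tjca = 75.0;
  double tffp = 2.5 * tff;
  double fp = Aff * X[iFfp] + Afs * X[iFs];
  double tfcafp = 2.5 * tfcaf;
  double fcap = Afcaf * X[iFcafp] + Afcas * X[iFcas];
  const double Kmn = 0.002, k2n = 1000.0;
  double km2n = X[iJca] * 1.0;
  double tmp = 1.0 + Kmn / cass;
  double anca = 1.0 / (k2n / km2n + tmp * tmp * tmp * tmp);
  double vfrt2 = 2.0 * vfrt;
  double e2v = std::exp(vfrt2), e1v = std::exp(vfrt);
  double den2 = e2v - 1.0, den1 = e1v - 1.0;
  if (std::fabs(den2) < 1e-12) den2 = (den2 >= 0 ? 1e-12 : -1e-12);
  if (std::fabs(den1) < 1e-12) den1 = (den1 >= 0 ? 1e-12 : -1e-12);
  double PhiCaL = 4.0 * vffrt * (cass * e2v - 0.341 * cao) / den2;
  double PhiCaNa = 1.0 * vffrt * (0.75 * nass * e1v - 0.75 * nao) / den1;
  double PhiCaK = 1.0 * vffrt * (0.75 * kss * e1v - 0.75 * ko) / den1;
  double PCa = 0.0001 * P.mPCa;
  if (P.celltype == 1) PCa *= 1.2;
  if (P.celltype == 2) PCa *= 2.5;
  double PCap = 1.1 * PCa;
  double PCaNa = 0.00125 * PCa, PCaK = 3.574e-4 * PCa;
  double PCaNap = 0.00125 * PCap, PCaKp = 3.574e-4 * PCap;
  double fICaLp = 1.0 / (1.0 + KmCaMK / CaMKa);
  double d_g = X[iD], nca = X[iNca], jca_g = X[iJca];
  double ICaL = (1.0 - fICaLp) * PCa * PhiCaL * d_g *
      (f * (1.0 - nca) + jca_g * fca * nca) +
    fICaLp * PCap * PhiCaL * d_g * (fp * (1.0 - nca) + jca_g * fcap * nca);
  double ICaNa = (1.0 - fICaLp) * PCaNa * PhiCaNa * d_g *
      (f * (1.0 - nca) + jca_g * fca * nca) +
    fICaLp * PCaNap * PhiCaNa * d_g * (fp * (1.0 - nca) + jca_g * fcap * nca);
  double ICaK = (1.0 - fICaLp) * PCaK * PhiCaK * d_g *
      (f * (1.0 - nca) + jca_g * fca * nca) +
    fICaLp * PCaKp * PhiCaK * d_g * (fp * (1.0 - nca) + jca_g * fcap * nca);

  // ---- IKr ----
  double xrss = 1.0 / (1.0 + std::exp(-(v + 8.337) / 6.789));
  double txrf = 12.98 + 1.0 / (0.3652 * std::exp((v - 31.66) / 3.869) +
                               4.123e-5 * std::exp(-(v - 47.78) / 20.38));
  double txrs = 1.865 + 1.0 / (0.06629 * std::exp((v - 34.70) / 7.355) +
                               1.128e-5 * std::exp(-(v - 29.74) / 25.94));
  double Axrf = 1.0 / (1.0 + std::exp((v + 54.81) / 38.21));
  double Axrs = 1.0 - Axrf;
  double xr = Axrf * X[iXrf] + Axrs * X[iXrs];
  double rkr = 1.0 / ((1.0 + std::exp((v + 55.0) / 75.0)) *
                      (1.0 + std::exp((v - 10.0) / 30.0)));
  double GKr = 0.046 * P.mGKr;
  if (P.celltype == 1) GKr *= 1.3;
  if (P.celltype == 2) GKr *= 0.8;
  double IKr = GKr * std::sqrt(ko / 5.4) * xr * rkr * (v - EK);

  // ---- IKs ----
  double xs1ss = 1.0 / (1.0 + std::exp(-(v + 11.60) / 8.932));
  double txs1 = 817.3 + 1.0 / (2.326e-4 * std::exp((v + 48.28) / 17.80) +
                               0.001292 * std::exp(-(v + 210.0) / 230.0));
  double xs2ss = xs1ss;
  double txs2 = 1.0 / (0.01 * std::exp((v - 50.0) / 20.0) +
                       0.0193 * std::exp(-(v + 66.54) / 31.0));
  double KsCa = 1.0 + 0.6 / (1.0 + std::pow(3.8e-5 / cai, 1.4));
  double GKs = 0.0034 * P.mGKs;
  if (P.celltype == 1) GKs *= 1.4;
  double IKs = GKs * KsCa * X[iXs1] * X[iXs2] * (v - EKs);

  // ---- IK1 ----
  double xk1ss = 1.0 / (1.0 + std::exp(-(v + 2.5538 * ko + 144.59) /
                                       (1.5692 * ko + 3.8115)));
  double txk1 = 122.2 / (std::exp(-(v + 127.2) / 20.36) +
                         std::exp((v + 236.8) / 69.33));
  double rk1 = 1.0 / (1.0 + std::exp((v + 105.8 - 2.6 * ko) / 9.493));
  double GK1 = 0.1908 * P.mGK1;
  if (P.celltype == 1) GK1 *= 1.2;
  if (P.celltype == 2) GK1 *= 1.3;
  double IK1 = GK1 * std::sqrt(ko) * rk1 * X[iXk1] * (v - EK);

  // ---- INaCa ----
  const double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5,
    wna = 6.0e4, wca = 6.0e4, wnaca = 5.0e3, kcaon = 1.5e6, kcaoff = 5.0e3,
    qna = 0.5224, qca = 0.1670;
  double hca = std::exp(qca * vfrt), hna = std::exp(qna * vfrt);
  double Gncx = 0.0008 * P.mGncx;
  if (P.celltype == 1) Gncx *= 1.1;
  if (P.celltype == 2) Gncx *= 1.4;
  const double KmCaAct = 150.0e-6;

  double INaCa_i, INaCa_ss;
  {
    double h1 = 1.0 + nai / kna3 * (1.0 + hna);
    double h2 = (nai * hna) / (kna3 * h1);
    double h3 = 1.0 / h1;
    double h4 = 1.0 + nai / kna1 * (1.0 + nai / kna2);
    double h5 = nai * nai / (h4 * kna1 * kna2);
    double h6 = 1.0 / h4;
    double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
    double h8 = nao / (kna3 * hna * h7);
    double h9 = 1.0 / h7;
    double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
    double h11 = nao * nao / (h10 * kna1 * kna2);
    double h12 = 1.0 / h10;
    double k1 = h12 * cao * kcaon, k2 = kcaoff;
    double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
    double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
    double k5 = kcaoff, k6 = h6 * cai * kcaon;
    double k7 = h5 * h2 * wna, k8 = h8 * h11 * wna;
    double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
    double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
    double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
    double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
    double s = x1 + x2 + x3 + x4;
    double E1 = x1 / s, E2 = x2 / s, E3 = x3 / s, E4 = x4 / s;
    double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
    double JncxCa = E2 * k2 - E1 * k1;
    double allo = 1.0 / (1.0 + (KmCaAct / cai) * (KmCaAct / cai));
    INaCa_i = 0.8 * Gncx * allo * (zna * JncxNa + zca * JncxCa);
  }
  {
    double h1 = 1.0 + nass / kna3 * (1.0 + hna);
    double h2 = (nass * hna) / (kna3 * h1);
    double h3 = 1.0 / h1;
    double h4 = 1.0 + nass / kna1 * (1.0 + nass / kna2);
    double h5 = nass * nass / (h4 * kna1 * kna2);
    double h6 = 1.0 / h4;
    double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
    double h8 = nao / (kna3 * hna * h7);
    double h9 = 1.0 / h7;
    double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
    double h11 = nao * nao / (h10 * kna1 * kna2);
    double h12 = 1.0 / h10;
    double k1 = h12 * cao * kcaon, k2 = kcaoff;
    double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
    double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
    double k5 = kcaoff, k6 = h6 * cass * kcaon;
    double k7 = h5 * h2 * wna, k8 = h8 * h11 * wna;
    double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
    double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
    double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
    double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
    double s = x1 + x2 + x3 + x4;
    double E1 = x1 / s, E2 = x2 / s, E3 = x3 / s, E4 = x4 / s;
    double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
    double JncxCa = E2 * k2 - E1 * k1;
    double allo = 1.0 / (1.0 + (KmCaAct / cass) * (KmCaAct / cass));
    INaCa_ss = 0.2 * Gncx * allo * (zna * JncxNa + zca * JncxCa);
  }

  // ---- INaK ----
  double INaK;
  {
    const double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4,
      k3p = 1899.0, k3m = 79300.0, k4p = 639.0, k4m = 40.0,
      Knai0 = 9.073, Knao0 = 27.78, delta = -0.1550,
      Kki = 0.5, Kko = 0.3582, MgADP = 0.05, MgATP = 9.8,
      Kmgatp = 1.698e-7, H = 1.0e-7, eP = 4.2, Khp = 1.698e-7,
      Knap = 224.0, Kxkur = 292.0;
    double Knai = Knai0 * std::exp(delta * vfrt / 3.0);
    double Knao = Knao0 * std::exp((1.0 - delta) * vfrt / 3.0);
    double Pfac = eP / (1.0 + H / Khp + nai / Knap + ki / Kxkur);
    double t1 = 1.0 + nai / Knai, t2 = 1.0 + ki / Kki;
    double t3 = 1.0 + nao / Knao, t4 = 1.0 + ko / Kko;
    double a1 = k1p * std::pow(nai / Knai, 3.0) /
      (t1 * t1 * t1 + t2 * t2 - 1.0);
    double b1 = k1m * MgADP;
    double a2 = k2p;
    double b2 = k2m * std::pow(nao / Knao, 3.0) /
      (t3 * t3 * t3 + t4 * t4 - 1.0);
    double a3 = k3p * (ko / Kko) * (ko / Kko) /
      (t3 * t3 * t3 + t4 * t4 - 1.0);
    double b3 = k3m * Pfac * H / (1.0 + MgATP / Kmgatp);
    double a4 = (k4p * MgATP / Kmgatp) / (1.0 + MgATP / Kmgatp);
    double b4 = k4m * (ki / Kki) * (ki / Kki) /
      (t1 * t1 * t1 + t2 * t2 - 1.0);
    double x1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
    double x2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
    double x3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
    double x4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b2 * a1;
    double s = x1 + x2 + x3 + x4;
    double E1 = x1 / s, E2 = x2 / s, E3 = x3 / s, E4 = x4 / s;
    double JnakNa = 3.0 * (E1 * a3 - E2 * b3);
    double JnakK = 2.0 * (E4 * b1 - E3 * a1);
    double Pnak = 30.0 * P.mPnak;
    if (P.celltype == 1) Pnak *= 0.9;
    if (P.celltype == 2) Pnak *= 0.7;
    INaK = Pnak * (zna * JnakNa + zk * JnakK);
  }

  // ---- background and pump currents ----
  double xkb = 1.0 / (1.0 + std::exp(-(v - 14.48) / 18.34));
  double GKb = 0.003;
  if (P.celltype == 1) GKb *= 0.6;
  double IKb = GKb * xkb * (v - EK);
  double INab = 3.75e-10 * vffrt * (nai * e1v - nao) / den1;
  double ICab = 2.5e-8 * 4.0 * vffrt * (cai * e2v - 0.341 * cao) / den2;
  double IpCa = 0.0005 * cai / (0.0005 + cai);

  // ---- diffusion, release, uptake ----
  double JdiffNa = (nass - nai) / 2.0;
  double JdiffK = (kss - ki) / 2.0;
  double Jdiff = (cass - cai) / 0.2;

  const double bt = 4.75;
  double a_rel = 0.5 * bt;
  double Jrel_inf = a_rel * (-ICaL) / (1.0 + std::pow(1.5 / cajsr, 8.0));
  if (P.celltype == 2) Jrel_inf *= 1.7;
  double tau_rel = bt / (1.0 + 0.0123 / cajsr);
  if (tau_rel < 0.001) tau_rel = 0.001;
  double btp = 1.25 * bt;
  double a_relp = 0.5 * btp;
  double Jrel_infp = a_relp * (-ICaL) / (1.0 + std::pow(1.5 / cajsr, 8.0));
  if (P.celltype == 2) Jrel_infp *= 1.7;
  double tau_relp = btp / (1.0 + 0.0123 / cajsr);
  if (tau_relp < 0.001) tau_relp = 0.001;
  double fJrelp = 1.0 / (1.0 + KmCaMK / CaMKa);
  double Jrel = (1.0 - fJrelp) * X[iJrelnp] + fJrelp * X[iJrelp];

  double Jupnp = 0.004375 * cai / (cai + 0.00092);
  double Jupp = 2.75 * 0.004375 * cai / (cai + 0.00092 - 0.00017);
  if (P.celltype == 1) { Jupnp *= 1.3; Jupp *= 1.3; }
  double fJupp = 1.0 / (1.0 + KmCaMK / CaMKa);
  double Jleak = 0.0039375 * cansr / 15.0;
  double Jup = (1.0 - fJupp) * Jupnp + fJupp * Jupp - Jleak;
  double Jtr = (cansr - cajsr) / 100.0;

  // ---- membrane potential ----
  double Iion = INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs + IK1 +
    INaCa_i + INaCa_ss + INaK + INab + IKb + IpCa + ICab + Ist;
  double dv = -Iion + Icoup;

  // ---- concentration derivatives ----
  double dnai = -(INa + INaL + 3.0 * INaCa_i + 3.0 * INaK + INab) * Acap /
      (Frdy * vmyo) + JdiffNa * vss / vmyo;
  double dnass = -(ICaNa + 3.0 * INaCa_ss) * Acap / (Frdy * vss) - JdiffNa;
  double dki = -(Ito + IKr + IKs + IK1 + IKb + Ist - 2.0 * INaK) * Acap /
      (Frdy * vmyo) + JdiffK * vss / vmyo;
  double dkss = -ICaK * Acap / (Frdy * vss) - JdiffK;
  const double cmdnmax0 = 0.05, kmcmdn = 0.00238, trpnmax = 0.07,
    kmtrpn = 0.0005, BSRmax = 0.047, KmBSR = 0.00087, BSLmax = 1.124,
    KmBSL = 0.0087, csqnmax = 10.0, kmcsqn = 0.8;
  double cmdnmax = cmdnmax0;
  if (P.celltype == 1) cmdnmax *= 1.3;
  double q1 = kmcmdn + cai, q2 = kmtrpn + cai;
  double Bcai = 1.0 / (1.0 + cmdnmax * kmcmdn / (q1 * q1) +
                       trpnmax * kmtrpn / (q2 * q2));
  double dcai = Bcai * (-(IpCa + ICab - 2.0 * INaCa_i) * Acap /
      (2.0 * Frdy * vmyo) - Jup * vnsr / vmyo + Jdiff * vss / vmyo);
  double q3 = KmBSR + cass, q4 = KmBSL + cass;
  double Bcass = 1.0 / (1.0 + BSRmax * KmBSR / (q3 * q3) +
                        BSLmax * KmBSL / (q4 * q4));
  double dcass = Bcass * (-(ICaL - 2.0 * INaCa_ss) * Acap /
      (2.0 * Frdy * vss) + Jrel * vjsr / vss - Jdiff);
  double dcansr = Jup - Jtr * vjsr / vnsr;
  double q5 = kmcsqn + cajsr;
  double Bcajsr = 1.0 / (1.0 + csqnmax * kmcsqn / (q5 * q5));
  double dcajsr = Bcajsr * (Jtr - Jrel);

  // ---- updates ----
  X[iM]  = rl(X[iM], mss, tm, dt);
  X[iHf] = rl(X[iHf], hss, thf, dt);
  X[iHs] = rl(X[iHs], hss, ths, dt);
  X[iJ]  = rl(X[iJ], jss, tj, dt);
  X[iHsp] = rl(X[iHsp], hssp, thsp, dt);
  X[iJp] = rl(X[iJp], jss, tjp, dt);
  X[iML] = rl(X[iML], mLss, tmL, dt);
  X[iHL] = rl(X[iHL], hLss, thL, dt);
  X[iHLp] = rl(X[iHLp], hLssp, thLp, dt);
  X[iA]  = rl(X[iA], ass, ta, dt);
  X[iIF] = rl(X[iIF], iss, tiF, dt);
  X[iIS] = rl(X[iIS], iss, tiS, dt);
  X[iAp] = rl(X[iAp], assp, ta, dt);
  X[iIFp] = rl(X[iIFp], iss, tiFp, dt);
  X[iISp] = rl(X[iISp], iss, tiSp, dt);
  X[iD]  = rl(X[iD], dss, td, dt);
  X[iFf] = rl(X[iFf], fss, tff, dt);
  X[iFs] = rl(X[iFs], fss, tfs, dt);
  X[iFcaf] = rl(X[iFcaf], fcass, tfcaf, dt);
  X[iFcas] = rl(X[iFcas], fcass, tfcas, dt);
  X[iJca] = rl(X[iJca], fcass, tjca, dt);
  X[iFfp] = rl(X[iFfp], fss, tffp, dt);
  X[iFcafp] = rl(X[iFcafp], fcass, tfcafp, dt);
  // nca relaxes toward anca*k2n/km2n with rate km2n
  X[iNca] = anca * k2n / km2n - (anca * k2n / km2n - X[iNca]) *
    std::exp(-km2n * dt);
  X[iXrf] = rl(X[iXrf], xrss, txrf, dt);
  X[iXrs] = rl(X[iXrs], xrss, txrs, dt);
  X[iXs1] = rl(X[iXs1], xs1ss, txs1, dt);
  X[iXs2] = rl(X[iXs2], xs2ss, txs2, dt);
  X[iXk1] = rl(X[iXk1], xk1ss, txk1, dt);
  X[iJrelnp] = rl(X[iJrelnp], Jrel_inf, tau_rel, dt);
  X[iJrelp] = rl(X[iJrelp], Jrel_infp, tau_relp, dt);
  X[iCaMKt] += dt * dCaMKt;

  double brate = b_on + b_off;
  if (brate > 1e-12) {
    double binf = b_on / brate;
    X[iB] = binf - (binf - X[iB]) * std::exp(-brate * dt);
  }
  if (X[iB] < 0.0) X[iB] = 0.0;
  if (X[iB] > 1.0) X[iB] = 1.0;

  X[iNai] += dt * dnai;
  X[iNass] += dt * dnass;
  X[iKi] += dt * dki;
  X[iKss] += dt * dkss;
  X[iCai] += dt * dcai;
  X[iCass] += dt * dcass;
  X[iCansr] += dt * dcansr;
  X[iCajsr] += dt * dcajsr;
  X[iV] += dt * dv;

  if (out) {
    out->INa = INa; out->INaL = INaL; out->Ito = Ito; out->ICaL = ICaL;
    out->IKr = IKr; out->IKs = IKs; out->IK1 = IK1;
    out->INaCa = INaCa_i + INaCa_ss; out->INaK = INaK; out->Istim = Ist;
  }
}

// published steady-state initial conditions (endo, 1 Hz pacing)
static void default_state(double* X) {
  X[iV] = -87.5; X[iNai] = 7.268; X[iNass] = 7.268;
  X[iKi] = 144.65; X[iKss] = 144.65;
  X[iCai] = 8.6e-5; X[iCass] = 8.49e-5; X[iCansr] = 1.61; X[iCajsr] = 1.56;
  X[iM] = 0.0074621; X[iHf] = 0.692591; X[iHs] = 0.692574; X[iJ] = 0.692477;
  X[iHsp] = 0.448501; X[iJp] = 0.692413;
  X[iML] = 0.000194015; X[iHL] = 0.496116; X[iHLp] = 0.265885;
  X[iA] = 0.00101185; X[iIF] = 0.999542; X[iIS] = 0.589579;
  X[iAp] = 0.000515567; X[iIFp] = 0.999542; X[iISp] = 0.641861;
  X[iD] = 2.43015e-9; X[iFf] = 0.9999843; X[iFs] = 0.9101062;
  X[iFcaf] = 0.9999014; X[iFcas] = 0.9998223; X[iJca] = 0.9999846;
  X[iNca] = 0.002749414; X[iFfp] = 0.9999843; X[iFcafp] = 0.9999014;
  X[iXrf] = 8.26608e-6; X[iXrs] = 0.453268;
  X[iXs1] = 0.270492; X[iXs2] = 0.0001962; X[iXk1] = 0.996801;
  X[iJrelnp] = 2.53943e-5; X[iJrelp] = 3.17262e-7; X[iCaMKt] = 0.0124065;
  X[iB] = 0.0;
}

static CellParams make_params(int cell_type, NumericVector mult,
                              NumericVector nav_block) {
  CellParams P;
  P.celltype = cell_type;
  P.mGNa = mult["GNa"]; P.mGNaL = mult["GNaL"]; P.mPCa = mult["PCa"];
  P.mGKr = mult["GKr"]; P.mGKs = mult["GKs"]; P.mGK1 = mult["GK1"];
  P.mGto = mult["Gto"]; P.mGncx = mult["Gncx"]; P.mPnak = mult["Pnak"];
  P.kob = nav_block["k_ob"]; P.kob_inv = nav_block["k_ob_inv"];
  P.kib = nav_block["k_ib"]; P.kib_inv = nav_block["k_ib_inv"];
  P.conc = nav_block["conc"];
  P.b_on_inal = nav_block["b_on_inal"] != 0.0;
  return P;
}

// per-beat AP feature tracker (shared by single-cell and strand runs)
struct BeatTracker {
  double rp, peak, peak_t, dvdt_max, dvdt_max_t, v_prev, t_prev;
  double apd90; bool have_apd;
  void start(double v, double t) {
    rp = v; peak = v; peak_t = t; dvdt_max = -1e30; dvdt_max_t = t;
    v_prev = v; t_prev = t; apd90 = NA_REAL; have_apd = false;
  }
  // The upstroke velocity is tracked only while V lies in the upstroke band
  // (-65..+10 mV): under very slow (gap-junction-limited) conduction the
  // electrotonic foot of the incoming wave can be steeper than the
  // regenerative upstroke itself, and an unrestricted max-dV/dt would mark
  // the foot, not the activation.
  void update(double v, double t) {
    double dvdt = (v - v_prev) / (t - t_prev);
    if (dvdt > dvdt_max && v_prev > -65.0 && v_prev < 10.0) {
      dvdt_max = dvdt; dvdt_max_t = t;
    }
    if (v > peak) { peak = v; peak_t = t; }
    if (!have_apd && t > peak_t && peak > 0.0) {
      double v90 = peak - 0.9 * (peak - rp);
      if (v <= v90 && v_prev > v90) {
        double frac = (v_prev - v90) / (v_prev - v);
        double t90 = t_prev + frac * (t - t_prev);
        apd90 = t90 - dvdt_max_t;
        have_apd = true;
      }
    }
    v_prev = v; t_prev = t;
  }
};

// [[Rcpp::export]]
List ord_paced_cpp(int cell_type, NumericVector mult, NumericVector nav_block,
                   double cl, double stim_amp, double stim_dur,
                   int n_beats, int n_record_beats, double dt,
                   double record_dt, Nullable<NumericVector> init) {
  CellParams P = make_params(cell_type, mult, nav_block);
  std::vector<double> X(NSTATE);
  if (init.isNotNull()) {
    NumericVector v0(init);
    if (v0.size() != NSTATE) stop("init state must have length %d", NSTATE);
    for (int i = 0; i < NSTATE; ++i) X[i] = v0[i];
  } else default_state(X.data());

  int steps_per_beat = (int)std::lround(cl / dt);
  int rec_every = std::max(1, (int)std::lround(record_dt / dt));
  if (n_record_beats > n_beats) n_record_beats = n_beats;
  int rec_start_beat = n_beats - n_record_beats;
  int n_rec = n_record_beats * (steps_per_beat / rec_every) + 1;

  NumericVector time(n_rec), V(n_rec), b(n_rec);
  NumericMatrix currents(n_rec, 9);
  colnames(currents) = CharacterVector::create(
    "INa", "INaL", "Ito", "ICaL", "IKr", "IKs", "IK1", "INaCa", "INaK");
  NumericVector apd90(n_beats), peak_v(n_beats), dvdt_max(n_beats);
  Currents cur;
  BeatTracker bt;
  int ri = 0;
  double t_global = 0.0;

  for (int beat = 0; beat < n_beats; ++beat) {
    bt.start(X[iV], t_global);
    bool recording = beat >= rec_start_beat;
    if (recording && ri == 0) {
      time[ri] = t_global; V[ri] = X[iV]; b[ri] = X[iB];
      for (int c = 0; c < 9; ++c) currents(ri, c) = 0.0;
      ++ri;
    }
    for (int s = 0; s < steps_per_beat; ++s) {
      double t_in_beat = s * dt;
      double Ist = (t_in_beat < stim_dur) ? stim_amp : 0.0;
      ord_step(X.data(), P, dt, Ist, 0.0, &cur);
      t_global += dt;
      bt.update(X[iV], t_global);
      if (recording && ((s + 1) % rec_every == 0) && ri < n_rec) {
        time[ri] = t_global; V[ri] = X[iV]; b[ri] = X[iB];
        currents(ri, 0) = cur.INa; currents(ri, 1) = cur.INaL;
        currents(ri, 2) = cur.Ito; currents(ri, 3) = cur.ICaL;
        currents(ri, 4) = cur.IKr; currents(ri, 5) = cur.IKs;
        currents(ri, 6) = cur.IK1; currents(ri, 7) = cur.INaCa;
        currents(ri, 8) = cur.INaK;
        ++ri;
      }
      if (!R_finite(X[iV]) || std::fabs(X[iV]) > 500.0)
        stop("solver blow-up at t = %.3f ms (beat %d): V = %g",
             t_global, beat + 1, X[iV]);
    }
    apd90[beat] = bt.apd90;
    peak_v[beat] = bt.peak;
    dvdt_max[beat] = bt.dvdt_max;
  }

  NumericVector final_state(NSTATE);
  for (int i = 0; i < NSTATE; ++i) final_state[i] = X[i];
  return List::create(
    _["time"] = time[Range(0, ri - 1)],
    _["V"] = V[Range(0, ri - 1)],
    _["b"] = b[Range(0, ri - 1)],
    _["currents"] = currents(Range(0, ri - 1), _),
    _["apd90"] = apd90,
    _["peak_v"] = peak_v,
    _["dvdt_max"] = dvdt_max,
    _["state"] = final_state);
}

// [[Rcpp::export]]
List ord_strand_cpp(int n_cells, NumericVector init_state, int cell_type,
                    NumericVector mult, NumericVector nav_block,
                    NumericVector gj_ps_pf, double cl,
                    double stim_amp, double stim_dur, int n_stim_cells,
                    int n_beats, double dt, double record_dt) {
  if (n_cells < 2) stop("n_cells must be >= 2");
  if (init_state.size() != NSTATE) stop("init state must have length %d", NSTATE);
  CellParams P = make_params(cell_type, mult, nav_block);

  // per-interface coupling, pS/pF -> uA/uF per mV is * 1e-3
  std::vector<double> g(n_cells - 1);
  if (gj_ps_pf.size() == 1)
    for (int i = 0; i < n_cells - 1; ++i) g[i] = gj_ps_pf[0] * 1e-3;
  else if (gj_ps_pf.size() == n_cells - 1)
    for (int i = 0; i < n_cells - 1; ++i) g[i] = gj_ps_pf[i] * 1e-3;
  else stop("gj must be scalar or one value per interface");

  std::vector<double> X((size_t)n_cells * NSTATE);
  for (int c = 0; c < n_cells; ++c)
    for (int i = 0; i < NSTATE; ++i) X[(size_t)c * NSTATE + i] = init_state[i];

  int steps_per_beat = (int)std::lround(cl / dt);
  int rec_every = std::max(1, (int)std::lround(record_dt / dt));
  int n_rec = steps_per_beat / rec_every + 1;
  NumericMatrix Vxt(n_rec, n_cells);   // last beat only
  NumericVector rec_time(n_rec);

  std::vector<BeatTracker> bt(n_cells);
  std::vector<double> vold(n_cells);
  double t_global = 0.0;
  NumericVector act_time(n_cells), pk(n_cells), dvm(n_cells);

  for (int beat = 0; beat < n_beats; ++beat) {
    bool last = beat == n_beats - 1;
    double t_beat0 = t_global;
    for (int c = 0; c < n_cells; ++c)
      bt[c].start(X[(size_t)c * NSTATE + iV], t_global);
    int ri = 0;
    if (last) {
      rec_time[ri] = 0.0;
      for (int c = 0; c < n_cells; ++c) Vxt(ri, c) = X[(size_t)c * NSTATE + iV];
      ++ri;
    }
    for (int s = 0; s < steps_per_beat; ++s) {
      double t_in_beat = s * dt;
      double Ist = (t_in_beat < stim_dur) ? stim_amp : 0.0;
      for (int c = 0; c < n_cells; ++c) vold[c] = X[(size_t)c * NSTATE + iV];
      for (int c = 0; c < n_cells; ++c) {
        double coup = 0.0;
        if (c > 0) coup += g[c - 1] * (vold[c - 1] - vold[c]);
        if (c < n_cells - 1) coup += g[c] * (vold[c + 1] - vold[c]);
        ord_step(&X[(size_t)c * NSTATE], P, dt, c < n_stim_cells ? Ist : 0.0,
                 coup, nullptr);
      }
      t_global += dt;
      for (int c = 0; c < n_cells; ++c) {
        double v = X[(size_t)c * NSTATE + iV];
        bt[c].update(v, t_global);
        if (!R_finite(v) || std::fabs(v) > 500.0)
          stop("solver blow-up in cell %d at t = %.3f ms", c + 1, t_global);
      }
      if (last && ((s + 1) % rec_every == 0) && ri < n_rec) {
        rec_time[ri] = t_global - t_beat0;
        for (int c = 0; c < n_cells; ++c)
          Vxt(ri, c) = X[(size_t)c * NSTATE + iV];
        ++ri;
      }
    }
    if (last) {
      for (int c = 0; c < n_cells; ++c) {
        act_time[c] = bt[c].dvdt_max_t - t_beat0;
        pk[c] = bt[c].peak;
        dvm[c] = bt[c].dvdt_max;
      }
    }
  }

  return List::create(
    _["activation_time"] = act_time,
    _["peak_v"] = pk,
    _["dvdt_max"] = dvm,
    _["time"] = rec_time,
    _["V"] = Vxt);
}
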