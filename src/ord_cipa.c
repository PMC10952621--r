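/* O'Hara-Rudy human ventricular myocyte model, CiPA v1.0 formulation:
 * ORd 2011 membrane/Ca handling equations with the 2017 rescaled maximal
 * conductances (ICaL x1.007, IKr x1.013, IKs x1.87, INaL x2.661, IK1 x1.698)
 * and the 6-state hERG Markov scheme for IKr (drug-free subsystem; the
 * drug-bound states are identically zero here and omitted).
 *
 * State layout (0-based):
 *  0 v      1 nai    2 nass   3 ki     4 kss    5 cai    6 cass
 *  7 cansr  8 cajsr  9 m     10 hf    11 hs    12 j     13 hsp   14 jp
 * 15 mL    16 hL    17 hLp   18 a     19 iF    20 iS    21 ap    22 iFp
 * 23 iSp   24 d     25 ff    26 fs    27 fcaf  28 fcas  29 jca   30 nca
 * 31 ffp   32 fcafp 33 xs1   34 xs2   35 xk1   36 Jrelnp 37 Jrelp
 * 38 CaMKt 39 IC1   40 IC2   41 C1    42 C2    43 O     44 IO
 *
 * Parameters: 0 celltype (0 endo, 1 epi, 2 mid), 1 iks_scale,
 *             2 stim_amp (uA/uF), 3 stim_start (ms), 4 stim_dur (ms)
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

#define N_STATE 45
#define N_PARMS 5
#define N_OUT   10

static double parms[N_PARMS];

void ord_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

/* extracellular ion concentrations (mM) and physical constants */
static const double nao = 140.0, cao = 1.8, ko = 5.4;
static const double Rgas = 8314.0, Temp = 310.0, Frdy = 96485.0;

/* hERG Markov rate parameters (A per ms, B per mV, q: Q10-style factor
 * applied as q^((T-20)/10) at T = 37 C) */
static const double hA1 = 0.0264,    hB1 = 4.631e-5,  hq1 = 4.843;
static const double hA2 = 4.986e-6,  hB2 = -0.004226, hq2 = 4.23;
static const double hA3 = 0.001214,  hB3 = 0.008516,  hq3 = 4.962;
static const double hA4 = 1.854e-5,  hB4 = -0.04641,  hq4 = 3.769;
static const double hA11 = 0.0007868, hB11 = 1.535e-8, hq11 = 4.942;
static const double hA21 = 5.455e-6, hB21 = -0.1688,  hq21 = 4.156;
static const double hA31 = 0.005509, hB31 = 7.771e-9, hq31 = 4.22;
static const double hA41 = 0.001416, hB41 = -0.02877, hq41 = 1.459;
static const double hA51 = 0.4492,   hB51 = 0.008595, hq51 = 5.0;
static const double hA52 = 0.3181,   hB52 = 3.613e-8, hq52 = 4.663;
static const double hA53 = 0.149,    hB53 = 0.004668, hq53 = 2.412;
static const double hA61 = 0.01241,  hB61 = 0.1725,   hq61 = 5.568;
static const double hA62 = 0.3226,   hB62 = -6.575e-4, hq62 = 5.0;
static const double hA63 = 0.008978, hB63 = -0.02215, hq63 = 5.682;
static const double hTemp = 37.0;

static double qfac(double q) { return exp((hTemp - 20.0) * log(q) / 10.0); }

/* full right-hand side; out[] receives membrane currents (uA/uF) */
static void ord_rhs(double t, const double *y, double *ydot,
                    const double *p, double *out)
{
    int celltype = (int) p[0];
    double iks_scale = p[1];
    double stim_amp = p[2], stim_start = p[3], stim_dur = p[4];

    double v = y[0];
    double nai = y[1], nass = y[2], ki = y[3], kss = y[4];
    double cai = y[5], cass = y[6], cansr = y[7], cajsr = y[8];
    double m = y[9], hf = y[10], hs = y[11], j = y[12], hsp = y[13],
        jp = y[14];
    double mL = y[15], hL = y[16], hLp = y[17];
    double a = y[18], iF = y[19], iS = y[20], ap = y[21], iFp = y[22],
        iSp = y[23];
    double d = y[24], ff = y[25], fs = y[26], fcaf = y[27], fcas = y[28],
        jca = y[29], nca = y[30], ffp = y[31], fcafp = y[32];
    double xs1 = y[33], xs2 = y[34], xk1 = y[35];
    double Jrelnp = y[36], Jrelp = y[37], CaMKt = y[38];
    double hIC1 = y[39], hIC2 = y[40], hC1 = y[41], hC2 = y[42],
        hO = y[43], hIO = y[44];

    /* cell geometry (cm, uL) */
    double L = 0.01, rad = 0.0011;
    double vcell = 1000.0 * 3.14 * rad * rad * L;
    double Ageo = 2.0 * 3.14 * rad * rad + 2.0 * 3.14 * rad * L;
    double Acap = 2.0 * Ageo;
    double vmyo = 0.68 * vcell, vnsr = 0.0552 * vcell,
        vjsr = 0.0048 * vcell, vss = 0.02 * vcell;

    /* reversal potentials */
    double ENa = (Rgas * Temp / Frdy) * log(nao / nai);
    double EK = (Rgas * Temp / Frdy) * log(ko / ki);
    double EKs = (Rgas * Temp / Frdy) *
        log((ko + 0.01833 * nao) / (ki + 0.01833 * nai));

    double vw = v;
    if (fabs(vw) < 1e-6) vw = 1e-6;  /* avoid 0/0 in GHK fluxes */
    double vfrt = vw * Frdy / (Rgas * Temp);
    double vffrt = vw * Frdy * Frdy / (Rgas * Temp);

    /* CaMK */
    double KmCaMK = 0.15, aCaMK = 0.05, bCaMK = 0.00068, CaMKo = 0.05,
        KmCaM = 0.0015;
    double CaMKb = CaMKo * (1.0 - CaMKt) / (1.0 + KmCaM / cass);
    double CaMKa = CaMKb + CaMKt;
    ydot[38] = aCaMK * CaMKb * (CaMKb + CaMKt) - bCaMK * CaMKt;

    /* INa (fast) */
    double mss = 1.0 / (1.0 + exp((-(v + 39.57)) / 9.871));
    double tm = 1.0 / (6.765 * exp((v + 11.64) / 34.77) +
                       8.552 * exp(-(v + 77.42) / 5.955));
    ydot[9] = (mss - m) / tm;
    double hss = 1.0 / (1.0 + exp((v + 82.90) / 6.086));
    double thf = 1.0 / (1.432e-5 * exp(-(v + 1.196) / 6.285) +
                        6.149 * exp((v + 0.5096) / 20.27));
    double ths = 1.0 / (0.009794 * exp(-(v + 17.95) / 28.05) +
                        0.3343 * exp((v + 5.730) / 56.66));
    double Ahf = 0.99, Ahs = 1.0 - Ahf;
    ydot[10] = (hss - hf) / thf;
    ydot[11] = (hss - hs) / ths;
    double h = Ahf * hf + Ahs * hs;
    double jss = hss;
    double tj = 2.038 + 1.0 / (0.02136 * exp(-(v + 100.6) / 8.281) +
                               0.3052 * exp((v + 0.9941) / 38.45));
    ydot[12] = (jss - j) / tj;
    double hssp = 1.0 / (1.0 + exp((v + 89.1) / 6.086));
    double thsp = 3.0 * ths;
    ydot[13] = (hssp - hsp) / thsp;
    double hp = Ahf * hf + Ahs * hsp;
    double tjp = 1.46 * tj;
    ydot[14] = (jss - jp) / tjp;
    double GNa = 75.0;
    double fINap = 1.0 / (1.0 + KmCaMK / CaMKa);
    double INa = GNa * (v - ENa) * m * m * m *
        ((1.0 - fINap) * h * j + fINap * hp * jp);

    /* INaL */
    double mLss = 1.0 / (1.0 + exp((-(v + 42.85)) / 5.264));
    double tmL = tm;
    ydot[15] = (mLss - mL) / tmL;
    double hLss = 1.0 / (1.0 + exp((v + 87.61) / 7.488));
    double thL = 200.0;
    ydot[16] = (hLss - hL) / thL;
    double hLssp = 1.0 / (1.0 + exp((v + 93.81) / 7.488));
    double thLp = 3.0 * thL;
    ydot[17] = (hLssp - hLp) / thLp;
    double GNaL = 0.0075 * 2.661;
    if (celltype == 1) GNaL *= 0.6;
    double fINaLp = 1.0 / (1.0 + KmCaMK / CaMKa);
    double INaL = GNaL * (v - ENa) * mL *
        ((1.0 - fINaLp) * hL + fINaLp * hLp);

    /* Ito */
    double ass = 1.0 / (1.0 + exp((-(v - 14.34)) / 14.82));
    double ta = 1.0515 / (1.0 / (1.2089 * (1.0 + exp(-(v - 18.4099) / 29.3814)))
                          + 3.5 / (1.0 + exp((v + 100.0) / 29.3814)));
    ydot[18] = (ass - a) / ta;
    double iss = 1.0 / (1.0 + exp((v + 43.94) / 5.711));
    double delta_epi = (celltype == 1)
        ? 1.0 - 0.95 / (1.0 + exp((v + 70.0) / 5.0)) : 1.0;
    double tiF = 4.562 + 1.0 / (0.3933 * exp((-(v + 100.0)) / 100.0) +
                                0.08004 * exp((v + 50.0) / 16.59));
    double tiS = 23.62 + 1.0 / (0.001416 * exp((-(v + 96.52)) / 59.05) +
                                1.780e-8 * exp((v + 114.1) / 8.079));
    tiF *= delta_epi;
    tiS *= delta_epi;
    double AiF = 1.0 / (1.0 + exp((v - 213.6) / 151.2));
    double AiS = 1.0 - AiF;
    ydot[19] = (iss - iF) / tiF;
    ydot[20] = (iss - iS) / tiS;
    double i_gate = AiF * iF + AiS * iS;
    double assp = 1.0 / (1.0 + exp((-(v - 24.34)) / 14.82));
    ydot[21] = (assp - ap) / ta;
    double dti_develop = 1.354 + 1.0e-4 / (exp((v - 167.4) / 15.89) +
                                           exp(-(v - 12.23) / 0.2154));
    double dti_recover = 1.0 - 0.5 / (1.0 + exp((v + 70.0) / 20.0));
    double tiFp = dti_develop * dti_recover * tiF;
    double tiSp = dti_develop * dti_recover * tiS;
    ydot[22] = (iss - iFp) / tiFp;
    ydot[23] = (iss - iSp) / tiSp;
    double ip = AiF * iFp + AiS * iSp;
    double Gto = 0.02;
    if (celltype == 1 || celltype == 2) Gto *= 4.0;
    double fItop = 1.0 / (1.0 + KmCaMK / CaMKa);
    double Ito = Gto * (v - EK) *
        ((1.0 - fItop) * a * i_gate + fItop * ap * ip);

    /* ICaL / ICaNa / ICaK */
    double dss = 1.0 / (1.0 + exp((-(v + 3.940)) / 4.230));
    double td = 0.6 + 1.0 / (exp(-0.05 * (v + 6.0)) + exp(0.09 * (v + 14.0)));
    ydot[24] = (dss - d) / td;
    double fss = 1.0 / (1.0 + exp((v + 19.58) / 3.696));
    double tff = 7.0 + 1.0 / (0.0045 * exp(-(v + 20.0) / 10.0) +
                              0.0045 * exp((v + 20.0) / 10.0));
    double tfs = 1000.0 + 1.0 / (0.000035 * exp(-(v + 5.0) / 4.0) +
                                 0.000035 * exp((v + 5.0) / 6.0));
    double Aff = 0.6, Afs = 1.0 - Aff;
    ydot[25] = (fss - ff) / tff;
    ydot[26] = (fss - fs) / tfs;
    double f = Aff * ff + Afs * fs;
    double fcass = fss;
    double tfcaf = 7.0 + 1.0 / (0.04 * exp(-(v - 4.0) / 7.0) +
                                0.04 * exp((v - 4.0) / 7.0));
    double tfcas = 100.0 + 1.0 / (0.00012 * exp(-v / 3.0) +
                                  0.00012 * exp(v / 7.0));
    double Afcaf = 0.3 + 0.6 / (1.0 + exp((v - 10.0) / 10.0));
    double Afcas = 1.0 - Afcaf;
    ydot[27] = (fcass - fcaf) / tfcaf;
    ydot[28] = (fcass - fcas) / tfcas;
    double fca = Afcaf * fcaf + Afcas * fcas;
    double tjca = 75.0;
    ydot[29] = (fcass - jca) / tjca;
    double tffp = 2.5 * tff;
    ydot[31] = (fss - ffp) / tffp;
    double fp = Aff * ffp + Afs * fs;
    double tfcafp = 2.5 * tfcaf;
    ydot[32] = (fcass - fcafp) / tfcafp;
    double fcap = Afcaf * fcafp + Afcas * fcas;
    double Kmn = 0.002, k2n = 1000.0;
    double km2n = jca * 1.0;
    double anca = 1.0 / (k2n / km2n + pow(1.0 + Kmn / cass, 4.0));
    ydot[30] = anca * k2n - nca * km2n;
    double PhiCaL = 4.0 * vffrt * (cass * exp(2.0 * vfrt) - 0.341 * cao) /
        (exp(2.0 * vfrt) - 1.0);
    double PhiCaNa = 1.0 * vffrt * (0.75 * nass * exp(1.0 * vfrt) -
                                    0.75 * nao) / (exp(1.0 * vfrt) - 1.0);
    double PhiCaK = 1.0 * vffrt * (0.75 * kss * exp(1.0 * vfrt) -
                                   0.75 * ko) / (exp(1.0 * vfrt) - 1.0);
    double PCa = 0.0001 * 1.007;
    if (celltype == 1) PCa *= 1.2;
    if (celltype == 2) PCa *= 2.5;
    double PCap = 1.1 * PCa;
    double PCaNa = 0.00125 * PCa, PCaK = 3.574e-4 * PCa;
    double PCaNap = 0.00125 * PCap, PCaKp = 3.574e-4 * PCap;
    double fICaLp = 1.0 / (1.0 + KmCaMK / CaMKa);
    double ICaL = (1.0 - fICaLp) * PCa * PhiCaL * d *
        (f * (1.0 - nca) + jca * fca * nca) +
        fICaLp * PCap * PhiCaL * d * (fp * (1.0 - nca) + jca * fcap * nca);
    double ICaNa = (1.0 - fICaLp) * PCaNa * PhiCaNa * d *
        (f * (1.0 - nca) + jca * fca * nca) +
        fICaLp * PCaNap * PhiCaNa * d * (fp * (1.0 - nca) + jca * fcap * nca);
    double ICaK = (1.0 - fICaLp) * PCaK * PhiCaK * d *
        (f * (1.0 - nca) + jca * fca * nca) +
        fICaLp * PCaKp * PhiCaK * d * (fp * (1.0 - nca) + jca * fcap * nca);

    /* IKr: hERG Markov scheme, drug-free.
     * Rows C1-C2-O (closed/open) and IC1-IC2-IO (inactivated), vertical
     * edges C1/IC1 (A51,A61), C2/IC2 (A52,A62), O/IO (A53,A63). */
    double a11 = hA11 * exp(hB11 * v) * qfac(hq11);   /* C1  -> C2 */
    double b11 = hA21 * exp(hB21 * v) * qfac(hq21);   /* C2  -> C1 */
    double a31 = hA31 * exp(hB31 * v) * qfac(hq31);   /* C2  -> O  */
    double b31 = hA41 * exp(hB41 * v) * qfac(hq41);   /* O   -> C2 */
    double a1 = hA1 * exp(hB1 * v) * qfac(hq1);       /* IC1 -> IC2 */
    double b1 = hA2 * exp(hB2 * v) * qfac(hq2);       /* IC2 -> IC1 */
    double a3 = hA3 * exp(hB3 * v) * qfac(hq3);       /* IC2 -> IO */
    double b3 = hA4 * exp(hB4 * v) * qfac(hq4);       /* IO  -> IC2 */
    double a51 = hA51 * exp(hB51 * v) * qfac(hq51);   /* C1  -> IC1 */
    double b51 = hA61 * exp(hB61 * v) * qfac(hq61);   /* IC1 -> C1 */
    double a52 = hA52 * exp(hB52 * v) * qfac(hq52);   /* C2  -> IC2 */
    double b52 = hA62 * exp(hB62 * v) * qfac(hq62);   /* IC2 -> C2 */
    double a53 = hA53 * exp(hB53 * v) * qfac(hq53);   /* O   -> IO */
    double b53 = hA63 * exp(hB63 * v) * qfac(hq63);   /* IO  -> O  */

    ydot[39] = -(a1 * hIC1 - b1 * hIC2) + (a51 * hC1 - b51 * hIC1);
    ydot[40] = (a1 * hIC1 - b1 * hIC2) - (a3 * hIC2 - b3 * hIO) +
        (a52 * hC2 - b52 * hIC2);
    ydot[41] = -(a11 * hC1 - b11 * hC2) - (a51 * hC1 - b51 * hIC1);
    ydot[42] = (a11 * hC1 - b11 * hC2) - (a31 * hC2 - b31 * hO) -
        (a52 * hC2 - b52 * hIC2);
    ydot[43] = (a31 * hC2 - b31 * hO) - (a53 * hO - b53 * hIO);
    ydot[44] = (a3 * hIC2 - b3 * hIO) + (a53 * hO - b53 * hIO);

    double GKr = 4.65854545454545618e-2;
    if (celltype == 1) GKr *= 1.3;
    if (celltype == 2) GKr *= 0.8;
    double IKr = GKr * sqrt(ko / 5.4) * hO * (v - EK);

    /* IKs (with the CaM block hook as a plain multiplier) */
    double xs1ss = 1.0 / (1.0 + exp((-(v + 11.60)) / 8.932));
    double txs1 = 817.3 + 1.0 / (2.326e-4 * exp((v + 48.28) / 17.80) +
                                 0.001292 * exp((-(v + 210.0)) / 230.0));
    ydot[33] = (xs1ss - xs1) / txs1;
    double xs2ss = xs1ss;
    double txs2 = 1.0 / (0.01 * exp((v - 50.0) / 20.0) +
                         0.0193 * exp((-(v + 66.54)) / 31.0));
    ydot[34] = (xs2ss - xs2) / txs2;
    double KsCa = 1.0 + 0.6 / (1.0 + pow(3.8e-5 / cai, 1.4));
    double GKs = 0.0034 * 1.87;
    if (celltype == 1) GKs *= 1.4;
    double IKs = iks_scale * GKs * KsCa * xs1 * xs2 * (v - EKs);

    /* IK1 */
    double xk1ss = 1.0 / (1.0 + exp(-(v + 2.5538 * ko + 144.59) /
                                    (1.5692 * ko + 3.8115)));
    double txk1 = 122.2 / (exp((-(v + 127.2)) / 20.36) +
                           exp((v + 236.8) / 69.33));
    ydot[35] = (xk1ss - xk1) / txk1;
    double rk1 = 1.0 / (1.0 + exp((v + 105.8 - 2.6 * ko) / 9.493));
    double GK1 = 0.1908 * 1.698;
    if (celltype == 1) GK1 *= 1.2;
    if (celltype == 2) GK1 *= 1.3;
    double IK1 = GK1 * sqrt(ko) * rk1 * xk1 * (v - EK);

    /* INaCa (myoplasmic and subspace components) */
    double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5;
    double wna = 6.0e4, wca = 6.0e4, wnaca = 5.0e3;
    double kcaon = 1.5e6, kcaoff = 5.0e3;
    double qna = 0.5224, qca = 0.1670;
    double hca = exp(qca * v * Frdy / (Rgas * Temp));
    double hna = exp(qna * v * Frdy / (Rgas * Temp));
    double zca = 2.0, zna = 1.0, zk = 1.0;
    double Gncx = 0.0008;
    if (celltype == 1) Gncx *= 1.1;
    if (celltype == 2) Gncx *= 1.4;
    double KmCaAct = 150.0e-6;

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
        double k1 = h12 * cao * kcaon;
        double k2 = kcaoff;
        double k3p = h9 * wca;
        double k3pp = h8 * wnaca;
        double k3 = k3p + k3pp;
        double k4p = h3 * wca / hca;
        double k4pp = h2 * wnaca;
        double k4 = k4p + k4pp;
        double k5 = kcaoff;
        double k6 = h6 * cai * kcaon;
        double k7 = h5 * h2 * wna;
        double k8 = h8 * h11 * wna;
        double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
        double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
        double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
        double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
        double E1 = x1 / (x1 + x2 + x3 + x4);
        double E2 = x2 / (x1 + x2 + x3 + x4);
        double E3 = x3 / (x1 + x2 + x3 + x4);
        double E4 = x4 / (x1 + x2 + x3 + x4);
        double allo = 1.0 / (1.0 + pow(KmCaAct / cai, 2.0));
        double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
        double JncxCa = E2 * k2 - E1 * k1;
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
        double k1 = h12 * cao * kcaon;
        double k2 = kcaoff;
        double k3p = h9 * wca;
        double k3pp = h8 * wnaca;
        double k3 = k3p + k3pp;
        double k4p = h3 * wca / hca;
        double k4pp = h2 * wnaca;
        double k4 = k4p + k4pp;
        double k5 = kcaoff;
        double k6 = h6 * cass * kcaon;
        double k7 = h5 * h2 * wna;
        double k8 = h8 * h11 * wna;
        double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
        double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
        double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
        double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
        double E1 = x1 / (x1 + x2 + x3 + x4);
        double E2 = x2 / (x1 + x2 + x3 + x4);
        double E3 = x3 / (x1 + x2 + x3 + x4);
        double E4 = x4 / (x1 + x2 + x3 + x4);
        double allo = 1.0 / (1.0 + pow(KmCaAct / cass, 2.0));
        double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
        double JncxCa = E2 * k2 - E1 * k1;
        INaCa_ss = 0.2 * Gncx * allo * (zna * JncxNa + zca * JncxCa);
    }

    /* INaK (Smith-Crampin scheme) */
    double INaK;
    {
        double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4;
        double k3p = 1899.0, k3m = 79300.0, k4p = 639.0, k4m = 40.0;
        double Knai0 = 9.073, Knao0 = 27.78, delta = -0.1550;
        double Knai = Knai0 * exp(delta * v * Frdy / (3.0 * Rgas * Temp));
        double Knao = Knao0 * exp((1.0 - delta) * v * Frdy /
                                  (3.0 * Rgas * Temp));
        double Kki = 0.5, Kko = 0.3582, MgADP = 0.05, MgATP = 9.8;
        double Kmgatp = 1.698e-7, H = 1.0e-7, eP = 4.2, Khp = 1.698e-7;
        double Knap = 224.0, Kxkur = 292.0;
        double P = eP / (1.0 + H / Khp + nai / Knap + ki / Kxkur);
        double a1 = (k1p * pow(nai / Knai, 3.0)) /
            (pow(1.0 + nai / Knai, 3.0) + pow(1.0 + ki / Kki, 2.0) - 1.0);
        double b1 = k1m * MgADP;
        double a2 = k2p;
        double b2 = (k2m * pow(nao / Knao, 3.0)) /
            (pow(1.0 + nao / Knao, 3.0) + pow(1.0 + ko / Kko, 2.0) - 1.0);
        double a3 = (k3p * pow(ko / Kko, 2.0)) /
            (pow(1.0 + nao / Knao, 3.0) + pow(1.0 + ko / Kko, 2.0) - 1.0);
        double b3 = (k3m * P * H) / (1.0 + MgATP / Kmgatp);
        double a4 = (k4p * MgATP / Kmgatp) / (1.0 + MgATP / Kmgatp);
        double b4 = (k4m * pow(ki / Kki, 2.0)) /
            (pow(1.0 + nao / Knao, 3.0) + pow(1.0 + ki / Kki, 2.0) - 1.0);
        double x1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
        double x2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
        double x3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
        double x4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b2 * a1;
        double E1 = x1 / (x1 + x2 + x3 + x4);
        double E2 = x2 / (x1 + x2 + x3 + x4);
        double E3 = x3 / (x1 + x2 + x3 + x4);
        double E4 = x4 / (x1 + x2 + x3 + x4);
        double JnakNa = 3.0 * (E1 * a3 - E2 * b3);
        double JnakK = 2.0 * (E4 * b1 - E3 * a1);
        double Pnak = 30.0;
        if (celltype == 1) Pnak *= 0.9;
        if (celltype == 2) Pnak *= 0.7;
        INaK = Pnak * (zna * JnakNa + zk * JnakK);
    }

    /* background and pump currents */
    double xkb = 1.0 / (1.0 + exp(-(v - 14.48) / 18.34));
    double GKb = 0.003;
    if (celltype == 1) GKb *= 0.6;
    double IKb = GKb * xkb * (v - EK);
    double PNab = 3.75e-10;
    double INab = PNab * vffrt * (nai * exp(vfrt) - nao) / (exp(vfrt) - 1.0);
    double PCab = 2.5e-8;
    double ICab = PCab * 4.0 * vffrt * (cai * exp(2.0 * vfrt) - 0.341 * cao) /
        (exp(2.0 * vfrt) - 1.0);
    double GpCa = 0.0005;
    double IpCa = GpCa * cai / (0.0005 + cai);

    /* stimulus */
    double Istim = (t >= stim_start && t < stim_start + stim_dur)
        ? stim_amp : 0.0;

    /* membrane potential */
    ydot[0] = -(INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs + IK1 +
                INaCa_i + INaCa_ss + INaK + INab + IKb + IpCa + ICab + Istim);

    /* diffusion fluxes */
    double JdiffNa = (nass - nai) / 2.0;
    double JdiffK = (kss - ki) / 2.0;
    double Jdiff = (cass - cai) / 0.2;

    /* SR calcium release */
    double bt = 4.75, a_rel = 0.5 * bt;
    double Jrel_inf = a_rel * (-ICaL) / (1.0 + pow(1.5 / cajsr, 8.0));
    if (celltype == 2) Jrel_inf *= 1.7;
    double tau_rel = bt / (1.0 + 0.0123 / cajsr);
    if (tau_rel < 0.001) tau_rel = 0.001;
    ydot[36] = (Jrel_inf - Jrelnp) / tau_rel;
    double btp = 1.25 * bt, a_relp = 0.5 * btp;
    double Jrel_infp = a_relp * (-ICaL) / (1.0 + pow(1.5 / cajsr, 8.0));
    if (celltype == 2) Jrel_infp *= 1.7;
    double tau_relp = btp / (1.0 + 0.0123 / cajsr);
    if (tau_relp < 0.001) tau_relp = 0.001;
    ydot[37] = (Jrel_infp - Jrelp) / tau_relp;
    double fJrelp = 1.0 / (1.0 + KmCaMK / CaMKa);
    double Jrel = (1.0 - fJrelp) * Jrelnp + fJrelp * Jrelp;

    /* SR calcium uptake and translocation */
    double Jupnp = 0.004375 * cai / (cai + 0.00092);
    double Jupp = 2.75 * 0.004375 * cai / (cai + 0.00092 - 0.00017);
    if (celltype == 1) {
        Jupnp *= 1.3;
        Jupp *= 1.3;
    }
    double fJupp = 1.0 / (1.0 + KmCaMK / CaMKa);
    double Jleak = 0.0039375 * cansr / 15.0;
    double Jup = (1.0 - fJupp) * Jupnp + fJupp * Jupp - Jleak;
    double Jtr = (cansr - cajsr) / 100.0;

    /* intracellular concentrations with instantaneous buffering */
    double cmdnmax = 0.05;
    if (celltype == 1) cmdnmax *= 1.3;
    double kmcmdn = 0.00238, trpnmax = 0.07, kmtrpn = 0.0005;
    double BSRmax = 0.047, KmBSR = 0.00087;
    double BSLmax = 1.124, KmBSL = 0.0087;
    double csqnmax = 10.0, kmcsqn = 0.8;

    ydot[1] = -(INa + INaL + 3.0 * INaCa_i + 3.0 * INaK + INab) *
        Acap / (Frdy * vmyo) + JdiffNa * vss / vmyo;
    ydot[2] = -(ICaNa + 3.0 * INaCa_ss) * Acap / (Frdy * vss) - JdiffNa;
    ydot[3] = -(Ito + IKr + IKs + IK1 + IKb + Istim - 2.0 * INaK) *
        Acap / (Frdy * vmyo) + JdiffK * vss / vmyo;
    ydot[4] = -ICaK * Acap / (Frdy * vss) - JdiffK;
    double Bcai = 1.0 / (1.0 + cmdnmax * kmcmdn / pow(kmcmdn + cai, 2.0) +
                         trpnmax * kmtrpn / pow(kmtrpn + cai, 2.0));
    ydot[5] = Bcai * (-(IpCa + ICab - 2.0 * INaCa_i) *
                      Acap / (2.0 * Frdy * vmyo) -
                      Jup * vnsr / vmyo + Jdiff * vss / vmyo);
    double Bcass = 1.0 / (1.0 + BSRmax * KmBSR / pow(KmBSR + cass, 2.0) +
                          BSLmax * KmBSL / pow(KmBSL + cass, 2.0));
    ydot[6] = Bcass * (-(ICaL - 2.0 * INaCa_ss) * Acap / (2.0 * Frdy * vss) +
                       Jrel * vjsr / vss - Jdiff);
    ydot[7] = Jup - Jtr * vjsr / vnsr;
    double Bcajsr = 1.0 / (1.0 + csqnmax * kmcsqn / pow(kmcsqn + cajsr, 2.0));
    ydot[8] = Bcajsr * (Jtr - Jrel);

    if (out != NULL) {
        out[0] = IKs;
        out[1] = IKr;
        out[2] = ICaL;
        out[3] = INaCa_i + INaCa_ss;
        out[4] = INaK;
        out[5] = Ito;
        out[6] = IK1;
        out[7] = INa;
        out[8] = INaL;
        out[9] = Istim;
    }
}

/* deSolve entry point */
void ord_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    if (ip[0] < N_OUT) error("nout should be at least %d", N_OUT);
    ord_rhs(*t, y, ydot, parms, yout);
}

/* single evaluation from R: returns c(derivatives, currents) */
SEXP ord_rhs_call(SEXP state, SEXP params, SEXP time)
{
    if (LENGTH(state) != N_STATE)
        error("state must have %d elements", N_STATE);
    if (LENGTH(params) != N_PARMS)
        error("params must have %d elements", N_PARMS);
    SEXP ans = PROTECT(allocVector(REALSXP, N_STATE + N_OUT));
    double out[N_OUT];
    ord_rhs(REAL(time)[0], REAL(state), REAL(ans), REAL(params), out);
    for (int i = 0; i < N_OUT; i++) REAL(ans)[N_STATE + i] = out[i];
    UNPROTECT(1);
    return ans;
}
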