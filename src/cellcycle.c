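/* Compiled right-hand side and event root function for the hybrid
 * cell-cycle model, in deSolve's compiled-model convention.  Must stay
 * term-for-term identical to the R reference implementation (caulo_rhs);
 * the test suite asserts agreement along trajectories.
 *
 * Parameter vector layout (see rhs_parm_vector() on the R side): the 62
 * kinetic constants used by the RHS in a fixed order, followed by the
 * runtime segment state: ks_Zring, plec_t0, qssa flag, and the five event
 * thresholds + armed flags for the root function.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_PARMS 77

static double parms[N_PARMS];

#define ks_Ini        parms[0]
#define k_elong       parms[1]
#define P_elong       parms[2]
#define km_Cori       parms[3]
#define km_ccrM       parms[4]
#define km_ctrA       parms[5]
#define Ja_Ini        parms[6]
#define Ji_Ini        parms[7]
#define Jm_Cori       parms[8]
#define Jm_ccrM       parms[9]
#define Jm_ctrA       parms[10]
#define Theta_CtrA    parms[11]
#define Theta_DnaA    parms[12]
#define Theta_Cori    parms[13]
#define ks_IccrM      parms[14]
#define kd_IccrM      parms[15]
#define ks_ccrM       parms[16]
#define kd_ccrM       parms[17]
#define ks_dnaA       parms[18]
#define kd_dnaA       parms[19]
#define ks_gcrA       parms[20]
#define kd_gcrA       parms[21]
#define ks1_ctrA      parms[22]
#define ks2_ctrA      parms[23]
#define kd_ctrA       parms[24]
#define ks_sciP       parms[25]
#define kd_sciP       parms[26]
#define Ja_ccrM_CtrA  parms[27]
#define Ji_ccrM_SciP  parms[28]
#define Ji_dnaA_GcrA  parms[29]
#define Ja_gcrA_DnaA  parms[30]
#define Ji_gcrA_CtrA  parms[31]
#define Ja_ctrA_CtrA  parms[32]
#define Ja_ctrA_GcrA  parms[33]
#define Ji_ctrA_CtrA  parms[34]
#define Ji_ctrA_SciP  parms[35]
#define Ja_sciP_CtrA  parms[36]
#define ks_CcrM       parms[37]
#define kd_CcrM       parms[38]
#define ks_DnaA       parms[39]
#define kd_DnaA       parms[40]
#define ks_GcrA       parms[41]
#define kd_GcrA       parms[42]
#define ks_SciP       parms[43]
#define kd_SciP       parms[44]
#define ks_CtrA       parms[45]
#define kd_CtrA       parms[46]
#define kd_CtrA_ClpXP parms[47]
#define Jd_CtrA_ClpXP parms[48]
#define kpho_CtrA     parms[49]
#define kdepho_CtrA   parms[50]
#define kpho_CckA     parms[51]
#define kdepho_CckA   parms[52]
#define k1_plus       parms[53]
#define k1_minus      parms[54]
#define k2_plus       parms[55]
#define k2_minus      parms[56]
#define k3_plus       parms[57]
#define k3_minus      parms[58]
#define kphos_PleD    parms[59]
#define kdephos_PleD  parms[60]
#define ks_CpdR       parms[61]
#define kd_CpdR       parms[62]
#define kphos_CpdR    parms[63]
#define kdephos_CpdR  parms[64]
#define ks_RcdA       parms[65]
#define kd_RcdA       parms[66]
#define ks_cdG        parms[67]
#define kd_cdG        parms[68]
#define ks_PleD       parms[69]
#define kd_PleD       parms[70]
#define ks_PdeA       parms[71]
#define kd_PdeA       parms[72]
#define Ja_CpdR_CtrA  parms[73]
#define Jd_CpdR       parms[74]
#define Ja_RcdA_CtrA  parms[75]
#define Jd_RcdA       parms[76]

/* second block, appended after the kinetic constants */
#define NK 77
static double parms2[22];
#define Ja_PdeA_CtrA  parms2[0]
#define Jd_PdeA       parms2[1]
#define Ja_PleD_CtrA  parms2[2]
#define Ji_cdG_cdG    parms2[3]
#define CckA_T        parms2[4]
#define ClpXP_pool    parms2[5]
#define alpha_PdeA    parms2[6]
#define alpha_PleD    parms2[7]
#define alpha_cdG     parms2[8]
#define plec_A1       parms2[9]
#define plec_w        parms2[10]
#define plec_phi1     parms2[11]
#define plec_A2       parms2[12]
#define plec_phi2     parms2[13]
#define ks_Zring_cur  parms2[14]
#define plec_t0       parms2[15]
#define qssa_flag     parms2[16]
#define thr_Ini       parms2[17]   /* = P_elong */
#define thr_ccrM      parms2[18]
#define thr_ctrA      parms2[19]
#define thr_term      parms2[20]
#define thr_zring     parms2[21]

static double armed[5];

void caulo_initmod(void (*odeparms)(int *, double *)) {
  int n = NK + 22 + 5;
  double all[NK + 22 + 5];
  odeparms(&n, all);
  for (int i = 0; i < NK; i++) parms[i] = all[i];
  for (int i = 0; i < 22; i++) parms2[i] = all[NK + i];
  for (int i = 0; i < 5; i++) armed[i] = all[NK + 22 + i];
}

static double sq(double x) { return x * x; }
static double p4(double x) { double s = x * x; return s * s; }

void caulo_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip) {
  double v[29];
  for (int i = 0; i < 29; i++) {
    double yi = y[i];
    if (yi < 0) {
      if (yi < -1e-6)
        error("negative state in integration (index %d, value %g)", i + 1, yi);
      yi = 0;
    }
    v[i] = yi;
  }
  double Ini = v[0], Elong = v[1];
  double hCori = v[3], hccrM = v[4], hctrA = v[5];
  double IccrM = v[6], mccrM = v[7], mdnaA = v[8], mgcrA = v[9],
         msciP = v[10], mctrA = v[11];
  double CcrM = v[12], DnaA = v[13], GcrA = v[14], SciP = v[15];
  double CtrA = v[16], CtrAP = v[17], CckAP = v[18];
  double Complex1 = v[19], CpdR = v[20], CpdRP = v[21], Complex2 = v[22],
         RcdA = v[23], Complex3 = v[24];
  double PleD = v[25], PleDP = v[26], PdeA = v[27], cdG = v[28];

  double ts = plec_w * (*t - plec_t0);
  double PleC = plec_A1 * sin(ts + plec_phi1) + plec_A2 * sin(ts + plec_phi2);
  if (PleC < 0) PleC = 0;

  double CtrAP2 = sq(CtrAP), CtrAP4 = sq(CtrAP2);
  double rD = p4(DnaA / Theta_DnaA), rC = p4(CtrAP / Theta_CtrA);
  double CcrM4 = p4(CcrM), cdG2 = sq(cdG);

  ydot[0] = ks_Ini * rD / (p4(Ja_Ini) + rC + rD) *
            (1 + 1 / (p4(Ji_Ini) + p4(hCori / Theta_Cori)));
  double El4 = p4(Elong);
  ydot[1] = k_elong * El4 / (El4 + p4(P_elong));
  ydot[2] = ks_Zring_cur;
  ydot[3] = -km_Cori * CcrM4 / (p4(Jm_Cori) + CcrM4) * hCori;
  ydot[4] = -km_ccrM * CcrM4 / (p4(Jm_ccrM) + CcrM4) * hccrM;
  ydot[5] = -km_ctrA * CcrM4 / (p4(Jm_ctrA) + CcrM4) * hctrA;

  ydot[6] = ks_IccrM * (CtrAP2 / (sq(Ja_ccrM_CtrA) + CtrAP2)) *
            (sq(Ji_ccrM_SciP) / (sq(Ji_ccrM_SciP) + sq(SciP))) * hccrM -
            kd_IccrM * IccrM;
  ydot[7] = ks_ccrM * IccrM - kd_ccrM * mccrM;
  ydot[8] = ks_dnaA * (sq(Ji_dnaA_GcrA) / (sq(Ji_dnaA_GcrA) + sq(GcrA))) *
            (2 - hCori) - kd_dnaA * mdnaA;
  ydot[9] = ks_gcrA * (sq(DnaA) / (sq(Ja_gcrA_DnaA) + sq(DnaA))) *
            (sq(Ji_gcrA_CtrA) / (sq(Ji_gcrA_CtrA) + CtrAP2)) -
            kd_gcrA * mgcrA;
  ydot[10] = ks_sciP * CtrAP2 / (sq(Ja_sciP_CtrA) + CtrAP2) - kd_sciP * msciP;
  ydot[11] = ks1_ctrA * (sq(GcrA) / (sq(Ja_ctrA_GcrA) + sq(GcrA))) *
             (p4(Ji_ctrA_CtrA) / (p4(Ji_ctrA_CtrA) + CtrAP4)) *
             (p4(Ji_ctrA_SciP) / (p4(Ji_ctrA_SciP) + p4(SciP))) * hctrA +
             ks2_ctrA * CtrAP2 / (sq(Ja_ctrA_CtrA) + CtrAP2) -
             kd_ctrA * mctrA;

  ydot[12] = ks_CcrM * mccrM - kd_CcrM * CcrM;
  ydot[13] = ks_DnaA * mdnaA - kd_DnaA * DnaA;
  ydot[14] = ks_GcrA * mgcrA - kd_GcrA * GcrA;
  ydot[15] = ks_SciP * msciP - kd_SciP * SciP;

  double C3 = qssa_flag != 0 ? k3_plus * cdG2 * Complex2 / k3_minus : Complex3;
  double degC = kd_CtrA + kd_CtrA_ClpXP * sq(C3) / (sq(Jd_CtrA_ClpXP) + sq(C3));
  double pho = kpho_CtrA * CckAP * CtrA;
  double depho = kdepho_CtrA * CtrAP;
  ydot[16] = ks_CtrA * mctrA - degC * CtrA - pho + depho;
  ydot[17] = -degC * CtrAP + pho - depho;

  ydot[18] = kpho_CckA * (CckA_T - CckAP) -
             kdepho_CckA * (1 + alpha_cdG * cdG) * CckAP;
  double c1frac = Complex1 / (Jd_CpdR + Complex1);
  ydot[19] = k1_plus * ClpXP_pool * CpdR - k1_minus * Complex1 -
             k2_plus * Complex1 * RcdA + k2_minus * Complex2;
  ydot[20] = ks_CpdR * CtrAP2 / (sq(Ja_CpdR_CtrA) + CtrAP2) -
             kd_CpdR * CpdR * c1frac + k1_minus * Complex1 -
             k1_plus * ClpXP_pool * CpdR + kdephos_CpdR * CpdRP -
             kphos_CpdR * CckAP * CpdR;
  ydot[21] = -kd_CpdR * CpdRP * c1frac + kphos_CpdR * CckAP * CpdR -
             kdephos_CpdR * CpdRP;
  ydot[22] = k2_plus * Complex1 * RcdA - k2_minus * Complex2 +
             (qssa_flag != 0 ? 0
                             : k3_minus * Complex3 -
                               k3_plus * cdG2 * Complex2);
  ydot[23] = ks_RcdA * CtrAP2 / (sq(Ja_RcdA_CtrA) + CtrAP2) -
             kd_RcdA * RcdA * Complex1 / (Jd_RcdA + Complex1);
  ydot[24] = qssa_flag != 0 ? 0
                            : k3_plus * cdG2 * Complex2 - k3_minus * Complex3;
  ydot[25] = ks_PleD * CtrAP2 / (sq(Ja_PleD_CtrA) + CtrAP2) -
             kd_PleD * PleD - kphos_PleD * PleD +
             kdephos_PleD * PleC * PleDP;
  ydot[26] = kphos_PleD * PleD - kdephos_PleD * PleC * PleDP;
  ydot[27] = ks_PdeA * CtrAP2 / (sq(Ja_PdeA_CtrA) + CtrAP2) -
             kd_PdeA * PdeA * Complex1 / (Jd_PdeA + Complex1);
  ydot[28] = ks_cdG * (1 + alpha_PleD * PleD) * sq(Ji_cdG_cdG) /
               (sq(Ji_cdG_cdG) + cdG2) -
             kd_cdG * (1 + alpha_PdeA * PdeA) * cdG +
             (qssa_flag != 0 ? 0
                             : k3_minus * Complex3 -
                               k3_plus * cdG2 * Complex2);
}

/* upward-crossing event roots, masked by the armed flags */
void caulo_root(int *neq, double *t, double *y, int *ng, double *gout,
                double *out, int *ip) {
  gout[0] = armed[0] != 0 ? y[0] - thr_Ini   : 1.0;
  gout[1] = armed[1] != 0 ? y[1] - thr_ccrM  : 1.0;
  gout[2] = armed[2] != 0 ? y[1] - thr_ctrA  : 1.0;
  gout[3] = armed[3] != 0 ? y[1] - thr_term  : 1.0;
  gout[4] = armed[4] != 0 ? y[2] - thr_zring : 1.0;
}
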