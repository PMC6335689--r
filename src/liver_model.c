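/* Compiled right-hand side of the 11-variable liver regeneration model,
 * in the deSolve compiled-code calling convention.
 *
 * Parameter vector layout (42 doubles), kept in lockstep with
 * hep_pack_parms() on the R side:
 *   [0..32]  the 33 tunable parameters in canonical order (see R/parameters.R)
 *   [33]     eps   (senescent functional fraction)
 *   [34]     N_SS  (pre-resection non-senescent mass)
 *   [35..41] k1..k7 homeostatic flux constants (precomputed in R)
 *
 * State vector: Q, P, R, IL6, JAK, STAT3, SOCS3, IE, GF, ECM, G.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

static double parms[42];

#define M_        parms[0]
#define k_IL6     parms[1]
#define kap_IL6   parms[2]
#define V_JAK     parms[3]
#define KM_JAK    parms[4]
#define kap_JAK   parms[5]
#define proSTAT3  parms[6]
#define V_ST3     parms[7]
#define KM_ST3    parms[8]
#define kap_ST3   parms[9]
#define V_SOCS3   parms[10]
#define KM_SOCS3  parms[11]
#define kap_SOCS3 parms[12]
#define KI_SOCS3  parms[13]
#define V_IE      parms[14]
#define KM_IE     parms[15]
#define kap_IE    parms[16]
#define k_deg     parms[17]
#define kap_ECM   parms[18]
#define k_GF      parms[19]
#define kap_GF    parms[20]
#define k_up      parms[21]
#define k_QP      parms[22]
#define k_PR      parms[23]
#define k_RQ      parms[24]
#define k_prol    parms[25]
#define k_req     parms[26]
#define th_req    parms[27]
#define be_req    parms[28]
#define k_ap      parms[29]
#define th_ap     parms[30]
#define be_ap     parms[31]
#define k_G       parms[32]
#define EPS_      parms[33]
#define K1        parms[35]
#define K2        parms[36]
#define K3        parms[37]
#define K4        parms[38]
#define K5        parms[39]
#define K6        parms[40]
#define K7        parms[41]

/* tanh with the argument clipped at +/-50; indistinguishable from tanh at
 * double precision but immune to platform quirks for huge arguments */
static double tanh_clip(double x)
{
    if (x > 50.0) x = 50.0;
    else if (x < -50.0) x = -50.0;
    return tanh(x);
}

void liver_init(void (*odeparms)(int *, double *))
{
    int n = 42;
    odeparms(&n, parms);
}

void liver_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double Q = y[0], P = y[1], R = y[2];
    double IL6 = y[3], JAK = y[4], ST3 = y[5], SOCS3 = y[6];
    double IE = y[7], GF = y[8], ECM = y[9], G = y[10];

    double N    = Q + G * (P + R);
    double load = M_ / (N + EPS_);
    double sap  = 0.5 * (1.0 + tanh_clip((th_ap - (N + EPS_) / M_) / be_ap));
    double sreq = 0.5 * (1.0 + tanh_clip((th_req - GF) / be_req));
    double pro2 = proSTAT3 * proSTAT3;

    /* cellular state transitions */
    ydot[0] = -k_QP * (IE - 1.0) * Q + k_RQ * ECM * R + k_req * sreq * P
              - k_ap * sap * Q;
    ydot[1] =  k_QP * (IE - 1.0) * Q - k_PR * (GF - 1.0) * P
              - k_req * sreq * P - k_ap * sap * P;
    ydot[2] =  k_PR * (GF - 1.0) * P - k_RQ * ECM * R + k_prol * R
              - k_ap * sap * R;

    /* molecular species */
    ydot[3] = k_IL6 * load - V_JAK * IL6 / (IL6 + KM_JAK) - kap_IL6 * IL6 + K1;
    ydot[4] = V_JAK * IL6 / (IL6 + KM_JAK) - kap_JAK * JAK + K2;
    ydot[5] = V_ST3 * JAK * pro2 / (pro2 + KM_ST3 * (1.0 + SOCS3 / KI_SOCS3))
              - V_IE * ST3 / (ST3 + KM_IE)
              - V_SOCS3 * ST3 / (ST3 + KM_SOCS3)
              - kap_ST3 * ST3 + K3;
    ydot[6] = V_SOCS3 * ST3 / (ST3 + KM_SOCS3) - kap_SOCS3 * SOCS3 + K4;
    ydot[7] = V_IE * ST3 / (ST3 + KM_IE) - kap_IE * IE + K5;
    ydot[8] = k_GF * load - k_up * GF * ECM - kap_GF * GF + K7;
    ydot[9] = -k_deg * IL6 * ECM - kap_ECM * ECM + K6;

    /* relative cell mass (hypertrophy) */
    ydot[10] = k_G * load - k_G * M_;
}

static const R_CMethodDef CEntries[] = {
    {"liver_init",   (DL_FUNC) &liver_init,   1},
    {"liver_derivs", (DL_FUNC) &liver_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_hepregen(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
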