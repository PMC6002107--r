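/* Four-state respiratory mechanics RHS for deSolve's compiled-model
 * interface.  States: total airflow [L/s], collapsible-airway volume [ml],
 * lung elastic recoil pressure [cm H2O], viscoelastic pressure [cm H2O].
 * Volumes are in ml, flows in L/s, resistances in cm H2O.s/L, so volume
 * derivatives carry a factor 1000.  Must mirror resp_rhs() in R/breath.R.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_PARMS 27
static double parms[N_PARMS];
#define TLC   parms[0]
#define RV    parms[1]
#define VC    parms[2]
#define KLUNG parms[3]
#define ALPHA parms[4]
#define GAMMA parms[5]
#define CF    parms[6]
#define DF    parms[7]
#define CWTR  parms[8]   /* chest-wall transition point c_w */
#define DW    parms[9]
#define BW    parms[10]
#define CC    parms[11]
#define DC    parms[12]
#define KC    parms[13]
#define VCMAX parms[14]
#define RSM   parms[15]
#define RSD   parms[16]
#define KS    parms[17]
#define IU    parms[18]
#define RUM   parms[19]
#define KU    parms[20]
#define BRAKE parms[21]  /* expiratory R_u multiplier, >= 1 */
#define CVE   parms[22]
#define RVE   parms[23]
#define PAO   parms[24]
#define AMUS  parms[25]
#define FREQ  parms[26]

void resp_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void resp_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double flow = y[0], Vc = y[1], Pel = y[2], Pve = y[3];

    /* lung curve: V_A = VC (1 - e^{-k P_el}) F_rec(P_el) + RV */
    double efr  = exp(-(Pel - CF)/DF);
    double frec = ALPHA + (GAMMA - ALPHA)/(1.0 + efr);
    double ekp  = exp(-KLUNG*Pel);
    double VA   = VC*(1.0 - ekp)*frec + RV;
    double dfr  = (GAMMA - ALPHA)*efr/(DF*(1.0 + efr)*(1.0 + efr));
    double CA   = VC*KLUNG*ekp*frec + VC*(1.0 - ekp)*dfr;

    /* chest wall: inverse softplus, guarded just above RV */
    double Vcw = VA + Vc;
    double x   = Vcw - RV;
    if (x < 1e-9) x = 1e-9;
    double Pcw  = DW*log(expm1(x/BW)) + CWTR;
    double Pmus = AMUS*cos(2.0*M_PI*FREQ*(*t)) - AMUS;
    double Ppl  = Pcw + Pmus;

    /* collapsible segment: inverse sigmoid, V_c clamped into its range */
    double Vcc = Vc;
    if (Vcc < 1e-6) Vcc = 1e-6;
    if (Vcc > VCMAX - 1e-6) Vcc = VCMAX - 1e-6;
    double Ptm = CC - DC*log(VCMAX/Vcc - 1.0);

    double Rs    = RSD*exp(KS*(VA - RV)/(TLC - RV)) + RSM;
    double flowA = (Ptm - Pel - Pve)/Rs;              /* L/s */

    double r  = VCMAX/Vcc;
    double Pu = Ptm + Ppl + KC*r*r*flow;
    double m  = (flow < 0.0) ? BRAKE : 1.0;
    double Ru = m*(RUM + KU*fabs(flow));

    ydot[0] = (PAO - Pu - Ru*flow)/IU;
    ydot[1] = 1000.0*(flow - flowA);
    ydot[2] = 1000.0*flowA/CA;
    ydot[3] = (flowA - Pve/RVE)/CVE;
}

static const R_CMethodDef cMethods[] = {
    {"resp_init",   (DL_FUNC) &resp_init,   1},
    {"resp_derivs", (DL_FUNC) &resp_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_respsim(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
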