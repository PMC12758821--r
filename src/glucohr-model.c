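/* Compiled right-hand side of the coupled glucose/heart-rate ODE system,
 * in the form deSolve expects for dllname-based models.
 *
 * Parameter vector layout (see .parm_vector() on the R side):
 *   0 Rg  1 alphaG  2 kg  3 Kg  4 Eg  5 betaH  6 Hv  7 GA  8 Gw
 *   9 tc  10 Gsleep 11 Hsleep 12 spike_on (0/1)
 *
 * spike_on lets the R side integrate the pre- and post-spike segments
 * separately so the t >= tc indicator never sits inside an adaptive step.
 */
#include <R.h>
#include <math.h>

static double parms[13];

#define P_Rg     parms[0]
#define P_alphaG parms[1]
#define P_kg     parms[2]
#define P_Kg     parms[3]
#define P_Eg     parms[4]
#define P_betaH  parms[5]
#define P_Hv     parms[6]
#define P_GA     parms[7]
#define P_Gw     parms[8]
#define P_tc     parms[9]
#define P_Gsleep parms[10]
#define P_Hsleep parms[11]
#define P_spike  parms[12]

void glucohr_initmod(void (*odeparms)(int *, double *))
{
    int N = 13;
    odeparms(&N, parms);
}

void glucohr_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double G = y[0], H = y[1];
    double spike = 0.0;

    if (P_spike > 0.5 && *t >= P_tc) {
        double z = (*t - P_tc) / P_Gw;
        spike = P_GA * exp(-0.5 * z * z);
    }

    ydot[0] = P_Rg + P_alphaG * G * (H - P_Hsleep) / P_Hsleep
              - P_kg * G / (G + P_Kg) - P_Eg * G + spike;
    ydot[1] = -P_betaH * (H - P_Hsleep) + P_Hv * (G - P_Gsleep) / P_Gsleep;
}
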