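/* Compiled right-hand side of the pheromone cascade ODEs for deSolve.
 *
 * Parameter vector layout (see .parms_vector in R/cascade-model.R):
 *   0 theta, 1 KR, 2 kact, 3 kact0, 4 kgap0, 5 kgap, 6 kf, 7 kd0, 8 kd,
 *   9 kt, 10 ktb, 11 natp_fus3, 12 natp_ste12,
 *   then 5 genes (STE2, FUS3, SST2, MSG5, FUS1) x (beta0, beta, KD, n, gamma).
 *
 * State layout: 0 A, 1 Rtot, 2 Ftot, 3 Fpp, 4 Ttot, 5 Tp,
 *               6 Sst2, 7 Msg5, 8 Rep, 9 Egtp, 10 Eatp.
 */
#include <R.h>
#include <math.h>

#define NPAR 38
static double parms[NPAR];

void cascade_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, parms);
}

static double hill(double tp, double kd, double n)
{
    double num;
    if (tp <= 0.0) return 0.0;
    num = pow(tp, n);
    return num / (num + pow(kd, n));
}

void cascade_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const double theta = parms[0], KR = parms[1], kact = parms[2];
    const double kact0 = parms[3], kgap0 = parms[4], kgap = parms[5];
    const double kf = parms[6], kd0 = parms[7], kd = parms[8];
    const double kt = parms[9], ktb = parms[10];
    const double natp_f = parms[11], natp_t = parms[12];
    const double *g = parms + 13;           /* gene blocks of 5 */
    const double A = y[0], Rtot = y[1], Ftot = y[2], Fpp = y[3];
    const double Ttot = y[4], Tp = y[5], Sst2 = y[6], Msg5 = y[7], Rep = y[8];
    double occR, deact, phos_f, dephos_f, phos_t, occ[5], synth[5];
    int i;

    occR = theta / (theta + KR);
    deact = kgap0 + kgap * Sst2;
    phos_f = kf * A * (Ftot - Fpp);
    dephos_f = (kd0 + kd * Msg5) * Fpp;
    phos_t = kt * Fpp * (Ttot - Tp);

    for (i = 0; i < 5; i++) {
        occ[i] = hill(Tp, g[5 * i + 2], g[5 * i + 3]);
        synth[i] = g[5 * i + 0] + g[5 * i + 1] * occ[i];
    }

    ydot[0] = (kact0 + kact * occR) * (Rtot - A) - deact * A; /* A   */
    ydot[1] = synth[0] - g[4] * Rtot;                        /* Rtot */
    ydot[2] = synth[1] - g[9] * Ftot;                        /* Ftot */
    ydot[3] = phos_f - dephos_f;                             /* Fpp  */
    ydot[4] = 0.0;                                           /* Ttot */
    ydot[5] = phos_t - ktb * Tp;                             /* Tp   */
    ydot[6] = synth[2] - g[14] * Sst2;                       /* Sst2 */
    ydot[7] = synth[3] - g[19] * Msg5;                       /* Msg5 */
    ydot[8] = synth[4] - g[24] * Rep;                        /* Rep  */
    ydot[9] = deact * A;                                     /* Egtp */
    ydot[10] = natp_f * phos_f + natp_t * phos_t;            /* Eatp */
}
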