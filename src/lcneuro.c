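/* Conductance-based LC chemosensitive neuron: ODE right-hand side.
 *
 * One fixed state layout shared with R/model.R:
 *   y[0]            V (mV)
 *   y[1]  .. y[13]  gates, canonical order:
 *                   CaL.m, CaN.m, CaT.m, CaT.h, H.m, KA.m, KA.h,
 *                   KM.m, KM.h, Kdr.m, Kdr.h, Na.m, Na.h
 *   y[14]           m_SK
 *   y[15]           Ca_in (mM)
 *
 * The parameter vector is assembled by lc_build_parms() in R; chemical
 * modulation (phi) is piecewise constant per protocol segment, so geff
 * already contains phi * gbar.  Units: mV, nA, uS, nF, ms, mM.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define LC_NCH   8
#define LC_CHPAR 21
#define LC_NPAR  (3 + LC_NCH * LC_CHPAR + 24)
#define LC_NEQ   16

static double pglob[LC_NPAR];

static void lc_core(double t, const double *y, double *dy, const double *p)
{
    const double V = y[0];
    double Isum = 0.0, ICa = 0.0, ICaL = 0.0;
    int j, k;

    for (k = 0; k < LC_NEQ; k++) dy[k] = 0.0;

    for (j = 0; j < LC_NCH; j++) {
        const double *q = p + 3 + j * LC_CHPAR;
        const double geff = q[0], E = q[1], alpha = q[2];
        const int im = (int) q[3], hash = (int) q[4], ih = (int) q[5];
        double m = y[im], h = 1.0, gate = 1.0, I, minf, tau, u;

        /* activation kinetics */
        minf = 1.0 / (1.0 + exp(-(V - q[6]) / q[7]));
        if (q[9] == 0.0) {
            tau = q[8];
        } else {
            u = (V - q[10]) / q[11];
            tau = (q[12] != 0.0) ? q[8] + q[9] * exp(-u * u)
                                 : q[8] + q[9] / cosh(u);
        }
        dy[im] = (minf - m) / tau;

        if (hash) {
            double hinf, tauh;
            h = y[ih];
            hinf = 1.0 / (1.0 + exp(-(V - q[13]) / q[14]));
            if (q[16] == 0.0) {
                tauh = q[15];
            } else {
                u = (V - q[17]) / q[18];
                tauh = (q[19] != 0.0) ? q[15] + q[16] * exp(-u * u)
                                      : q[15] + q[16] / cosh(u);
            }
            dy[ih] = (hinf - h) / tauh;
        }

        for (k = 0, gate = 1.0; k < (int) alpha; k++) gate *= m;
        I = geff * gate * h * (E - V);
        Isum += I;
        if (q[20] != 0.0) ICa += I;        /* high-threshold Ca currents */
        if (j == (int) p[175]) ICaL = I;   /* L-type, feeds BK coupling  */
    }

    /* inward rectifier, as printed (added to the sum at face value) */
    Isum += p[171] * (V - p[172] - 36.0) /
            (1.0 + exp((V - p[172] + 140.0) * p[173]));

    /* BK: coupled to the normalized magnitude of the partner Ca current
     * (L is zero when the partner channel carries no conductance) */
    if (p[176] > 0.0)
        Isum += p[174] * (fabs(ICaL) / p[176]) * (p[172] - V);

    /* SK: calcium-gated, first-order activation */
    {
        const int imsk = (int) p[193], ica = (int) p[194];
        const double Ca = (y[ica] > 0.0) ? y[ica] : 0.0;
        const double Kc = p[178], nsk = p[179];
        double can = 1.0, kcn = 1.0, msinf, PB, dCa;
        for (k = 0; k < (int) nsk; k++) { can *= Ca; kcn *= Kc; }
        msinf = (can + kcn > 0.0) ? can / (can + kcn) : 0.0;
        dy[imsk] = (msinf - y[imsk]) / p[180];
        Isum += p[177] * y[imsk] * (p[172] - V);

        /* calcium shell: influx (buffer-attenuated) minus pump */
        PB = p[189] / (Ca + p[189] + p[190]);
        dCa = p[187] * ICa * p[188] * (1.0 - PB)
              - p[191] * Ca / (Ca + p[192]);
        if (y[ica] <= 0.0 && dCa < 0.0) dCa = 0.0;
        dy[ica] = dCa;
    }

    /* linear background leaks (Na / K-TASK / Cl) */
    Isum += p[181] * (p[182] - V);
    Isum += p[183] * (p[184] - V);
    Isum += p[185] * (p[186] - V);

    dy[0] = (Isum + p[1]) / p[0];
}

/* deSolve entry points */
void lc_initmod(void (*odeparms)(int *, double *))
{
    int N = LC_NPAR;
    odeparms(&N, pglob);
}

void lc_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    lc_core(*t, y, ydot, pglob);
}

/* direct single evaluation, for membrane_rhs() and tests */
SEXP C_lc_rhs(SEXP t, SEXP y, SEXP pars)
{
    SEXP ans;
    if (LENGTH(y) != LC_NEQ) error("state vector must have length %d", LC_NEQ);
    if (LENGTH(pars) != LC_NPAR) error("parameter vector must have length %d", LC_NPAR);
    ans = PROTECT(allocVector(REALSXP, LC_NEQ));
    lc_core(asReal(t), REAL(y), REAL(ans), REAL(pars));
    UNPROTECT(1);
    return ans;
}

static const R_CallMethodDef callMethods[] = {
    {"C_lc_rhs", (DL_FUNC) &C_lc_rhs, 3},
    {NULL, NULL, 0}
};

/* registered so deSolve can look the addresses up by name */
static const R_CMethodDef cMethods[] = {
    {"lc_derivs",  (DL_FUNC) &lc_derivs,  6},
    {"lc_initmod", (DL_FUNC) &lc_initmod, 1},
    {NULL, NULL, 0}
};

void R_init_lcneuro(DllInfo *info)
{
    R_registerRoutines(info, cMethods, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
}
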