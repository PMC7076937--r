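/* Compiled right-hand sides for the tumor growth inhibition models,
 * in deSolve's compiled-model interface.  Systems are "batched": one
 * parameter block per replicate so that population sampling (SAEM,
 * importance sampling) can integrate many individuals in a single call.
 *
 * Parameter vectors are fetched as a full SEXP via get_deSolve_gparms so
 * the batch size can be arbitrary.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

static SEXP gparms = NULL;

typedef SEXP (*gparms_fun)(void);
typedef void (*lag_fun)(double, int *, int, double *);

void tgimix_initmod(void (*odeparms)(int *, double *))
{
    static gparms_fun get_gparms = NULL;
    if (get_gparms == NULL)
        get_gparms = (gparms_fun) R_GetCCallable("deSolve", "get_deSolve_gparms");
    gparms = get_gparms();
}

/* one-compartment drug concentration after a single bolus,
 * first-order elimination */
static double conc(double t, double amount, double ke, double t_dose)
{
    if (amount <= 0.0 || t < t_dose)
        return 0.0;
    return amount * exp(-ke * (t - t_dose));
}

/* biphasic tumor growth function: exponential at small V (rate l0),
 * linear at large V (slope l1), switching sharpness psi.
 * Evaluated in log form so that (l0/l1 * V)^psi cannot overflow. */
static double tgf_rate(double Z1, double V, double l0, double l1, double psi)
{
    double u, lp, denom;

    if (Z1 <= 0.0)
        return 0.0;
    u = (l0 / l1) * (V > 0.0 ? V : 0.0);
    if (u <= 0.0)
        return l0 * Z1;
    lp = psi * log(u);
    if (lp > 700.0)
        denom = u;              /* (1 + u^psi)^(1/psi) ~ u */
    else
        denom = exp(log1p(exp(lp)) / psi);
    return l0 * Z1 / denom;
}

/* Transit-compartment system.
 * parms: [0] n_rep, [1] n_transit, [2] psi, then per replicate (stride 7):
 *   lambda0, lambda1, k1, k2, dose_amount, ke, dose_time
 * state per replicate: Z1, then n_transit damaged-cell compartments. */
void tgimix_derivs_simeoni(int *neq, double *t, double *y, double *ydot,
                           double *yout, int *ip)
{
    double *p = REAL(gparms);
    int n_rep = (int) p[0];
    int n_tr = (int) p[1];
    double psi = p[2];
    int ns = 1 + n_tr;
    int r, j;

    for (r = 0; r < n_rep; r++) {
        const double *q = p + 3 + 7 * r;
        double *yr = y + ns * r;
        double *dr = ydot + ns * r;
        double V = 0.0, c, g, kill;

        for (j = 0; j < ns; j++)
            V += yr[j];
        c = conc(*t, q[4], q[5], q[6]);
        g = tgf_rate(yr[0], V, q[0], q[1], psi);
        kill = q[2] * c * yr[0];
        dr[0] = g - kill;
        if (n_tr >= 1) {
            dr[1] = kill - q[3] * yr[1];
            for (j = 2; j < ns; j++)
                dr[j] = q[3] * (yr[j - 1] - yr[j]);
        }
    }
}

static void lagval(double T, int idx0, double *out)
{
    static lag_fun fun = NULL;
    int nr = idx0;
    if (fun == NULL)
        fun = (lag_fun) R_GetCCallable("deSolve", "lagvalue");
    fun(T, &nr, 1, out);
}

/* Delay variant: one damaged compartment, elimination acts on
 * Z2(t - t2); history Z2 = 0 at and before the start time.
 * parms: [0] n_rep, [1] psi, [2] t_start, then per replicate (stride 8):
 *   lambda0, lambda1, k1, k2, t2, dose_amount, ke, dose_time
 * state per replicate: Z1, Z2. */
void tgimix_derivs_delay(int *neq, double *t, double *y, double *ydot,
                         double *yout, int *ip)
{
    double *p = REAL(gparms);
    int n_rep = (int) p[0];
    double psi = p[1];
    double t0 = p[2];
    int r;

    for (r = 0; r < n_rep; r++) {
        const double *q = p + 3 + 8 * r;
        double *yr = y + 2 * r;
        double *dr = ydot + 2 * r;
        double V = yr[0] + yr[1];
        double c = conc(*t, q[5], q[6], q[7]);
        double g = tgf_rate(yr[0], V, q[0], q[1], psi);
        double kill = q[2] * c * yr[0];
        double tlag = *t - q[4];
        double z2lag = 0.0;

        if (tlag > t0)
            lagval(tlag, 2 * r + 1, &z2lag);
        dr[0] = g - kill;
        dr[1] = kill - q[3] * z2lag;
    }
}

static const R_CMethodDef CEntries[] = {
    {"tgimix_initmod",        (DL_FUNC) &tgimix_initmod,        1},
    {"tgimix_derivs_simeoni", (DL_FUNC) &tgimix_derivs_simeoni, 6},
    {"tgimix_derivs_delay",   (DL_FUNC) &tgimix_derivs_delay,   6},
    {NULL, NULL, 0}
};

void R_init_tgimix(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
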