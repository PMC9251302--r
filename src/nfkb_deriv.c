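/* Right-hand side of the NF-kB / IkB / IKK negative-feedback model with
 * quasi-static temperature rescaling of the nine kinetic rates, in the
 * deSolve compiled-model convention.
 *
 * State y = (N_n, I_m, I, IKK_a, IKK_i), concentrations in uM, time in min.
 * IKK_n = IKK_tot - IKK_a - IKK_i is derived, never integrated, so the IKK
 * pool is conserved by construction.
 *
 * Parameter vector layout (see build_solver_parms() on the R side):
 *   [0..8]   reference rates at T_ref:
 *            k_Nin, k_Iin, k_t, k_tl, gamma_m, alpha, k_a, k_i, k_p
 *   [9..17]  thermal slope coefficients c_r (per K): the rate at absolute
 *            temperature T is k0 * (1 + c_r * (T - T_ref));
 *            c_r = 1/T_ref (diffusion limited), S/T_ref (reaction limited)
 *            or 0 (temperature independent)
 *   [18..23] K_I, K_N, N_tot, k_A20, IKK_tot, A20
 *   [24]     T_ref (K)
 *   [25]     temp_mode: 0 constant, 1 sinusoid
 *   [26..28] temp_base (degC), temp_amplitude (degC), temp_frequency (1/min)
 *   [29]     tnf_mode: 0 constant, 1 sinusoid, 2 step sequence
 *   [30..32] tnf_base, tnf_amplitude, tnf_period (min)
 *   [33]     number of TNF steps (<= NFKB_MAX_STEPS)
 *   [34..65] step times (min), [66..97] step levels
 */

#include <R.h>
#include <math.h>
#include <R_ext/Rdynload.h>

#define NFKB_MAX_STEPS 32
#define NFKB_NPARMS (34 + 2 * NFKB_MAX_STEPS)
#define RATE_FLOOR 1e-12

static double parms[NFKB_NPARMS];

void nfkb_initmod(void (*odeparms)(int *, double *))
{
    int n = NFKB_NPARMS;
    odeparms(&n, parms);
}

static double tnf_value(double t)
{
    int mode = (int) parms[29];
    double tnf = parms[30];
    if (mode == 1) {
        tnf = parms[30] + parms[31] * sin(2.0 * M_PI * t / parms[32]);
    } else if (mode == 2) {
        int nstep = (int) parms[33];
        for (int i = 0; i < nstep; i++) {
            if (t >= parms[34 + i]) tnf = parms[66 + i];
        }
    }
    return tnf < 0.0 ? 0.0 : tnf;
}

static double temp_celsius(double t)
{
    if ((int) parms[25] == 1)
        return parms[26] + parms[27] * sin(2.0 * M_PI * parms[28] * t);
    return parms[26];
}

void nfkb_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double dT = temp_celsius(*t) + 273.15 - parms[24];
    double r[9];
    for (int i = 0; i < 9; i++) {
        r[i] = parms[i] * (1.0 + parms[9 + i] * dT);
        if (r[i] < RATE_FLOOR) r[i] = RATE_FLOOR;
    }
    double k_Nin = r[0], k_Iin = r[1], k_t = r[2], k_tl = r[3],
           gamma_m = r[4], alpha = r[5], k_a = r[6], k_i = r[7], k_p = r[8];
    double K_I = parms[18], K_N = parms[19], N_tot = parms[20],
           k_A20 = parms[21], IKK_tot = parms[22], A20 = parms[23];

    double N_n = y[0], I_m = y[1], I = y[2], IKK_a = y[3], IKK_i = y[4];
    double TNF = tnf_value(*t);
    double IKK_n = IKK_tot - IKK_a - IKK_i;

    ydot[0] = k_Nin * (N_tot - N_n) * K_I / (K_I + I)
            - k_Iin * I * N_n / (K_N + N_n);
    ydot[1] = k_t * N_n * N_n - gamma_m * I_m;
    ydot[2] = k_tl * I_m - alpha * IKK_a * (N_tot - N_n) * I / (K_I + I);
    ydot[3] = k_a * TNF * IKK_n - k_i * IKK_a;
    ydot[4] = k_i * IKK_a - k_p * IKK_i * k_A20 / (k_A20 + A20 * TNF);

    if (ip[0] >= 2) {
        yout[0] = TNF;
        yout[1] = temp_celsius(*t);
    }
}

static const R_CMethodDef cMethods[] = {
    {"nfkb_initmod", (DL_FUNC) &nfkb_initmod, 1},
    {"nfkb_derivs",  (DL_FUNC) &nfkb_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_nfkbtherm(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
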