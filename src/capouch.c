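/* Tissue-scale right-hand side for the coupled IP3/Ca2+/IP3R model,
 * evaluated by deSolve's lsodes.
 *
 * Parameter vector layout (doubles):
 *   [0] N cells, [1] nE edges, [2] reactions on/off,
 *   [3..19] k5P K_PLC beta V_SERCA K_SERCA k1 k2 Ka Kr Kp tau_max k_tau
 *           Fp Fc c_tot variant(1=modified,2=constant_tau) tau_r
 *   [20 .. 20+N)            per-cell V_PLC
 *   [.. +nE), [.. +nE), [.. +nE)  edge i (1-based), edge j, shared length l_ij
 *
 * State layout: y = [p_1..p_N, c_1..c_N, r_1..r_N].
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

static double *gpar = NULL;
static int npar = 0;

void capouch_alloc(int *n)
{
    if (gpar) R_Free(gpar);
    npar = *n;
    gpar = R_Calloc((size_t) npar, double);
}

void capouch_init(void (*odeparms)(int *, double *))
{
    odeparms(&npar, gpar);
}

void capouch_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const double *pv = gpar;
    const int N = (int) pv[0];
    const int nE = (int) pv[1];
    const int react = (int) pv[2];
    const double k5P = pv[3], K_PLC = pv[4], beta = pv[5], V_SERCA = pv[6],
        K_SERCA = pv[7], k1 = pv[8], k2 = pv[9], Ka = pv[10], Kr = pv[11],
        Kp = pv[12], tau_max = pv[13], k_tau = pv[14], Fp = pv[15],
        Fc = pv[16], c_tot = pv[17];
    const int variant = (int) pv[18];
    const double tau_r = pv[19];
    const double *vplc = pv + 20;
    const double *ei = pv + 20 + N;
    const double *ej = pv + 20 + N + nE;
    const double *el = pv + 20 + N + 2 * nE;

    const double *p = y, *c = y + N, *r = y + 2 * N;
    double *dp = ydot, *dc = ydot + N, *dr = ydot + 2 * N;

    for (int i = 0; i < 3 * N; i++) ydot[i] = 0.0;

    /* gap-junction exchange: J_i = F * sum_j l_ij (x_j - x_i) */
    for (int e = 0; e < nE; e++) {
        const int i = (int) ei[e] - 1, j = (int) ej[e] - 1;
        const double l = el[e];
        const double gp = l * (p[j] - p[i]);
        const double gc = l * (c[j] - c[i]);
        dp[i] += Fp * gp; dp[j] -= Fp * gp;
        dc[i] += Fc * gc; dc[j] -= Fc * gc;
    }

    if (react) {
        const double kt4 = k_tau * k_tau * k_tau * k_tau;
        for (int i = 0; i < N; i++) {
            const double ci = c[i], pi = p[i], ri = r[i];
            const double c2 = ci * ci;
            const double s = (c_tot - ci) / beta;
            const double A = ri * ci / (Ka + ci) * pi / (Kp + pi);
            const double rel = (k1 * A * A * A + k2) * (s - ci);
            const double serca = V_SERCA * c2 / (c2 + K_SERCA * K_SERCA);
            dp[i] += vplc[i] * c2 / (K_PLC * K_PLC + c2) - k5P * pi;
            dc[i] += rel - serca;
            const double drive = 1.0 - ri * (Kr + ci) / Kr;
            if (variant == 1) {
                const double c4 = c2 * c2;
                dr[i] = (kt4 + c4) / (tau_max * kt4) * drive;
            } else {
                dr[i] = drive / tau_r;
            }
        }
    }
}

static const R_CMethodDef CEntries[] = {
    {"capouch_alloc",  (DL_FUNC) &capouch_alloc,  1},
    {"capouch_derivs", (DL_FUNC) &capouch_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_capouch(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
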