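/* Mass-action right-hand side of the 8-state Nox1 assembly/disassembly
 * network, in the form deSolve expects from a compiled model.
 *
 * States  x1..x8: Nox1_active, Nox1/p22, p47, p47_P, Rac1_GDP, Rac1_GTP,
 *                 NoxA1, NoxA1_P.
 * Parms   p[0..15] = gamma1..gamma16, p[16..18] = S1..S3.
 */
#include <R.h>
#include <R_ext/Rdynload.h>

static double p[19];

void nox1_init(void (*odeparms)(int *, double *))
{
    int n = 19;
    odeparms(&n, p);
}

void nox1_derivs(int *neq, double *t, double *x, double *dx,
                 double *yout, int *ip)
{
    double f[17]; /* 1-based: f[1]..f[16] */
    double s1 = p[16], s2 = p[17], s3 = p[18];

    f[1]  = p[0]  * x[1] * x[3] * x[5] * x[6]; /* g1 x2 x4 x6 x7 */
    f[2]  = p[1]  * x[0];                      /* g2 x1          */
    f[3]  = p[2]  * x[0];
    f[4]  = p[3]  * x[0];
    f[5]  = p[4]  * x[2] * s1;                 /* g5 x3 S1       */
    f[6]  = p[5]  * x[3];
    f[7]  = p[6]  * x[4] * s2;                 /* g7 x5 S2       */
    f[8]  = p[7]  * x[5];
    f[9]  = p[8]  * x[6] * s3;                 /* g9 x7 S3       */
    f[10] = p[9]  * x[7];
    f[11] = p[10];
    f[12] = p[11];
    f[13] = p[12];
    f[14] = p[13] * x[0];
    f[15] = p[14];
    f[16] = p[15] * x[7];

    dx[0] = f[1] - f[2] - f[3] - f[4] - f[14];          /* x1 */
    dx[1] = -f[1] + f[2] + f[3] + f[4] + f[11];         /* x2 */
    dx[2] = f[3] - f[5] + f[6] + f[12];                 /* x3 */
    dx[3] = -f[1] + f[2] + f[4] + f[5] - f[6];          /* x4 */
    dx[4] = f[4] - f[7] + f[8] + f[13];                 /* x5 */
    dx[5] = -f[1] + f[2] + f[3] + f[7] - f[8];          /* x6 */
    dx[6] = -f[1] + f[3] + f[4] - f[9] + f[10] + f[15]; /* x7 */
    dx[7] = f[2] + f[9] - f[10] - f[16];                /* x8 */
}

static const R_CMethodDef cMethods[] = {
    {"nox1_derivs", (DL_FUNC) &nox1_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_nox1design(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
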