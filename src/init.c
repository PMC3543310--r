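#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_qssa_run(SEXP par, SEXP y0, SEXP tout, SEXP tol);

void gc_initmod_invitro(void (*odeparms)(int *, double *));
void gc_derivs_invitro(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip);
void gc_initmod_invivo(void (*odeparms)(int *, double *));
void gc_initforc_invivo(void (*odeforcs)(int *, double *));
void gc_derivs_invivo(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip);

static const R_CallMethodDef callMethods[] = {
    { "C_qssa_run", (DL_FUNC) &C_qssa_run, 4 },
    { NULL, NULL, 0 }
};

void R_init_gcsteroid(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, TRUE); /* deSolve looks symbols up by name */
}
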