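#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void cc_initmod(void (*odeparms)(int *, double *));
void cc_derivs(int *neq, double *t, double *y, double *ydot, double *yout,
               int *ip);
void cc_rhs_direct(double *t, double *y, double *p, double *ydot);

static const R_CMethodDef CEntries[] = {
    {"cc_rhs_direct", (DL_FUNC) &cc_rhs_direct, 4},
    {NULL, NULL, 0}
};

void R_init_circacycle(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);  /* deSolve looks up cc_derivs/cc_initmod by name */
}
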