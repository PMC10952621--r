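#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP ord_rhs_call(SEXP state, SEXP params, SEXP time);
void ord_init(void (*odeparms)(int *, double *));
void ord_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);

static const R_CallMethodDef call_entries[] = {
    {"ord_rhs_call", (DL_FUNC) &ord_rhs_call, 3},
    {NULL, NULL, 0}
};

/* registered so deSolve can resolve them by name via getNativeSymbolInfo */
static const R_CMethodDef c_entries[] = {
    {"ord_init", (DL_FUNC) &ord_init, 1},
    {"ord_derivs", (DL_FUNC) &ord_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_camiks(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
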