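#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* cdtw.cpp */
extern SEXP c_cdtw(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP c_cdtw_matrix(SEXP, SEXP, SEXP, SEXP, SEXP);

/* pathway_rhs.c (looked up by deSolve via getNativeSymbolInfo) */
extern void pathway_init(void (*odeparms)(int *, double *));
extern void pathway_derivs(int *, double *, double *, double *, double *,
                           int *);

static const R_CallMethodDef CallEntries[] = {
    {"c_cdtw", (DL_FUNC) &c_cdtw, 6},
    {"c_cdtw_matrix", (DL_FUNC) &c_cdtw_matrix, 5},
    {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
    {"pathway_init", (DL_FUNC) &pathway_init, 1},
    {"pathway_derivs", (DL_FUNC) &pathway_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_smadtier(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
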