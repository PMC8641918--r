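#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_trideig_top(SEXP diag_, SEXP offdiag_, SEXP ntop_);

static const R_CallMethodDef callMethods[] = {
    {"C_trideig_top", (DL_FUNC) &C_trideig_top, 3},
    {NULL, NULL, 0}
};

void R_init_blockspec(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
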