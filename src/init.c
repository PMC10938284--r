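#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP msio_inflate(SEXP, SEXP);

static const R_CallMethodDef call_entries[] = {
    {"msio_inflate", (DL_FUNC) &msio_inflate, 2},
    {NULL, NULL, 0}
};

void R_init_msio(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
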