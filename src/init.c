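#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP C_im2col(SEXP, SEXP, SEXP, SEXP);
extern SEXP C_col2im(SEXP, SEXP, SEXP, SEXP);
extern SEXP C_maxpool(SEXP, SEXP, SEXP, SEXP);
extern SEXP C_maxpool_bw(SEXP, SEXP, SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"C_im2col",     (DL_FUNC) &C_im2col,     4},
    {"C_col2im",     (DL_FUNC) &C_col2im,     4},
    {"C_maxpool",    (DL_FUNC) &C_maxpool,    4},
    {"C_maxpool_bw", (DL_FUNC) &C_maxpool_bw, 3},
    {NULL, NULL, 0}
};

void R_init_rightreasons(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
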