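#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP C_cc_derivs(SEXP, SEXP);
extern void cc_initmod(void (*)(int *, double *));
extern void cc_derivs(int *, double *, double *, double *, double *, int *);
extern void cc_root(int *, double *, double *, int *, double *, double *,
                    int *);

static const R_CallMethodDef call_entries[] = {
  {"C_cc_derivs", (DL_FUNC) &C_cc_derivs, 2},
  {NULL, NULL, 0}
};

void R_init_hifcycle(DllInfo *dll)
{
  R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
  R_useDynamicSymbols(dll, TRUE); /* deSolve looks up cc_* by name */
}
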