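#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_ds_set_scale(SEXP, SEXP, SEXP);
SEXP C_ds_attach(SEXP, SEXP, SEXP, SEXP, SEXP);
SEXP C_ds_scales(SEXP, SEXP, SEXP);
SEXP C_ds_label(SEXP, SEXP, SEXP);
SEXP C_vlen_write(SEXP, SEXP, SEXP);
SEXP C_vlen_write_row(SEXP, SEXP, SEXP, SEXP);
SEXP C_vlen_read(SEXP, SEXP);
SEXP C_dtype_class(SEXP, SEXP);
SEXP C_dset_dims(SEXP, SEXP);
SEXP C_attrs(SEXP, SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"C_ds_set_scale",   (DL_FUNC) &C_ds_set_scale,   3},
    {"C_ds_attach",      (DL_FUNC) &C_ds_attach,      5},
    {"C_ds_scales",      (DL_FUNC) &C_ds_scales,      3},
    {"C_ds_label",       (DL_FUNC) &C_ds_label,       3},
    {"C_vlen_write",     (DL_FUNC) &C_vlen_write,     3},
    {"C_vlen_write_row", (DL_FUNC) &C_vlen_write_row, 4},
    {"C_vlen_read",      (DL_FUNC) &C_vlen_read,      2},
    {"C_dtype_class",    (DL_FUNC) &C_dtype_class,    2},
    {"C_dset_dims",      (DL_FUNC) &C_dset_dims,      2},
    {"C_attrs",          (DL_FUNC) &C_attrs,          2},
    {NULL, NULL, 0}
};

void R_init_nsdf(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
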