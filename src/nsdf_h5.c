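/* Minimal HDF5 helpers not covered by rhdf5: dimension scales (H5DS high
 * level API) and variable-length double datasets.  All functions open the
 * file by path and close every handle before returning, so they can be
 * interleaved freely with rhdf5 calls. */

#include <R.h>
#include <Rinternals.h>
#include <hdf5.h>
#include <hdf5_hl.h>
#include <string.h>

#define MAX_SCALES 256

static hid_t open_file(const char *path, unsigned flags)
{
    hid_t f;
    H5E_BEGIN_TRY { f = H5Fopen(path, flags, H5P_DEFAULT); } H5E_END_TRY;
    if (f < 0) error("cannot open HDF5 file '%s'", path);
    return f;
}

static hid_t open_dset(hid_t f, const char *path)
{
    hid_t d;
    H5E_BEGIN_TRY { d = H5Dopen2(f, path, H5P_DEFAULT); } H5E_END_TRY;
    if (d < 0) { H5Fclose(f); error("no such dataset '%s'", path); }
    return d;
}

SEXP C_ds_set_scale(SEXP file, SEXP dset, SEXP name)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), H5F_ACC_RDWR);
    hid_t d = open_dset(f, CHAR(STRING_ELT(dset, 0)));
    herr_t s = H5DSset_scale(d, CHAR(STRING_ELT(name, 0)));
    H5Dclose(d); H5Fclose(f);
    return ScalarLogical(s >= 0);
}

/* attach `scale` to dimension `dim` of `dset` and set the dimension label;
 * idempotent. */
SEXP C_ds_attach(SEXP file, SEXP dset, SEXP scale, SEXP dim, SEXP label)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), H5F_ACC_RDWR);
    hid_t d = open_dset(f, CHAR(STRING_ELT(dset, 0)));
    hid_t s;
    H5E_BEGIN_TRY { s = H5Dopen2(f, CHAR(STRING_ELT(scale, 0)), H5P_DEFAULT); } H5E_END_TRY;
    if (s < 0) { H5Dclose(d); H5Fclose(f); error("no such scale dataset"); }
    unsigned idx = (unsigned) INTEGER(dim)[0];
    htri_t have = H5DSis_attached(d, s, idx);
    herr_t r = (have > 0) ? 0 : H5DSattach_scale(d, s, idx);
    herr_t r2 = H5DSset_label(d, idx, CHAR(STRING_ELT(label, 0)));
    H5Dclose(s); H5Dclose(d); H5Fclose(f);
    return ScalarLogical(r >= 0 && r2 >= 0);
}

struct scale_acc { char *paths[MAX_SCALES]; int n; };

static herr_t scale_cb(hid_t did, unsigned dim, hid_t dsid, void *data)
{
    (void) did; (void) dim;
    struct scale_acc *acc = (struct scale_acc *) data;
    ssize_t len = H5Iget_name(dsid, NULL, 0);
    if (len > 0 && acc->n < MAX_SCALES) {
        char *buf = (char *) R_alloc((size_t) len + 1, 1);
        H5Iget_name(dsid, buf, (size_t) len + 1);
        acc->paths[acc->n++] = buf;
    }
    return 0;
}

/* absolute paths of all scales attached to dimension `dim` */
SEXP C_ds_scales(SEXP file, SEXP dset, SEXP dim)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), H5F_ACC_RDONLY);
    hid_t d = open_dset(f, CHAR(STRING_ELT(dset, 0)));
    struct scale_acc acc; acc.n = 0;
    int idx0 = 0;
    H5E_BEGIN_TRY {
        H5DSiterate_scales(d, (unsigned) INTEGER(dim)[0], &idx0, scale_cb, &acc);
    } H5E_END_TRY;
    H5Dclose(d); H5Fclose(f);
    SEXP out = PROTECT(allocVector(STRSXP, acc.n));
    for (int i = 0; i < acc.n; i++)
        SET_STRING_ELT(out, i, mkChar(acc.paths[i]));
    UNPROTECT(1);
    return out;
}

SEXP C_ds_label(SEXP file, SEXP dset, SEXP dim)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), H5F_ACC_RDONLY);
    hid_t d = open_dset(f, CHAR(STRING_ELT(dset, 0)));
    char buf[256]; buf[0] = '\0';
    ssize_t r;
    H5E_BEGIN_TRY { r = H5DSget_label(d, (unsigned) INTEGER(dim)[0], buf, sizeof buf); } H5E_END_TRY;
    H5Dclose(d); H5Fclose(f);
    return mkString(r > 0 ? buf : "");
}

/* (re)create a 1D variable-length float64 dataset and write `rows` (a list
 * of double vectors) in one go */
SEXP C_vlen_write(SEXP file, SEXP path, SEXP rows)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), H5F_ACC_RDWR);
    hid_t vt = H5Tvlen_create(H5T_NATIVE_DOUBLE);
    hsize_t n = (hsize_t) XLENGTH(rows);
    hid_t sp = H5Screate_simple(1, &n, NULL);
    H5E_BEGIN_TRY { H5Ldelete(f, CHAR(STRING_ELT(path, 0)), H5P_DEFAULT); } H5E_END_TRY;
    hid_t d = H5Dcreate2(f, CHAR(STRING_ELT(path, 0)), vt, sp,
                         H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
    if (d < 0) { H5Sclose(sp); H5Tclose(vt); H5Fclose(f); error("vlen create failed"); }
    hvl_t *buf = (hvl_t *) R_alloc((size_t) n, sizeof(hvl_t));
    for (R_xlen_t i = 0; i < (R_xlen_t) n; i++) {
        SEXP row = VECTOR_ELT(rows, i);
        buf[i].len = (size_t) XLENGTH(row);
        buf[i].p = REAL(row);
    }
    herr_t s = H5Dwrite(d, vt, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf);
    H5Dclose(d); H5Sclose(sp); H5Tclose(vt); H5Fclose(f);
    if (s < 0) error("vlen write failed");
    return ScalarLogical(1);
}

/* overwrite row `i` (0-based) of an existing vlen dataset */
SEXP C_vlen_write_row(SEXP file, SEXP path, SEXP i, SEXP values)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), H5F_ACC_RDWR);
    hid_t d = open_dset(f, CHAR(STRING_ELT(path, 0)));
    hid_t vt = H5Tvlen_create(H5T_NATIVE_DOUBLE);
    hid_t fsp = H5Dget_space(d);
    hsize_t start = (hsize_t) INTEGER(i)[0], count = 1;
    H5Sselect_hyperslab(fsp, H5S_SELECT_SET, &start, NULL, &count, NULL);
    hid_t msp = H5Screate_simple(1, &count, NULL);
    hvl_t buf;
    buf.len = (size_t) XLENGTH(values);
    buf.p = REAL(values);
    herr_t s = H5Dwrite(d, vt, msp, fsp, H5P_DEFAULT, &buf);
    H5Sclose(msp); H5Sclose(fsp); H5Tclose(vt); H5Dclose(d); H5Fclose(f);
    if (s < 0) error("vlen row write failed");
    return ScalarLogical(1);
}

SEXP C_vlen_read(SEXP file, SEXP path)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), H5F_ACC_RDONLY);
    hid_t d = open_dset(f, CHAR(STRING_ELT(path, 0)));
    hid_t sp = H5Dget_space(d);
    hsize_t n = 0;
    H5Sget_simple_extent_dims(sp, &n, NULL);
    hid_t vt = H5Tvlen_create(H5T_NATIVE_DOUBLE);
    hvl_t *buf = (hvl_t *) R_alloc((size_t) n, sizeof(hvl_t));
    herr_t s = H5Dread(d, vt, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf);
    SEXP out = PROTECT(allocVector(VECSXP, (R_xlen_t) n));
    if (s >= 0) {
        for (R_xlen_t i = 0; i < (R_xlen_t) n; i++) {
            SEXP row = allocVector(REALSXP, (R_xlen_t) buf[i].len);
            SET_VECTOR_ELT(out, i, row);
            if (buf[i].len > 0)
                memcpy(REAL(row), buf[i].p, buf[i].len * sizeof(double));
        }
        H5Dvlen_reclaim(vt, sp, H5P_DEFAULT, buf);
    }
    H5Tclose(vt); H5Sclose(sp); H5Dclose(d); H5Fclose(f);
    UNPROTECT(1);
    if (s < 0) error("vlen read failed");
    return out;
}

/* coarse datatype class of a dataset: float / integer / string / compound /
 * vlen / other */
SEXP C_dtype_class(SEXP file, SEXP path)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), H5F_ACC_RDONLY);
    hid_t d = open_dset(f, CHAR(STRING_ELT(path, 0)));
    hid_t t = H5Dget_type(d);
    H5T_class_t c = H5Tget_class(t);
    const char *nm;
    switch (c) {
    case H5T_FLOAT:    nm = "float";    break;
    case H5T_INTEGER:  nm = "integer";  break;
    case H5T_STRING:   nm = "string";   break;
    case H5T_COMPOUND: nm = "compound"; break;
    case H5T_VLEN:     nm = "vlen";     break;
    default:           nm = "other";    break;
    }
    H5Tclose(t); H5Dclose(d); H5Fclose(f);
    return mkString(nm);
}

/* Read all attributes of a node as a named list.  Only string, float and
 * integer attributes are returned; reference-typed attributes (e.g. the
 * DIMENSION_LIST bookkeeping of dimension scales) are skipped. */
SEXP C_attrs(SEXP file, SEXP path)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), H5F_ACC_RDONLY);
    hid_t o;
    H5E_BEGIN_TRY { o = H5Oopen(f, CHAR(STRING_ELT(path, 0)), H5P_DEFAULT); } H5E_END_TRY;
    if (o < 0) { H5Fclose(f); error("no such object '%s'", CHAR(STRING_ELT(path, 0))); }
    H5O_info_t oinfo;
#if H5_VERSION_GE(1, 12, 0)
    H5Oget_info3(o, &oinfo, H5O_INFO_NUM_ATTRS);
#else
    H5Oget_info2(o, &oinfo, H5O_INFO_NUM_ATTRS);
#endif
    int n = (int) oinfo.num_attrs;
    SEXP out = PROTECT(allocVector(VECSXP, n));
    SEXP nms = PROTECT(allocVector(STRSXP, n));
    int kept = 0;
    for (int i = 0; i < n; i++) {
        hid_t a = H5Aopen_by_idx(o, ".", H5_INDEX_NAME, H5_ITER_INC,
                                 (hsize_t) i, H5P_DEFAULT, H5P_DEFAULT);
        if (a < 0) continue;
        char aname[256];
        H5Aget_name(a, sizeof aname, aname);
        hid_t t = H5Aget_type(a);
        hid_t sp = H5Aget_space(a);
        hssize_t np = H5Sget_simple_extent_npoints(sp);
        H5T_class_t cls = H5Tget_class(t);
        SEXP val = R_NilValue;
        if (np >= 0 && cls == H5T_STRING) {
            val = PROTECT(allocVector(STRSXP, (R_xlen_t) np));
            if (H5Tis_variable_str(t)) {
                hid_t mt = H5Tcopy(H5T_C_S1);
                H5Tset_size(mt, H5T_VARIABLE);
                char **buf = (char **) R_alloc((size_t) np, sizeof(char *));
                if (H5Aread(a, mt, buf) >= 0) {
                    for (R_xlen_t k = 0; k < np; k++)
                        SET_STRING_ELT(val, k, mkChar(buf[k] ? buf[k] : ""));
                    H5Dvlen_reclaim(mt, sp, H5P_DEFAULT, buf);
                }
                H5Tclose(mt);
            } else {
                size_t sz = H5Tget_size(t);
                char *buf = (char *) R_alloc((size_t) np, sz + 1);
                hid_t mt = H5Tcopy(t);
                if (H5Aread(a, mt, buf) >= 0) {
                    char *one = (char *) R_alloc(1, sz + 1);
                    for (R_xlen_t k = 0; k < np; k++) {
                        memcpy(one, buf + k * sz, sz);
                        one[sz] = '\0';
                        SET_STRING_ELT(val, k, mkChar(one));
                    }
                }
                H5Tclose(mt);
            }
        } else if (np >= 0 && (cls == H5T_FLOAT || cls == H5T_INTEGER)) {
            val = PROTECT(allocVector(REALSXP, (R_xlen_t) np));
            if (H5Aread(a, H5T_NATIVE_DOUBLE, REAL(val)) < 0)
                for (R_xlen_t k = 0; k < np; k++) REAL(val)[k] = NA_REAL;
        }
        if (val != R_NilValue) {
            SET_VECTOR_ELT(out, kept, val);
            SET_STRING_ELT(nms, kept, mkChar(aname));
            kept++;
            UNPROTECT(1); /* val, now protected by out */
        }
        H5Sclose(sp); H5Tclose(t); H5Aclose(a);
    }
    H5Oclose(o); H5Fclose(f);
    SEXP out2 = PROTECT(xlengthgets(out, kept));
    SEXP nms2 = PROTECT(xlengthgets(nms, kept));
    setAttrib(out2, R_NamesSymbol, nms2);
    UNPROTECT(4);
    return out2;
}

/* rank and dims of a dataset's dataspace, in file (C) order */
SEXP C_dset_dims(SEXP file, SEXP path)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), H5F_ACC_RDONLY);
    hid_t d = open_dset(f, CHAR(STRING_ELT(path, 0)));
    hid_t sp = H5Dget_space(d);
    int rank = H5Sget_simple_extent_ndims(sp);
    SEXP out = PROTECT(allocVector(REALSXP, rank > 0 ? rank : 0));
    if (rank > 0) {
        hsize_t dims[32];
        H5Sget_simple_extent_dims(sp, dims, NULL);
        for (int i = 0; i < rank; i++) REAL(out)[i] = (double) dims[i];
    }
    H5Sclose(sp); H5Dclose(d); H5Fclose(f);
    UNPROTECT(1);
    return out;
}
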