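/* Top eigenpairs of a symmetric tridiagonal matrix via LAPACK dstevr.
 * Used for the Slepian (DPSS) system, where the concentration operator
 * commutes with a tridiagonal matrix whose eigenvectors are the tapers. */

#define USE_FC_LEN_T
#include <R.h>
#include <Rinternals.h>
#include <R_ext/RS.h>
#include <R_ext/Lapack.h>
#include <stdlib.h>
#include <string.h>

#ifndef FCLEN
# define FCLEN
#endif
#ifndef FCONE
# define FCONE
#endif

/* dstevr comes from R_ext/Lapack.h; its int* (non-const) signature is
 * satisfied below because d/e are writable copies. */

SEXP C_trideig_top(SEXP diag_, SEXP offdiag_, SEXP ntop_)
{
    int n = LENGTH(diag_);
    int ntop = asInteger(ntop_);
    if (ntop < 1 || ntop > n)
        error("number of requested eigenpairs out of range");
    if (LENGTH(offdiag_) != n - 1)
        error("off-diagonal must have length n - 1");

    /* dstevr overwrites d and e */
    double *d = (double *) R_alloc(n, sizeof(double));
    double *e = (double *) R_alloc(n > 1 ? n : 1, sizeof(double));
    memcpy(d, REAL(diag_), n * sizeof(double));
    if (n > 1) memcpy(e, REAL(offdiag_), (n - 1) * sizeof(double));

    int il = n - ntop + 1, iu = n; /* largest ntop, ascending */
    double vl = 0.0, vu = 0.0, abstol = 0.0;
    int m = 0, ldz = n, info = 0;
    int lwork = 20 * n, liwork = 10 * n;

    SEXP vals = PROTECT(allocVector(REALSXP, ntop));
    SEXP vecs = PROTECT(allocMatrix(REALSXP, n, ntop));
    int *isuppz = (int *) R_alloc(2 * (size_t) ntop, sizeof(int));
    double *work = (double *) R_alloc(lwork, sizeof(double));
    int *iwork = (int *) R_alloc(liwork, sizeof(int));

    F77_CALL(dstevr)("V", "I", &n, d, e, &vl, &vu, &il, &iu, &abstol,
                     &m, REAL(vals), REAL(vecs), &ldz, isuppz,
                     work, &lwork, iwork, &liwork, &info FCONE FCONE);
    if (info != 0)
        error("LAPACK dstevr failed with code %d", info);
    if (m != ntop)
        error("dstevr returned %d of %d requested eigenpairs", m, ntop);

    SEXP out = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(out, 0, vals);
    SET_VECTOR_ELT(out, 1, vecs);
    SEXP nms = PROTECT(allocVector(STRSXP, 2));
    SET_STRING_ELT(nms, 0, mkChar("values"));
    SET_STRING_ELT(nms, 1, mkChar("vectors"));
    setAttrib(out, R_NamesSymbol, nms);
    UNPROTECT(4);
    return out;
}
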