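/* Gather/scatter kernels for batched convolution and max pooling.
 * Layout contract (column-major, as in the R code):
 *   - padded input volume per sample: vol = Hp*Wp*Cin doubles
 *   - idx: integer matrix (KKC x PQ), 1-based indices into one volume
 *   - col: (KKC x PQ*N), sample-major blocks of PQ columns
 */
#include <R.h>
#include <Rinternals.h>
#include <string.h>

SEXP C_im2col(SEXP xp, SEXP idx, SEXP n_sexp, SEXP vol_sexp)
{
    const int N = asInteger(n_sexp);
    const R_xlen_t vol = (R_xlen_t) asReal(vol_sexp);
    const int KKC = nrows(idx), PQ = ncols(idx);
    const int *ip = INTEGER(idx);
    const double *x = REAL(xp);
    const R_xlen_t block = (R_xlen_t) KKC * PQ;
    SEXP out = PROTECT(allocMatrix(REALSXP, KKC, (R_xlen_t) PQ * N));
    double *o = REAL(out);
    for (int n = 0; n < N; n++) {
        const double *xn = x + vol * n;
        double *on = o + block * n;
        for (R_xlen_t j = 0; j < block; j++)
            on[j] = xn[ip[j] - 1];
    }
    UNPROTECT(1);
    return out;
}

SEXP C_col2im(SEXP gcol, SEXP idx, SEXP n_sexp, SEXP vol_sexp)
{
    const int N = asInteger(n_sexp);
    const R_xlen_t vol = (R_xlen_t) asReal(vol_sexp);
    const int KKC = nrows(idx), PQ = ncols(idx);
    const int *ip = INTEGER(idx);
    const double *g = REAL(gcol);
    const R_xlen_t block = (R_xlen_t) KKC * PQ;
    SEXP out = PROTECT(allocVector(REALSXP, vol * N));
    double *o = REAL(out);
    memset(o, 0, sizeof(double) * vol * N);
    for (int n = 0; n < N; n++) {
        const double *gn = g + block * n;
        double *on = o + vol * n;
        for (R_xlen_t j = 0; j < block; j++)
            on[ip[j] - 1] += gn[j];
    }
    UNPROTECT(1);
    return out;
}

/* Max pooling over `planes` independent (H x W) planes.
 * Returns list(out, argidx, argoff): pooled values, 1-based flat index of
 * each window maximum into the full input, and the winning window offset. */
SEXP C_maxpool(SEXP x, SEXP idx, SEXP planes_sexp, SEXP planesize_sexp)
{
    const int planes = asInteger(planes_sexp);
    const R_xlen_t psize = (R_xlen_t) asReal(planesize_sexp);
    const int kk = nrows(idx), PQ = ncols(idx);
    const int *ip = INTEGER(idx);
    const double *xv = REAL(x);
    const R_xlen_t nout = (R_xlen_t) PQ * planes;
    SEXP out = PROTECT(allocVector(REALSXP, nout));
    SEXP argidx = PROTECT(allocVector(REALSXP, nout));  /* may exceed INT_MAX */
    SEXP argoff = PROTECT(allocVector(INTSXP, nout));
    double *ov = REAL(out), *ai = REAL(argidx);
    int *ao = INTEGER(argoff);
    for (int pl = 0; pl < planes; pl++) {
        const double *xp = xv + psize * pl;
        const R_xlen_t base = psize * pl;
        for (int j = 0; j < PQ; j++) {
            const int *ij = ip + (R_xlen_t) kk * j;
            double best = xp[ij[0] - 1];
            int boff = 0;
            for (int r = 1; r < kk; r++) {
                double v = xp[ij[r] - 1];
                if (v > best) { best = v; boff = r; }
            }
            R_xlen_t o = (R_xlen_t) PQ * pl + j;
            ov[o] = best;
            ai[o] = (double) (base + ij[boff]);
            ao[o] = boff + 1;
        }
    }
    SEXP res = PROTECT(allocVector(VECSXP, 3));
    SET_VECTOR_ELT(res, 0, out);
    SET_VECTOR_ELT(res, 1, argidx);
    SET_VECTOR_ELT(res, 2, argoff);
    UNPROTECT(4);
    return res;
}

/* Scatter-add pooled gradients back to input positions. */
SEXP C_maxpool_bw(SEXP gout, SEXP argidx, SEXP nin_sexp)
{
    const R_xlen_t nin = (R_xlen_t) asReal(nin_sexp);
    const R_xlen_t nout = XLENGTH(gout);
    const double *g = REAL(gout);
    const double *ai = REAL(argidx);
    SEXP out = PROTECT(allocVector(REALSXP, nin));
    double *o = REAL(out);
    memset(o, 0, sizeof(double) * nin);
    for (R_xlen_t j = 0; j < nout; j++)
        o[(R_xlen_t) ai[j] - 1] += g[j];
    UNPROTECT(1);
    return out;
}
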