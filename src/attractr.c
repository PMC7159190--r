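#include <R.h>
#include <Rinternals.h>
#include <math.h>

/* Euler-Maruyama integration of dz = -V'(z) dt + sigma dW with polynomial
 * drift coefficients (ascending).  The Wiener increments are generated on
 * the R side so seed semantics stay with R's RNG.  Returns the (n + burn)
 * recorded samples; the first index where |z| exceeded `bound` (1-based,
 * 0 when none) is returned in `blow`. */
SEXP C_langevin_em(SEXP dcoef_, SEXP sigma_, SEXP z0_, SEXP nrec_,
                   SEXP substeps_, SEXP h_, SEXP dw_, SEXP bound_,
                   SEXP blow_)
{
    const double *dcoef = REAL(dcoef_);
    const int L = LENGTH(dcoef_);
    const double sigma = asReal(sigma_), h = asReal(h_),
                 bound = asReal(bound_);
    const int nrec = asInteger(nrec_), substeps = asInteger(substeps_);
    const double *dw = REAL(dw_);
    SEXP z_ = PROTECT(allocVector(REALSXP, nrec));
    double *z = REAL(z_);
    double cur = asReal(z0_);
    int *blow = INTEGER(blow_);
    blow[0] = 0;
    R_xlen_t ii = 0;
    for (int i = 0; i < nrec; i++) {
        for (int s = 0; s < substeps; s++) {
            /* Horner evaluation of V'(cur) */
            double drift = dcoef[L - 1];
            for (int k = L - 2; k >= 0; k--) drift = drift * cur + dcoef[k];
            cur += -drift * h + sigma * dw[ii++];
        }
        if (!R_FINITE(cur) || fabs(cur) > bound) {
            blow[0] = i + 1;
            break;
        }
        z[i] = cur;
    }
    UNPROTECT(1);
    return z_;
}

/* False-nearest-neighbour fraction at dimension `dim` with the Kennel
 * criteria; brute-force O(npts^2 dim) scan, first minimum wins ties. */
SEXP C_fnn_fraction(SEXP x_, SEXP npts_, SEXP delay_, SEXP dim_,
                    SEXP rtol_, SEXP atol_, SEXP ra_)
{
    const double *x = REAL(x_);
    const int npts = asInteger(npts_), delay = asInteger(delay_),
              dim = asInteger(dim_);
    const double rtol = asReal(rtol_), atol = asReal(atol_),
                 ra = asReal(ra_);
    const double zero = 1e-8 * ra;
    int nfalse = 0;
    for (int i = 0; i < npts; i++) {
        double best = R_PosInf;
        int nn = -1;
        for (int j = 0; j < npts; j++) {
            if (j == i) continue;
            double d2 = 0.0;
            for (int k = 0; k < dim; k++) {
                double d = x[i + k * delay] - x[j + k * delay];
                d2 += d * d;
                if (d2 >= best) break;
            }
            if (d2 < best) { best = d2; nn = j; }
        }
        double rd = sqrt(best);
        double extra = fabs(x[i + dim * delay] - x[nn + dim * delay]);
        int crit1 = (rd > zero) ? (extra / rd > rtol) : (extra > zero);
        int crit2 = sqrt(rd * rd + extra * extra) / ra > atol;
        if (crit1 || crit2) nfalse++;
    }
    return ScalarReal((double) nfalse / npts);
}

#include <R_ext/Rdynload.h>

static const R_CallMethodDef CallEntries[] = {
    {"C_langevin_em", (DL_FUNC) &C_langevin_em, 9},
    {"C_fnn_fraction", (DL_FUNC) &C_fnn_fraction, 7},
    {NULL, NULL, 0}
};

void R_init_attractr(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
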