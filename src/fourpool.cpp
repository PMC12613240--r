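#include <Rcpp.h>
using namespace Rcpp;

// Four-pool Lorentzian Z-spectrum model used for voxel-wise fitting.
//
// Z(w) = z0 - plateau - sum_i A_i * (G_i/2)^2 / ((G_i/2)^2 + (w - d_i)^2)
//
// Parameter vector layout (11 free parameters):
//   0..3  amplitudes   A_ds, A_amide, A_rnoe, A_ssmt
//   4..7  FWHM (ppm)   G_ds, G_amide, G_rnoe, G_ssmt
//   8     d_ds         DS centre (ppm); other centres fixed at
//                      +3.5 (amide), -3.5 (rNOE), -2.5 (ssMT)
//   9     plateau      constant added to the DS resonance
//   10    z0           baseline
static const double CENTERS_FIXED[3] = {3.5, -3.5, -2.5}; // amide, rnoe, ssmt

static inline void pool_centers(const double* par, double* d) {
    d[0] = par[8];
    d[1] = CENTERS_FIXED[0];
    d[2] = CENTERS_FIXED[1];
    d[3] = CENTERS_FIXED[2];
}

// [[Rcpp::export(name = ".fp_model")]]
NumericVector fp_model(NumericVector par, NumericVector w) {
    const int n = w.size();
    double d[4];
    pool_centers(par.begin(), d);
    NumericVector out(n);
    for (int j = 0; j < n; ++j) {
        double z = par[10] - par[9];
        for (int i = 0; i < 4; ++i) {
            const double g = par[4 + i] / 2.0;
            const double x = w[j] - d[i];
            z -= par[i] * g * g / (g * g + x * x);
        }
        out[j] = z;
    }
    return out;
}

// [[Rcpp::export(name = ".fp_sse")]]
double fp_sse(NumericVector par, NumericVector w, NumericVector y) {
    const int n = w.size();
    double d[4];
    pool_centers(par.begin(), d);
    double sse = 0.0;
    for (int j = 0; j < n; ++j) {
        double z = par[10] - par[9];
        for (int i = 0; i < 4; ++i) {
            const double g = par[4 + i] / 2.0;
            const double x = w[j] - d[i];
            z -= par[i] * g * g / (g * g + x * x);
        }
        const double r = z - y[j];
        sse += r * r;
    }
    return sse;
}

// [[Rcpp::export(name = ".fp_grad")]]
NumericVector fp_grad(NumericVector par, NumericVector w, NumericVector y) {
    const int n = w.size();
    double d[4];
    pool_centers(par.begin(), d);
    NumericVector grad(11);
    for (int j = 0; j < n; ++j) {
        double L[4], dLdG[4], x4[4], den4[4];
        double z = par[10] - par[9];
        for (int i = 0; i < 4; ++i) {
            const double g = par[4 + i] / 2.0;
            const double x = w[j] - d[i];
            const double den = g * g + x * x;
            L[i] = g * g / den;
            // dL/dG = (1/2) * 2 g x^2 / den^2
            dLdG[i] = g * x * x / (den * den);
            x4[i] = x;
            den4[i] = den;
            z -= par[i] * L[i];
        }
        const double r2 = 2.0 * (z - y[j]);
        for (int i = 0; i < 4; ++i) {
            grad[i]     += r2 * (-L[i]);
            grad[4 + i] += r2 * (-par[i] * dLdG[i]);
        }
        // DS centre: dZ/d(d_ds) = -A_ds * 2 g^2 x / den^2
        {
            const double g = par[4] / 2.0;
            grad[8] += r2 * (-par[0] * 2.0 * g * g * x4[0] / (den4[0] * den4[0]));
        }
        grad[9]  += r2 * (-1.0);
        grad[10] += r2;
    }
    return grad;
}
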