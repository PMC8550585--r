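#include <Rcpp.h>
using namespace Rcpp;

// Matrix-free product K p for the element-loop linear-elastic stiffness
// operator.  Per element I with neighbor nodes i and stored shape gradients
// g_i = grad(phi_i^I) evaluated at the element center:
//   eps   = sym(sum_i g_i (x) p_i)
//   sigma = lambda tr(eps) I + 2 mu eps
//   f_i  -= V_I sigma g_i
// K is symmetric negative semi-definite; rigid translations are in its
// nullspace because the stored gradients sum to zero per element.
//
// conn:  n_elems x W node indices (1-based; slots >= len are ignored)
// len:   per-row occupancy
// grads: n_elems x 3W, slot s holds (gx, gy, gz) at columns 3s..3s+2
// fixed: 1-based node indices projected out (input and output components
//        zeroed) so the operator stays symmetric on the free subspace
// [[Rcpp::export]]
NumericMatrix cpp_apply_stiffness(IntegerMatrix conn, IntegerVector len,
                                  NumericMatrix grads, NumericVector vol,
                                  double lambda, double mu,
                                  NumericMatrix p, IntegerVector fixed) {
    const int ne = conn.nrow();
    const int nn = p.nrow();
    NumericMatrix f(nn, 3);

    // work on a projected copy of p
    std::vector<double> px(nn), py(nn), pz(nn);
    for (int i = 0; i < nn; ++i) {
        px[i] = p(i, 0); py[i] = p(i, 1); pz[i] = p(i, 2);
    }
    for (int k = 0; k < fixed.size(); ++k) {
        int i = fixed[k] - 1;
        px[i] = 0.0; py[i] = 0.0; pz[i] = 0.0;
    }

    for (int e = 0; e < ne; ++e) {
        const int L = len[e];
        if (L < 1) continue;
        // displacement "gradient" G_ab = sum_i g_a p_b
        double G00 = 0, G01 = 0, G02 = 0,
               G10 = 0, G11 = 0, G12 = 0,
               G20 = 0, G21 = 0, G22 = 0;
        for (int s = 0; s < L; ++s) {
            const int i = conn(e, s) - 1;
            const double gx = grads(e, 3 * s);
            const double gy = grads(e, 3 * s + 1);
            const double gz = grads(e, 3 * s + 2);
            const double ux = px[i], uy = py[i], uz = pz[i];
            G00 += gx * ux; G01 += gx * uy; G02 += gx * uz;
            G10 += gy * ux; G11 += gy * uy; G12 += gy * uz;
            G20 += gz * ux; G21 += gz * uy; G22 += gz * uz;
        }
        // eps = sym(G), sigma = lambda tr(eps) I + 2 mu eps
        const double e00 = G00, e11 = G11, e22 = G22;
        const double e01 = 0.5 * (G01 + G10);
        const double e02 = 0.5 * (G02 + G20);
        const double e12 = 0.5 * (G12 + G21);
        const double ltr = lambda * (e00 + e11 + e22);
        const double s00 = ltr + 2.0 * mu * e00;
        const double s11 = ltr + 2.0 * mu * e11;
        const double s22 = ltr + 2.0 * mu * e22;
        const double s01 = 2.0 * mu * e01;
        const double s02 = 2.0 * mu * e02;
        const double s12 = 2.0 * mu * e12;
        const double V = vol[e];
        for (int s = 0; s < L; ++s) {
            const int i = conn(e, s) - 1;
            const double gx = grads(e, 3 * s);
            const double gy = grads(e, 3 * s + 1);
            const double gz = grads(e, 3 * s + 2);
            f(i, 0) -= V * (s00 * gx + s01 * gy + s02 * gz);
            f(i, 1) -= V * (s01 * gx + s11 * gy + s12 * gz);
            f(i, 2) -= V * (s02 * gx + s12 * gy + s22 * gz);
        }
    }
    for (int k = 0; k < fixed.size(); ++k) {
        int i = fixed[k] - 1;
        f(i, 0) = 0.0; f(i, 1) = 0.0; f(i, 2) = 0.0;
    }
    return f;
}

// Round a double vector through IEEE single precision (the optional
// reduced-precision state switch).
// [[Rcpp::export]]
NumericVector cpp_round_to_float(NumericVector x) {
    NumericVector out(x.size());
    for (R_xlen_t i = 0; i < x.size(); ++i)
        out[i] = static_cast<double>(static_cast<float>(x[i]));
    return out;
}
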