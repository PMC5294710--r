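#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Unpolarized Fresnel reflectance for a ray crossing from index n1 into n2
// with incidence cosine ci (> 0). On transmission, ct receives the cosine of
// the refracted angle; returns 1 (and ct = 0) under total internal reflection.
static double fresnel_reflectance(double n1, double n2, double ci, double &ct) {
    if (ci > 1.0) ci = 1.0;
    double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
    double st = n1 / n2 * si;
    if (st >= 1.0) { ct = 0.0; return 1.0; }
    ct = std::sqrt(1.0 - st * st);
    if (ci > 0.999999) { // normal incidence: avoid 0/0 in the oblique formulas
        double r = (n1 - n2) / (n1 + n2);
        return r * r;
    }
    double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
    double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
    return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein deflection cosine by inverse CDF (isotropic branch at g=0).
static inline double hg_cosine(double g, double u) {
    if (std::fabs(g) < 1e-8) return 2.0 * u - 1.0;
    double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
    return (1.0 + g * g - tmp * tmp) / (2.0 * g);
}

// Rotate the direction (ux, uy, uz) by deflection cosine `cost` and azimuth
// `phi` (standard multi-layer Monte Carlo update).
static inline void spin(double &ux, double &uy, double &uz,
                        double cost, double phi) {
    double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
    double cosp = std::cos(phi), sinp = std::sin(phi);
    if (std::fabs(uz) > 0.99999) {
        ux = sint * cosp;
        uy = sint * sinp;
        uz = cost * (uz >= 0.0 ? 1.0 : -1.0);
    } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nux = sint * (ux * uz * cosp - uy * sinp) / den + ux * cost;
        double nuy = sint * (uy * uz * cosp + ux * sinp) / den + uy * cost;
        double nuz = -sint * cosp * den + uz * cost;
        ux = nux; uy = nuy; uz = nuz;
    }
}

//' @title Low-level photon random-walk kernel
//' @description Launches `n_photons` SHG photons at depth `depth` (cm, from
//'   the objective-side surface) inside a homogeneous slab and random-walks
//'   them to the faces. All photons start in the axial direction given by
//'   `launch_dir` (+1 toward the condenser / bottom, -1 toward the
//'   objective / top), with the polar angle drawn uniformly in solid angle
//'   within the emission cone (`cos_emission_min` = cosine of the cone
//'   half-angle; 1 = collimated). Uses R's RNG stream.
//' @return List of summed weights: detected_forward, detected_backward,
//'   escaped_undetected, absorbed (true absorption plus the Russian-roulette
//'   net, so the four sinks sum to `launched` to machine precision),
//'   launched, detected_forward_unscattered (zero-collision forward weight,
//'   the collimated Beer-Lambert tally).
//' @keywords internal
// [[Rcpp::export]]
List mc_propagate_kernel(int n_photons, double depth, double thickness,
                         double mu_s, double mu_a, double g, double n_tissue,
                         double n_top, double n_bottom,
                         double cos_emission_min, int launch_dir,
                         double cos_accept_forward, double cos_accept_backward,
                         double roulette_threshold, double roulette_survival) {
    if (n_photons < 1) stop("n_photons must be >= 1");
    if (depth < 0.0 || depth > thickness) stop("depth outside slab");
    if (mu_s < 0.0 || mu_a < 0.0) stop("negative optical coefficient");
    if (g <= -1.0 || g >= 1.0) stop("anisotropy g must lie in (-1, 1)");
    if (roulette_survival <= 0.0 || roulette_survival >= 1.0)
        stop("roulette_survival must lie in (0, 1)");

    const double ACC_EPS = 1e-12;
    const double mu_t = mu_s + mu_a;
    double det_f = 0.0, det_b = 0.0, escaped = 0.0, absorbed = 0.0;
    double det_f_unscat = 0.0;

    for (int i = 0; i < n_photons; ++i) {
        double w = 1.0;
        double z = depth;
        // launch: uniform in solid angle within the emission cone
        double cost0 = (cos_emission_min >= 1.0)
            ? 1.0
            : cos_emission_min + (1.0 - cos_emission_min) * unif_rand();
        double sint0 = std::sqrt(std::max(0.0, 1.0 - cost0 * cost0));
        double phi0 = 2.0 * M_PI * unif_rand();
        double ux = sint0 * std::cos(phi0);
        double uy = sint0 * std::sin(phi0);
        double uz = launch_dir > 0 ? cost0 : -cost0;
        int n_scat = 0;
        bool alive = true;

        while (alive) {
            double s;
            if (mu_t > 0.0) {
                double u = unif_rand();
                while (u <= 0.0) u = unif_rand();
                s = -std::log(u) / mu_t;
            } else {
                s = R_PosInf;
            }
            double db = R_PosInf; // distance to the face ahead
            if (uz > 0.0)      db = (thickness - z) / uz;
            else if (uz < 0.0) db = -z / uz;

            if (db <= s) {
                // face interaction (fresh exponential after reflection is
                // statistically identical by memorylessness)
                bool bottom = uz > 0.0;
                double ci = std::fabs(uz);
                double n_out = bottom ? n_bottom : n_top;
                double ct;
                double R = fresnel_reflectance(n_tissue, n_out, ci, ct);
                if (unif_rand() < R) {
                    z = bottom ? thickness : 0.0;
                    uz = -uz;
                    continue;
                }
                if (bottom) {
                    if (ct >= cos_accept_forward - ACC_EPS) {
                        det_f += w;
                        if (n_scat == 0) det_f_unscat += w;
                    } else escaped += w;
                } else {
                    if (ct >= cos_accept_backward - ACC_EPS) det_b += w;
                    else escaped += w;
                }
                alive = false;
            } else {
                z += uz * s;
                // collision: deposit the absorbed fraction, then scatter
                if (mu_t > 0.0) {
                    absorbed += w * (mu_a / mu_t);
                    w *= mu_s / mu_t;
                }
                ++n_scat;
                double cost = hg_cosine(g, unif_rand());
                spin(ux, uy, uz, cost, 2.0 * M_PI * unif_rand());
                if (w < roulette_threshold) {
                    if (unif_rand() < roulette_survival) {
                        // bookkeeping keeps the tally exactly conservative:
                        // the boost is drawn from the absorbed sink
                        absorbed -= w * (1.0 / roulette_survival - 1.0);
                        w /= roulette_survival;
                    } else {
                        absorbed += w;
                        alive = false;
                    }
                }
            }
        }
    }

    return List::create(
        _["detected_forward"] = det_f,
        _["detected_backward"] = det_b,
        _["escaped_undetected"] = escaped,
        _["absorbed"] = absorbed,
        _["launched"] = (double)n_photons,
        _["detected_forward_unscattered"] = det_f_unscat);
}

//' @title Henyey-Greenstein deflection-cosine draws
//' @description Vector of `n` deflection cosines for anisotropy `g` using
//'   the inverse-CDF sampler shared with the transport kernel (R RNG stream).
//' @keywords internal
// [[Rcpp::export]]
NumericVector mc_sample_hg(int n, double g) {
    if (g <= -1.0 || g >= 1.0) stop("anisotropy g must lie in (-1, 1)");
    NumericVector out(n);
    for (int i = 0; i < n; ++i) out[i] = hg_cosine(g, unif_rand());
    return out;
}
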