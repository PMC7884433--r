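#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gaussian kernels are truncated at KERNEL_CUTOFF_SD standard deviations;
// the neglected tail weight is < 1.5e-8 of an individual kernel.
static const double KERNEL_CUTOFF_SD = 6.0;

static inline double per_locus_phenotype(int dosage, double dominance) {
    if (dosage <= 0) return 0.0;
    if (dosage >= 2) return 1.0;
    return dominance;
}

// one Mendelian gamete allele from a diploid dosage
static inline int transmit(int dosage) {
    if (dosage <= 0) return 0;
    if (dosage >= 2) return 1;
    return (unif_rand() < 0.5) ? 1 : 0;
}

static inline double reflect01(double x) {
    // reflecting boundaries at 0 and 1 (repeatedly if needed)
    while (x < 0.0 || x > 1.0) {
        if (x < 0.0) x = -x;
        if (x > 1.0) x = 2.0 - x;
    }
    return x;
}

// Advance the population one full (non-overlapping) generation.
// `loc` must be sorted ascending; `mat`/`neu` rows follow the same order.
// Every adult acts once as mother: she searches for a father among
// candidates drawn without replacement with probability proportional to a
// Gaussian encounter kernel, accepting each with pref_ratio^(dtrait^2);
// on success she produces Poisson(mu) offspring where mu follows
// Beverton-Holt regulation of the kernel-smoothed local density.
// [[Rcpp::export]]
List generation_core(NumericVector loc, IntegerMatrix mat, IntegerMatrix neu,
                     double dominance, double pref_ratio,
                     double density_sd, double dispersal_sd, double mate_sd,
                     double growth_rate, double carrying_capacity,
                     double hybrid_fitness, int max_mate_rejections) {
    const int n = loc.size();
    const int lm = mat.ncol();
    const int ln = neu.ncol();

    std::vector<double> trait(n);
    for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int l = 0; l < lm; ++l) s += per_locus_phenotype(mat(i, l), dominance);
        trait[i] = s / lm;
    }

    const double rho0 = 2.0 * carrying_capacity * density_sd * std::sqrt(2.0 * M_PI);
    const double dcut = KERNEL_CUTOFF_SD * density_sd;
    const double mcut = KERNEL_CUTOFF_SD * mate_sd;

    std::vector<double> oloc;
    std::vector<int> omat, oneu;
    oloc.reserve(2 * (size_t)carrying_capacity + 64);

    // scratch buffers for the mate-choice window
    std::vector<int> cand(n);
    std::vector<double> cw(n), cums(n);
    std::vector<char> tried(n);

    int dlo = 0, dhi = 0;   // density window  [dlo, dhi)
    int mlo = 0, mhi = 0;   // encounter window [mlo, mhi)

    for (int i = 0; i < n; ++i) {
        const double x = loc[i];

        // --- mate search ------------------------------------------------
        while (mlo < n && loc[mlo] < x - mcut) ++mlo;
        while (mhi < n && loc[mhi] <= x + mcut) ++mhi;

        int ncand = 0;
        double wtot = 0.0;
        for (int j = mlo; j < mhi; ++j) {
            if (j == i) continue;
            const double dx = (loc[j] - x) / mate_sd;
            const double w = std::exp(-0.5 * dx * dx);
            cand[ncand] = j;
            cw[ncand] = w;
            tried[ncand] = 0;
            wtot += w;
            ++ncand;
        }
        if (ncand == 0 && n > 1) {
            // no candidate inside the truncation window: the nearest
            // individual carries essentially all remaining kernel weight
            int j = (i == 0) ? 1 : (i == n - 1 ? n - 2 :
                    ((x - loc[i - 1] <= loc[i + 1] - x) ? i - 1 : i + 1));
            cand[0] = j; cw[0] = 1.0; tried[0] = 0;
            wtot = 1.0; ncand = 1;
        }

        int father = -1;
        if (ncand > 0) {
            int rejections = 0, ntried = 0;
            // cumulative weights for inverse-CDF draws
            double cum = 0.0;
            for (int k = 0; k < ncand; ++k) { cum += cw[k]; cums[k] = cum; }
            int guard = 0;
            const int guard_max = 50 * (max_mate_rejections + ncand + 10);
            while (rejections < max_mate_rejections && ntried < ncand) {
                if (++guard > guard_max) break;
                const double u = unif_rand() * wtot;
                int k = (int)(std::lower_bound(cums.begin(), cums.begin() + ncand, u) - cums.begin());
                if (k >= ncand) k = ncand - 1;
                if (tried[k]) continue;  // redraw = sampling without replacement
                tried[k] = 1;
                ++ntried;
                const double d = trait[i] - trait[cand[k]];
                const double p_acc = std::pow(pref_ratio, d * d);
                if (unif_rand() < p_acc) { father = cand[k]; break; }
                ++rejections;
            }
        }
        if (father < 0) continue;  // unmated this generation

        // --- density-regulated fecundity --------------------------------
        while (dlo < n && loc[dlo] < x - dcut) ++dlo;
        while (dhi < n && loc[dhi] <= x + dcut) ++dhi;
        double ksum = 0.0;
        for (int j = dlo; j < dhi; ++j) {
            const double dx = (loc[j] - x) / density_sd;
            ksum += std::exp(-0.5 * dx * dx);
        }
        const double edge = R::pnorm((1.0 - x) / density_sd, 0.0, 1.0, 1, 0) -
                            R::pnorm((0.0 - x) / density_sd, 0.0, 1.0, 1, 0);
        const double rho = ksum / edge;
        const double mu = hybrid_fitness * growth_rate /
                          (1.0 + (growth_rate - 1.0) * rho / rho0);
        const int noff = (int)R::rpois(mu);

        // --- offspring --------------------------------------------------
        for (int k = 0; k < noff; ++k) {
            for (int l = 0; l < lm; ++l)
                omat.push_back(transmit(mat(i, l)) + transmit(mat(father, l)));
            for (int l = 0; l < ln; ++l)
                oneu.push_back(transmit(neu(i, l)) + transmit(neu(father, l)));
            oloc.push_back(reflect01(x + norm_rand() * dispersal_sd));
        }
    }

    const int no = (int)oloc.size();
    NumericVector rloc(no);
    IntegerMatrix rmat(no, lm), rneu(no, ln);
    for (int i = 0; i < no; ++i) {
        rloc[i] = oloc[i];
        for (int l = 0; l < lm; ++l) rmat(i, l) = omat[(size_t)i * lm + l];
        for (int l = 0; l < ln; ++l) rneu(i, l) = oneu[(size_t)i * ln + l];
    }
    return List::create(_["location"] = rloc, _["mating"] = rmat,
                        _["neutral"] = rneu);
}
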