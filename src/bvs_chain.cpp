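#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gibbs sampler core for the spike-and-slab regression.
// Scan order per iteration: sigma2_eps, mu, (theta_j, alpha_j) for
// j = 1..p ascending, sigma2_alpha, pi.  Random draws go through R's RNG
// (R::rnorm etc.) in exactly the order of the pure-R reference engine in
// R/updates.R, so both engines produce the same chain from the same seed.
// Accumulations use long double to match R's sum()/colSums() arithmetic.

static inline double scaled_inv_chisq(double df, double scale) {
    return df * scale / R::rchisq(df);
}

// [[Rcpp::export(name = ".bvs_chain_cpp")]]
List bvs_chain_cpp(NumericMatrix X, NumericVector y, LogicalVector updatable,
                   List priors, List cfg, double muInit, double s2eInit) {
    const int n = X.nrow(), p = X.ncol();

    const double vEps = priors["vEps"], sEps = priors["sEps"];
    const double vAlpha = priors["vAlpha"], sAlpha = priors["sAlpha"];
    const double a0 = priors["a0"], b0 = priors["b0"];
    const bool shared = priors["sharedSlab"];
    NumericVector fixS2e = priors["fixSigma2Eps"];
    NumericVector fixS2a = priors["fixSigma2Alpha"];
    NumericVector fixPi = priors["fixPi"];
    NumericVector fixMu = priors["fixMu"];

    const int nIter = cfg["nIter"], burnIn = cfg["burnIn"];
    const int thin = cfg["thin"], recompute = cfg["recomputeResidEvery"];

    // sparse column storage: most dosage columns are mostly zero
    std::vector< std::vector<int> > idx(p);
    std::vector< std::vector<double> > val(p);
    std::vector<double> cjj(p);
    for (int j = 0; j < p; ++j) {
        long double acc = 0.0L;
        for (int i = 0; i < n; ++i) {
            double x = X(i, j);
            if (x != 0.0) {
                idx[j].push_back(i);
                val[j].push_back(x);
                acc += x * x;
            }
        }
        cjj[j] = (double) acc;
    }

    double mu = fixMu.size() ? fixMu[0] : muInit;
    double s2e = fixS2e.size() ? fixS2e[0] : s2eInit;
    double s2a0 = fixS2a.size() ? fixS2a[0] : sAlpha;
    std::vector<double> s2aLoc;
    if (!shared) s2aLoc.assign(p, s2a0);
    double pi = fixPi.size() ? fixPi[0] : a0 / (a0 + b0);

    std::vector<double> alpha(p, 0.0), r(n);
    std::vector<int> theta(p, 0);
    for (int i = 0; i < n; ++i) r[i] = y[i] - mu;
    int k = 0;

    std::vector<double> inclCount(p, 0.0), alphaSum(p, 0.0);
    std::vector<int> kSamples;
    std::vector<double> trMu, trS2e, trS2a, trPi;
    const int nKeep = (nIter - burnIn) / thin + 1;
    kSamples.reserve(nKeep);
    trMu.reserve(nKeep); trS2e.reserve(nKeep);
    trS2a.reserve(nKeep); trPi.reserve(nKeep);

    for (int it = 1; it <= nIter; ++it) {
        if (it % 256 == 0) Rcpp::checkUserInterrupt();

        if (!fixS2e.size()) {
            long double rss = 0.0L;
            for (int i = 0; i < n; ++i) rss += r[i] * r[i];
            double drss = (double) rss;
            if (!R_FINITE(drss)) stop("non-finite residual sum of squares");
            double df = vEps + n;
            s2e = scaled_inv_chisq(df, (vEps * sEps + drss) / df);
        }

        if (!fixMu.size()) {
            long double sr = 0.0L;
            for (int i = 0; i < n; ++i) sr += r[i];
            double m = mu + ((double) sr) / n;
            double muNew = R::rnorm(m, std::sqrt(s2e / n));
            double d = muNew - mu;
            for (int i = 0; i < n; ++i) r[i] -= d;
            mu = muNew;
        }

        // log-odds of inclusion: logit(pi) - log(v1/v0)/2
        //   + u^2 (1/v0 - 1/v1)/2, with v0 = cjj s2e, v1 = v0 + cjj^2 s2a
        // (identical expression to inclusionProbability() in R/updates.R)
        const double logitPi = std::log(pi) - std::log(1.0 - pi);
        for (int j = 0; j < p; ++j) {
            if (!updatable[j]) continue;
            const std::vector<int> &ij = idx[j];
            const std::vector<double> &vj = val[j];
            const int m = (int) ij.size();
            double s2aj = shared ? s2a0 : s2aLoc[j];

            if (theta[j] == 1) {
                double a = alpha[j];
                for (int t = 0; t < m; ++t) r[ij[t]] += a * vj[t];
            }
            long double uacc = 0.0L;
            for (int t = 0; t < m; ++t) uacc += vj[t] * r[ij[t]];
            double u = (double) uacc;

            double w = cjj[j] * s2aj;
            double lo = logitPi - 0.5 * std::log((s2e + w) / s2e) +
                0.5 * u * u * w / (cjj[j] * s2e * (s2e + w));
            double p1 = 1.0 / (1.0 + std::exp(-lo));

            int th = unif_rand() < p1 ? 1 : 0;
            double al = 0.0;
            if (th == 1) {
                double cj = cjj[j] + s2e / s2aj;
                al = R::rnorm(u / cj, std::sqrt(s2e / cj));
                if (!R_FINITE(al)) stop("non-finite effect draw");
                for (int t = 0; t < m; ++t) r[ij[t]] -= al * vj[t];
            }
            theta[j] = th;
            alpha[j] = al;
        }
        k = 0;
        for (int j = 0; j < p; ++j) k += theta[j];

        if (!fixS2a.size()) {
            if (shared) {
                long double ss = 0.0L;
                for (int j = 0; j < p; ++j)
                    if (theta[j] == 1) ss += alpha[j] * alpha[j];
                double df = vAlpha + k;
                s2a0 = scaled_inv_chisq(
                    df, (vAlpha * sAlpha + (double) ss) / df);
            } else {
                for (int j = 0; j < p; ++j) {
                    if (!updatable[j]) continue;
                    if (theta[j] == 1) {
                        double df = vAlpha + 1.0;
                        s2aLoc[j] = scaled_inv_chisq(
                            df, (vAlpha * sAlpha + alpha[j] * alpha[j]) / df);
                    } else {
                        s2aLoc[j] = scaled_inv_chisq(vAlpha, sAlpha);
                    }
                }
            }
        }

        if (!fixPi.size())
            pi = R::rbeta(a0 + k, b0 + (double) (p - k));

        if (it % recompute == 0) {
            for (int i = 0; i < n; ++i) r[i] = y[i] - mu;
            for (int j = 0; j < p; ++j) {
                if (theta[j] != 1) continue;
                double a = alpha[j];
                const std::vector<int> &ij = idx[j];
                const std::vector<double> &vj = val[j];
                for (size_t t = 0; t < ij.size(); ++t)
                    r[ij[t]] -= a * vj[t];
            }
        }

        if (it > burnIn && (it - burnIn) % thin == 0) {
            for (int j = 0; j < p; ++j) {
                if (theta[j] == 1) {
                    inclCount[j] += 1.0;
                    alphaSum[j] += alpha[j];
                }
            }
            kSamples.push_back(k);
            trMu.push_back(mu);
            trS2e.push_back(s2e);
            trS2a.push_back(shared ? s2a0 : NA_REAL);
            trPi.push_back(pi);
        }
    }

    return List::create(
        _["inclCount"] = NumericVector(inclCount.begin(), inclCount.end()),
        _["alphaSum"] = NumericVector(alphaSum.begin(), alphaSum.end()),
        _["kSamples"] = IntegerVector(kSamples.begin(), kSamples.end()),
        _["traceMu"] = NumericVector(trMu.begin(), trMu.end()),
        _["traceSigma2Eps"] = NumericVector(trS2e.begin(), trS2e.end()),
        _["traceSigma2Alpha"] = NumericVector(trS2a.begin(), trS2a.end()),
        _["tracePi"] = NumericVector(trPi.begin(), trPi.end()),
        _["finalMu"] = mu, _["finalSigma2Eps"] = s2e, _["finalPi"] = pi,
        _["finalResid"] = NumericVector(r.begin(), r.end()),
        _["finalTheta"] = IntegerVector(theta.begin(), theta.end()),
        _["finalAlpha"] = NumericVector(alpha.begin(), alpha.end()));
}
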