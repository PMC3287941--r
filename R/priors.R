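#' Specify priors for the spike-and-slab model
#'
#' The model for a quantitative trait y on n individuals and p SNPs is
#' \deqn{y = \mu 1 + X(\theta \circ \alpha) + \epsilon,}
#' with dosage matrix X, inclusion indicators \eqn{\theta_j \sim
#' Bern(\pi)}, slab effects \eqn{\alpha_j \sim N(0, \sigma^2_\alpha)},
#' residuals \eqn{\epsilon \sim N(0, \sigma^2_\epsilon I)}, scaled inverse
#' chi-square priors \eqn{\sigma^2_\alpha \sim ScInv\chi^2(v_\alpha,
#' S_\alpha)} and \eqn{\sigma^2_\epsilon \sim ScInv\chi^2(v_\epsilon,
#' S_\epsilon)}, and \eqn{\pi \sim Beta(a_0, b_0)}.
#'
#' @param sAlpha,vAlpha scale and degrees of freedom of the slab-variance
#'   prior (trait^2 per dosage^2 units).
#' @param sEps,vEps scale and degrees of freedom of the residual-variance
#'   prior (trait^2 units).
#' @param a0,b0 Beta prior parameters for the inclusion probability pi
#'   (default uniform).
#' @param fixSigma2Eps,fixSigma2Alpha,fixPi,fixMu optional fixed values
#'   (testing hooks); each disables the corresponding Gibbs update.
#' @param sharedSlab one slab variance pooled over all included effects
#'   (default) or one per locus.
#' @return A \linkS4class{BvsPriors} object.
#' @seealso [defaultPriors()] for data-scaled defaults.
#' @examples
#' bvsPriors(sAlpha = 0.05, sEps = 0.5)
#' @export
bvsPriors <- function(sAlpha = 1, vAlpha = 4, sEps = 1, vEps = 10,
                      a0 = 1, b0 = 1,
                      fixSigma2Eps = numeric(), fixSigma2Alpha = numeric(),
                      fixPi = numeric(), fixMu = numeric(),
                      sharedSlab = TRUE) {
    new("BvsPriors", sAlpha = sAlpha, vAlpha = vAlpha, sEps = sEps,
        vEps = vEps, a0 = a0, b0 = b0,
        fixSigma2Eps = as.numeric(fixSigma2Eps),
        fixSigma2Alpha = as.numeric(fixSigma2Alpha),
        fixPi = as.numeric(fixPi), fixMu = as.numeric(fixMu),
        sharedSlab = sharedSlab)
}

#' Weakly informative, scale-aware default priors
#'
#' Centres the residual-variance prior on half the phenotypic variance
#' (vEps = 10, sEps = var(y)/2) and the slab prior on the variance left for
#' an expected number of associated SNPs (vAlpha = 4, sAlpha =
#' var(y)/(2 * expectedK)).  All values can be overridden afterwards.
#'
#' @param y phenotype vector.
#' @param expectedK prior guess of the number of associated SNPs.
#' @param ... passed on to [bvsPriors()].
#' @return A \linkS4class{BvsPriors}.
#' @export
defaultPriors <- function(y, expectedK = 10, ...) {
    vy <- var(as.numeric(y))
    if (!is.finite(vy) || vy <= 0)
        stop("phenotype variance must be positive to scale default priors")
    bvsPriors(sAlpha = vy / (2 * expectedK), vAlpha = 4,
              sEps = vy / 2, vEps = 10, ...)
}

#' Configure a Gibbs chain
#'
#' Defaults follow the analysis protocol: 15,000 iterations with the first
#' 1,000 discarded as burn-in, no thinning.
#'
#' @param nIter total MCMC iterations.
#' @param burnIn iterations discarded before summarising.
#' @param thin keep every thin-th post-burn-in sample.
#' @param seed random seed for the chain.
#' @param recomputeResidEvery period of the full residual recomputation
#'   that guards the incremental updates against numerical drift.
#' @param engine "cpp" (compiled, default) or "R" (reference
#'   implementation); both consume the identical random stream.
#' @return A \linkS4class{BvsChainConfig}.
#' @export
bvsChainConfig <- function(nIter = 15000L, burnIn = 1000L, thin = 1L,
                           seed = 1L, recomputeResidEvery = 1000L,
                           engine = c("cpp", "R")) {
    new("BvsChainConfig", nIter = as.integer(nIter),
        burnIn = as.integer(burnIn), thin = as.integer(thin),
        seed = as.integer(seed),
        recomputeResidEvery = as.integer(recomputeResidEvery),
        engine = match.arg(engine))
}

setMethod("show", "BvsPriors", function(object) {
    f <- function(v) if (length(v)) sprintf("fixed at %g", v) else "sampled"
    cat("BvsPriors\n",
        sprintf("  slab:     ScInv-chi2(v = %g, S = %g), %s\n",
                object@vAlpha, object@sAlpha,
                if (object@sharedSlab) "shared" else "per-locus"),
        sprintf("  residual: ScInv-chi2(v = %g, S = %g)\n",
                object@vEps, object@sEps),
        sprintf("  pi ~ Beta(%g, %g) [%s]; sigma2_eps %s; sigma2_alpha %s\n",
                object@a0, object@b0, f(object@fixPi),
                f(object@fixSigma2Eps), f(object@fixSigma2Alpha)),
        sep = "")
    invisible(NULL)
})

setMethod("show", "BvsChainConfig", function(object) {
    cat(sprintf(
        "BvsChainConfig: %d iterations (%d burn-in, thin %d), seed %d, %s engine\n",
        object@nIter, object@burnIn, object@thin, object@seed, object@engine))
    invisible(NULL)
})
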