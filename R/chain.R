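#' Fit the spike-and-slab model by Gibbs sampling
#'
#' Runs one MCMC chain for the model \eqn{y = \mu 1 + X(\theta \circ
#' \alpha) + \epsilon} and summarises the retained post-burn-in samples.
#' The per-SNP posterior probability of association (PPA) is the
#' proportion of retained samples in which the SNP's inclusion indicator
#' equals 1; the posterior mean effect averages \eqn{\theta_j \alpha_j}
#' over retained samples (exactly 0 when excluded).
#'
#' Missing dosages are imputed to the SNP's mean observed dosage before
#' fitting.  Monomorphic SNPs (constant dosage) are excluded from the
#' updates, keep PPA 0, and are flagged in the returned fit.
#'
#' @param x genotypes: a \linkS4class{SnpExperiment}, or a numeric matrix
#'   with individuals as rows and SNPs as columns (entries 0/1/2 or NA).
#' @param y numeric phenotype vector, one entry per individual.
#' @param priors a \linkS4class{BvsPriors}; defaults to
#'   [defaultPriors()] scaled to var(y).
#' @param config a \linkS4class{BvsChainConfig}; defaults to 15,000
#'   iterations with 1,000 burn-in.
#' @return A \linkS4class{BvsFit}.
#' @examples
#' set.seed(7)
#' X <- matrix(rbinom(200 * 10, 2, 0.3), 200, 10)
#' y <- X[, 1] * 0.8 + rnorm(200)
#' fit <- runChain(X, y, config = bvsChainConfig(nIter = 2000, burnIn = 500))
#' head(ppa(fit))
#' @export
runChain <- function(x, y, priors = NULL, config = bvsChainConfig()) {
    X <- if (is(x, "SnpExperiment")) dosages(x, snpsAsRows = FALSE)
         else as.matrix(x)
    storage.mode(X) <- "double"
    y <- as.numeric(y)
    n <- nrow(X); p <- ncol(X)
    if (length(y) != n)
        stop("length of y (", length(y), ") must equal the number of ",
             "individuals (", n, ")")
    if (n < 2L) stop("need at least 2 individuals")
    if (any(!is.finite(y))) stop("phenotypes must be finite")
    if (p > 0L && is.null(colnames(X)))
        colnames(X) <- paste0("snp", seq_len(p))

    # p = 0 is allowed: the intercept-only conjugate model
    X <- imputeDosages(X)
    if (any(X < 0 | X > 2))
        stop("dosages must lie in [0, 2]")
    mono <- vapply(seq_len(p),
                   function(j) all(X[, j] == X[1L, j]), logical(1))
    if (p > 0L && all(mono))
        stop("all SNPs are monomorphic; nothing to fit")
    if (any(mono))
        message(sum(mono), " monomorphic SNP(s) excluded from updates")

    if (is.null(priors)) priors <- defaultPriors(y)
    validObject(priors); validObject(config)

    muInit <- sum(y) / n
    s2eInit <- var(y)
    set.seed(config@seed)

    if (config@engine == "cpp") {
        out <- .bvs_chain_cpp(
            X, y, !mono,
            list(vEps = priors@vEps, sEps = priors@sEps,
                 vAlpha = priors@vAlpha, sAlpha = priors@sAlpha,
                 a0 = priors@a0, b0 = priors@b0,
                 sharedSlab = priors@sharedSlab,
                 fixSigma2Eps = priors@fixSigma2Eps,
                 fixSigma2Alpha = priors@fixSigma2Alpha,
                 fixPi = priors@fixPi, fixMu = priors@fixMu),
            list(nIter = config@nIter, burnIn = config@burnIn,
                 thin = config@thin,
                 recomputeResidEvery = config@recomputeResidEvery),
            muInit, s2eInit)
        inclCount <- out$inclCount
        alphaSum <- out$alphaSum
        kSamples <- out$kSamples
        trace <- data.frame(mu = out$traceMu,
                            sigma2Eps = out$traceSigma2Eps,
                            sigma2Alpha = out$traceSigma2Alpha,
                            pi = out$tracePi)
    } else {
        state <- newChainState(X, y, priors, updatable = !mono)
        state$mu <- if (length(priors@fixMu)) priors@fixMu else muInit
        state$resid <- y - state$mu
        inclCount <- numeric(p); alphaSum <- numeric(p)
        kSamples <- integer(0)
        trMu <- trS2e <- trS2a <- trPi <- numeric(0)
        for (it in seq_len(config@nIter)) {
            state <- gibbsStep(state, X, y, priors)
            if (it %% config@recomputeResidEvery == 0L) {
                r <- y - state$mu
                for (j in which(state$theta == 1L))
                    r <- r - state$alpha[j] * X[, j]
                state$resid <- r
            }
            if (it > config@burnIn &&
                (it - config@burnIn) %% config@thin == 0L) {
                on <- state$theta == 1L
                inclCount[on] <- inclCount[on] + 1
                alphaSum[on] <- alphaSum[on] + state$alpha[on]
                kSamples <- c(kSamples, state$k)
                trMu <- c(trMu, state$mu)
                trS2e <- c(trS2e, state$sigma2Eps)
                trS2a <- c(trS2a, if (priors@sharedSlab)
                    state$sigma2Alpha else NA_real_)
                trPi <- c(trPi, state$pi)
            }
        }
        trace <- data.frame(mu = trMu, sigma2Eps = trS2e,
                            sigma2Alpha = trS2a, pi = trPi)
    }

    nRet <- length(kSamples)
    new("BvsFit", snpIds = as.character(colnames(X)),
        ppa = inclCount / nRet, alphaMean = alphaSum / nRet,
        kSamples = as.integer(kSamples), kPoint = modeSmallest(kSamples),
        nRetained = as.integer(nRet), monomorphic = mono,
        hyperTrace = trace, priors = priors, config = config)
}

imputeDosages <- function(X) {
    nas <- colSums(is.na(X))
    for (j in which(nas > 0L)) {
        obs <- X[, j][!is.na(X[, j])]
        X[is.na(X[, j]), j] <- if (length(obs)) sum(obs) / length(obs) else 0
    }
    X
}

# posterior mode; ties broken toward the smaller count (parsimony)
modeSmallest <- function(k) {
    tab <- tabulate(k + 1L)
    as.integer(which.max(tab) - 1L)
}

#' @describeIn runChain per-SNP posterior probability of association.
#' @export
setMethod("ppa", "BvsFit", function(x) setNames(x@ppa, x@snpIds))

#' @describeIn runChain per-SNP posterior mean effect (trait units per
#'   dosage unit; 0 contribution whenever the SNP is excluded).
#' @export
setMethod("effectMean", "BvsFit", function(x) setNames(x@alphaMean, x@snpIds))

#' @describeIn runChain retained posterior draws of the model size k.
#' @export
setMethod("kSamples", "BvsFit", function(x) x@kSamples)

#' @describeIn runChain posterior mode of k (ties toward the smaller k).
#' @export
setMethod("kPoint", "BvsFit", function(x) x@kPoint)

#' @describeIn runChain per-retained-sample trace of (mu, sigma2Eps,
#'   sigma2Alpha, pi); sigma2Alpha is NA in per-locus slab mode.
#' @export
setMethod("hyperTrace", "BvsFit", function(x) x@hyperTrace)

setMethod("show", "BvsFit", function(object) {
    cat(sprintf("BvsFit: %d SNPs, %d retained samples (seed %d)\n",
                length(object@snpIds), object@nRetained,
                object@config@seed))
    cat(sprintf("  k: point estimate %d, posterior mean %.2f\n",
                object@kPoint, mean(object@kSamples)))
    top <- order(object@ppa, decreasing = TRUE)[seq_len(min(
        5L, length(object@ppa)))]
    cat("  top PPA:\n")
    for (j in top)
        cat(sprintf("    %-12s ppa = %.3f  effect = %+.3f\n",
                    object@snpIds[j], object@ppa[j], object@alphaMean[j]))
    invisible(NULL)
})
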