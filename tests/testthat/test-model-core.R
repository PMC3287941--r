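test_that("residual-variance update follows its scaled inverse chi-square FCPF", {
    # r'r = 96 over n = 96, vEps = 4, sEps = 1 -> df = 100, scale = 1
    pr <- bvsPriors(sEps = 1, vEps = 4)
    r <- rep(1, 96)
    set.seed(1)
    draws <- replicate(1e5, sampleResidualVariance(r, pr))
    expect_true(all(draws > 0))
    expect_equal(mean(draws), scInvChisqMean(100, 1), tolerance = 0.003)
    expect_error(sampleResidualVariance(c(r, Inf), pr), "non-finite")
})

test_that("intercept update is Normal(mean residual, sigma2_eps/n)", {
    set.seed(2)
    # zero-sum case: mean exactly 0, variance 2/50
    y <- rnorm(50); y <- y - mean(y)
    d0 <- replicate(2e4, sampleIntercept(y, numeric(50), 2))
    expect_equal(mean(d0), 0, tolerance = 0.005)
    # constant residual 1 over n = 100, s2e = 1: Normal(1, 0.01)
    d1 <- replicate(1e5, sampleIntercept(rep(1, 100), numeric(100), 1))
    expect_equal(mean(d1), 1, tolerance = 0.002)
    expect_lt(abs(var(d1) - 0.01), 2e-4)
    expect_error(sampleIntercept(numeric(0), numeric(0), 1), "zero individuals")
})

test_that("inclusion probability: extremes, zero slab, independent value", {
    expect_identical(inclusionProbability(5, 10, 1, 0.5, 0), 0)
    expect_identical(inclusionProbability(5, 10, 1, 0.5, 1), 1)
    # zero slab variance makes both likelihoods equal: returns pi
    expect_equal(inclusionProbability(3, 20, 1.3, 0, 0.07), 0.07)
    # frozen from an independent high-precision evaluation of the two
    # zero-mean normal log-densities (variances 100 and 1100)
    expect_equal(inclusionProbability(30, 100, 1, 0.1, 0.1),
                 0.6670198389336623, tolerance = 1e-9)
    expect_error(inclusionProbability(1, 0, 1, 1, 0.5), "monomorphic")
    expect_error(inclusionProbability(1, 1, 1, 1, 1.5), "pi")
})

test_that("effect update: orthogonality and the flat-prior limit", {
    set.seed(3)
    n <- 120
    X <- cbind(c(rep(1, 60), rep(0, 60)), simGeno(n, 2))
    y <- rnorm(n)
    pr <- bvsPriors(fixPi = 0.999, sAlpha = 1)
    st <- newChainState(X, y, pr)
    st$pi <- 0.999999           # force near-certain inclusion
    # orthogonal residual: conditional effect mean is 0
    r <- c(rep(1, 30), rep(-1, 30), rnorm(60))
    st$resid <- r - X[, 1] * (sum(X[, 1] * r) / sum(X[, 1]^2))
    u <- sum(X[, 1] * st$resid)
    expect_lt(abs(u), 1e-8)
    draws <- replicate(5e3, {
        s <- sampleEffectAndIndicator(1, st, X)
        s$alpha[1]
    })
    expect_equal(mean(draws[draws != 0]), 0, tolerance = 0.01)
    # flat-prior limit: huge slab variance -> posterior mean -> OLS coef
    st2 <- newChainState(X, y, pr)
    st2$pi <- 0.999999
    st2$sigma2Alpha <- 1e12
    st2$sigma2Eps <- 1e-6       # tiny noise: draws concentrate on the mean
    ols <- sum(X[, 2] * st2$resid) / sum(X[, 2]^2)
    s <- sampleEffectAndIndicator(2, st2, X)
    expect_equal(s$alpha[2], ols, tolerance = 1e-2)
})

test_that("incremental residual matches from-scratch recomputation", {
    set.seed(4)
    n <- 200; p <- 50
    X <- simGeno(n, p)
    y <- X[, 5] * 0.8 - X[, 20] * 0.6 + rnorm(n)
    pr <- defaultPriors(y)
    st <- newChainState(X, y, pr)
    for (i in 1:200) st <- gibbsStep(st, X, y, pr)
    ref <- y - st$mu - drop(X %*% (st$theta * st$alpha))
    expect_lt(max(abs(st$resid - ref)) / (1 + max(abs(y))), 1e-8)
    expect_identical(st$k, sum(st$theta))
})

test_that("slab-variance update: empty-model reduction and stated scale", {
    pr <- bvsPriors(sAlpha = 0.5, vAlpha = 6)
    set.seed(5)
    # k = 0: draw from the prior ScInv-chi2(6, 0.5), mean 0.75
    d0 <- replicate(5e4, sampleSlabVariance(numeric(3), integer(3), pr))
    expect_equal(mean(d0), scInvChisqMean(6, 0.5), tolerance = 0.02)
    # included effects {1, -1}, vAlpha = 4, sAlpha = 0.5:
    # df = 6, scale = (2 + 2)/6 = 2/3, mean 1
    pr2 <- bvsPriors(sAlpha = 0.5, vAlpha = 4)
    d1 <- replicate(1e5, sampleSlabVariance(c(1, -1, 9), c(1L, 1L, 0L), pr2))
    expect_equal(mean(d1), 1, tolerance = 0.02)
    # per-locus mode returns one variance per SNP
    pr3 <- bvsPriors(sAlpha = 0.5, vAlpha = 6, sharedSlab = FALSE)
    v <- sampleSlabVariance(c(1, 0, 0), c(1L, 0L, 0L), pr3)
    expect_length(v, 3)
    expect_true(all(v > 0))
})

test_that("pi update draws from Beta(a0 + k, b0 + p - k)", {
    pr <- bvsPriors(a0 = 1, b0 = 1)
    set.seed(6)
    d <- replicate(1e5, samplePi(3, 97, pr))
    expect_lt(abs(mean(d) - 0.04), 0.001)
    expect_error(samplePi(5, 3, pr), "k must lie")
    # all-included with uniform prior: Beta(p + 1, 1), mean (p+1)/(p+2)
    d2 <- replicate(2e4, samplePi(10, 10, pr))
    expect_equal(mean(d2), 11 / 12, tolerance = 0.003)
})

test_that("the two engines consume one random stream and agree exactly", {
    set.seed(7)
    X <- simGeno(150, 25)
    y <- 0.7 * X[, 4] + rnorm(150)
    for (shared in c(TRUE, FALSE)) {
        pr <- defaultPriors(y, sharedSlab = shared)
        cfgC <- bvsChainConfig(nIter = 1500, burnIn = 300, seed = 42,
                               engine = "cpp")
        cfgR <- bvsChainConfig(nIter = 1500, burnIn = 300, seed = 42,
                               engine = "R")
        f1 <- runChain(X, y, pr, cfgC)
        f2 <- runChain(X, y, pr, cfgR)
        expect_identical(ppa(f1), ppa(f2))
        expect_identical(kSamples(f1), kSamples(f2))
        expect_equal(effectMean(f1), effectMean(f2), tolerance = 1e-12)
        expect_equal(hyperTrace(f1)$sigma2Eps, hyperTrace(f2)$sigma2Eps,
                     tolerance = 1e-12)
    }
})

test_that("retention bookkeeping: PPA is the inclusion proportion", {
    set.seed(8)
    X <- simGeno(100, 10)
    y <- X[, 1] + rnorm(100)
    f <- runChain(X, y, config = bvsChainConfig(nIter = 2000, burnIn = 400,
                                                thin = 4, seed = 2))
    expect_identical(f@nRetained, 400L)
    # every ppa is an integer count over nRetained
    expect_true(all(abs(ppa(f) * f@nRetained -
                        round(ppa(f) * f@nRetained)) < 1e-9))
    # sum of PPAs equals the mean of the k draws exactly
    expect_equal(sum(ppa(f)), mean(kSamples(f)), tolerance = 1e-12)
    expect_true(all(ppa(f) >= 0 & ppa(f) <= 1))
})

test_that("raising fixed pi never lowers the mean posterior model size", {
    set.seed(9)
    X <- simGeno(120, 15)
    y <- 0.5 * X[, 2] + rnorm(120)
    meanK <- vapply(c(0.02, 0.1, 0.3), function(pp) {
        ks <- vapply(1:3, function(s) {
            pr <- defaultPriors(y, fixPi = pp)
            mean(kSamples(runChain(X, y, pr,
                bvsChainConfig(nIter = 2000, burnIn = 400, seed = s))))
        }, numeric(1))
        mean(ks)
    }, numeric(1))
    expect_true(all(diff(meanK) >= 0))
})

test_that("degenerate inputs: monomorphic columns, NAs, bad configs", {
    set.seed(10)
    X <- cbind(simGeno(60, 4), 0, 2)   # two monomorphic columns
    y <- rnorm(60)
    expect_message(f <- runChain(X, y,
        config = bvsChainConfig(nIter = 500, burnIn = 100, seed = 1)),
        "monomorphic")
    expect_identical(unname(ppa(f)[5:6]), c(0, 0))
    expect_identical(f@monomorphic, c(rep(FALSE, 4), TRUE, TRUE))
    # NA dosages are imputed, not fatal
    X2 <- simGeno(60, 3); X2[1:5, 2] <- NA
    expect_s4_class(runChain(X2, y,
        config = bvsChainConfig(nIter = 300, burnIn = 50, seed = 1)),
        "BvsFit")
    expect_error(runChain(matrix(1, 60, 2), y,
        config = bvsChainConfig(nIter = 300, burnIn = 50)), "monomorphic")
    expect_error(runChain(X, rnorm(10)), "must equal")
    expect_error(bvsChainConfig(nIter = 100, burnIn = 100), "burnIn")
    expect_error(bvsPriors(sEps = -1), "positive")
    expect_error(bvsPriors(fixPi = 1.2), "fixPi")
})

test_that("identical seed and inputs reproduce the fit exactly", {
    set.seed(11)
    X <- simGeno(80, 8)
    y <- X[, 3] * 0.6 + rnorm(80)
    cfg <- bvsChainConfig(nIter = 1000, burnIn = 200, seed = 99)
    f1 <- runChain(X, y, config = cfg)
    f2 <- runChain(X, y, config = cfg)
    expect_identical(ppa(f1), ppa(f2))
    expect_identical(effectMean(f1), effectMean(f2))
    expect_identical(kSamples(f1), kSamples(f2))
    expect_identical(hyperTrace(f1), hyperTrace(f2))
})
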