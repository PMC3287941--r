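test_that("prior extreme pi = 0 puts all weight on the empty model", {
    set.seed(20)
    X <- simGeno(50, 4)
    y <- rnorm(50)
    o <- enumeratePosterior(X, y, 1, 0.5, 0)
    expect_equal(unname(o@kDist["0"]), 1)
    expect_true(all(ppa(o) == 0))
    expect_equal(sum(o@weights), 1, tolerance = 1e-12)
})

test_that("p = 1 matches the hand-computed two-model Bayes factor", {
    set.seed(21)
    for (rep in 1:5) {
        x <- rbinom(80, 2, runif(1, 0.1, 0.4))
        y <- 0.4 * x + rnorm(80)
        s2e <- runif(1, 0.5, 2); s2a <- runif(1, 0.1, 1)
        pp <- runif(1, 0.02, 0.5)
        o <- enumeratePosterior(matrix(x, 80, 1), y, s2e, s2a, pp)
        expect_equal(unname(ppa(o)), ppaSingleSnp(x, y, s2e, s2a, pp),
                     tolerance = 1e-10)
    }
})

test_that("a zero column has no likelihood: its PPA equals pi", {
    set.seed(22)
    X <- simGeno(60, 5)
    y <- 0.6 * X[, 1] + rnorm(60)
    o1 <- enumeratePosterior(X, y, 1, 0.4, 0.15)
    o2 <- enumeratePosterior(cbind(X, zero = 0), y, 1, 0.4, 0.15)
    expect_equal(unname(ppa(o2)[6]), 0.15, tolerance = 1e-10)
    expect_equal(unname(ppa(o2)[1:5]), unname(ppa(o1)), tolerance = 1e-10)
})

test_that("a duplicated causal column splits inclusion mass", {
    set.seed(23)
    X <- simGeno(100, 4)
    y <- 0.9 * X[, 2] + rnorm(100, 0, 0.7)
    Xd <- cbind(X, dup = X[, 2])
    o <- enumeratePosterior(Xd, y, 0.5, 0.5, 0.1)
    pA <- ppa(o)[2]; pB <- ppa(o)[5]
    union <- sum(o@weights[o@models[, 2] == 1L | o@models[, 5] == 1L])
    expect_gt(union, pA)
    expect_gt(union, pB)
})

test_that("model weights are a distribution consistent with PPA and k", {
    set.seed(24)
    X <- simGeno(40, 6)
    y <- rnorm(40)
    o <- enumeratePosterior(X, y, 1.2, 0.3, 0.2)
    expect_equal(sum(o@weights), 1, tolerance = 1e-12)
    expect_equal(sum(o@kDist), 1, tolerance = 1e-12)
    # E[k] two ways: sum of PPAs and expectation of the k distribution
    expect_equal(sum(ppa(o)),
                 sum(as.numeric(names(o@kDist)) * o@kDist),
                 tolerance = 1e-10)
    expect_error(enumeratePosterior(simGeno(10, 15), rnorm(10), 1, 1, 0.1),
                 "p <= 14")
})
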