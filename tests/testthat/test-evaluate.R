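test_that("averaging a single replicate returns its values and sort order", {
    f <- makeFit(ppa = c(0.9, 0.2, 0.5), alphaMean = c(-1.2, 0.1, 0.6),
                 kPoint = 2L)
    a <- averageOverReplicates(list(f))
    expect_equal(a@table$mean_ppa, c(0.9, 0.2, 0.5))
    expect_equal(a@table$mean_abs_coef, c(1.2, 0.1, 0.6))
    expect_identical(a@table$rank_ppa, c(1L, 3L, 2L))
    expect_identical(a@table$rank_coef, c(1L, 3L, 2L))
    expect_identical(a@kPoints, 2L)
})

test_that("symmetric replicates average to a tie broken by SNP index", {
    f1 <- makeFit(ppa = c(0.9, 0.1), alphaMean = c(0.5, -0.1))
    f2 <- makeFit(ppa = c(0.1, 0.9), alphaMean = c(0.1, -0.5))
    a <- averageOverReplicates(list(f1, f2))
    expect_equal(a@table$mean_ppa, c(0.5, 0.5))
    expect_identical(a@table$rank_ppa, c(1L, 2L))   # index breaks the tie
    bad <- makeFit(ppa = 0.5, alphaMean = 0, ids = "other")
    expect_error(averageOverReplicates(list(f1, bad)), "SNP set")
    expect_error(averageOverReplicates(list()), "no replicate")
})

test_that("ranks are a permutation of 1..p on random instances", {
    set.seed(50)
    for (i in 1:10) {
        p <- sample(2:40, 1)
        fits <- lapply(1:3, function(r)
            makeFit(ppa = runif(p), alphaMean = rnorm(p)))
        a <- averageOverReplicates(fits)
        expect_identical(sort(a@table$rank_ppa), seq_len(p))
        expect_identical(sort(a@table$rank_coef), seq_len(p))
    }
})

test_that("the k-range calling rule uses the range maximum under both scores", {
    fits <- list(makeFit(ppa = c(0.9, 0.8, 0.1, 0.3), alphaMean = c(2, 1, 0, 0.5), kPoint = 3L),
                 makeFit(ppa = c(0.7, 0.9, 0.2, 0.1), alphaMean = c(1, 2, 0.5, 0), kPoint = 8L),
                 makeFit(ppa = c(0.8, 0.7, 0.1, 0.1), alphaMean = c(2, 1, 0, 0), kPoint = 5L))
    cl <- callAssociated(averageOverReplicates(fits))
    expect_identical(cl$kRange, c(3L, 8L))
    expect_identical(cl$threshold, 8L)
    expect_true(all(cl$table$called))   # p = 4 <= threshold 8
    # constant k collapses the range
    fits2 <- lapply(1:3, function(i)
        makeFit(ppa = c(0.9, 0.5, 0.1), alphaMean = c(1, 0.5, 0),
                kPoint = 1L))
    cl2 <- callAssociated(averageOverReplicates(fits2))
    expect_identical(cl2$kRange, c(1L, 1L))
    expect_identical(cl2$table$called, c(TRUE, FALSE, FALSE))
    # conjunction: a SNP top-ranked under only one score is not called
    fd <- makeFit(ppa = c(0.9, 0.1), alphaMean = c(0.01, 2), kPoint = 1L)
    cl3 <- callAssociated(averageOverReplicates(list(fd)))
    expect_identical(cl3$table$called, c(FALSE, FALSE))
    expect_identical(callAssociated(averageOverReplicates(list(fd)),
                                    rule = "ppa")$table$called,
                     c(TRUE, FALSE))
})

test_that("ROC worked examples match brute-force pair counting", {
    r <- rocCurve(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0))
    expect_equal(auc(r), 0.75)
    expect_equal(auc(r), concordanceAuc(c(0.9, 0.8, 0.4, 0.2),
                                        c(1, 0, 1, 0)))
    # perfect separation, pure ties, reversal
    expect_equal(auc(rocCurve(c(5, 4, 1, 0), c(1, 1, 0, 0))), 1)
    expect_equal(auc(rocCurve(rep(2, 6), c(1, 0, 1, 0, 0, 1))), 0.5)
    s <- c(0.3, 0.9, 0.1, 0.6); t <- c(0, 1, 1, 0)
    expect_equal(auc(rocCurve(-s, t)), 1 - auc(rocCurve(s, t)))
    # curve anchors and monotonicity
    pts <- rocPoints(r)
    expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
    expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
    expect_true(!is.unsorted(pts$tpr) && !is.unsorted(pts$fpr))
    expect_error(rocCurve(1:3, c(1, 1, 1)), "undefined ROC")
})

test_that("trapezoidal AUC equals pairwise concordance on random instances", {
    set.seed(51)
    for (i in 1:25) {
        p <- sample(4:50, 1)
        scores <- sample(round(runif(p), 2))   # duplicates likely
        truth <- as.logical(rbinom(p, 1, 0.4))
        if (!any(truth) || all(truth)) next
        expect_equal(auc(rocCurve(scores, truth)),
                     concordanceAuc(scores, truth), tolerance = 1e-12)
    }
})

test_that("ROC is invariant to strictly increasing score transforms", {
    set.seed(52)
    scores <- runif(30); truth <- rbinom(30, 1, 0.3)
    truth[1] <- 1; truth[2] <- 0
    r1 <- rocCurve(scores, truth)
    r2 <- rocCurve(exp(3 * scores) + 7, truth)
    expect_equal(auc(r1), auc(r2), tolerance = 1e-12)
    expect_equal(rocPoints(r1)$tpr, rocPoints(r2)$tpr)
    expect_equal(rocPoints(r1)$fpr, rocPoints(r2)$fpr)
})

test_that("the rare-subset ROC restricts both rates to the admitted SNPs", {
    set.seed(53)
    p <- 40
    scores <- runif(p); truth <- rbinom(p, 1, 0.3)
    truth[1:2] <- c(1, 0)
    maf <- runif(p, 0.001, 0.2)
    # threshold 1.0 admits everything: identical to the all-SNP ROC
    expect_equal(auc(rareSubsetRoc(scores, truth, maf, 1.0)),
                 auc(rocCurve(scores, truth)))
    # below the minimum MAF the subset is empty
    expect_error(rareSubsetRoc(scores, truth, maf, min(maf) / 2),
                 "undefined ROC")
    keep <- maf < 0.01
    if (any(truth[keep] == 1) && any(truth[keep] == 0)) {
        rs <- rareSubsetRoc(scores, truth, maf, 0.01)
        expect_equal(auc(rs), concordanceAuc(scores[keep], truth[keep]),
                     tolerance = 1e-12)
    }
    expect_error(rareSubsetRoc(scores, truth, maf[-1]), "every SNP")
})
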