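test_that("dosages follow Hardy-Weinberg moments at known MAF", {
    # pin the MAF near 0.1 and check the observed frequency
    d <- simDesign(nIndividuals = 10000L, nSnps = 3L,
                   mafRange = c(0.0999999, 0.1000001), rareFraction = 0,
                   nGenes = 1L, seed = 31)
    g <- simulateGenotypes(d)
    obs <- rowMeans(dosages(g)) / 2
    expect_true(all(abs(obs - 0.1) < 0.006))
    # MAF 0.5: mean dosage 1, variance 2pq = 0.5
    d2 <- simDesign(nIndividuals = 20000L, nSnps = 1L,
                    mafRange = c(0.4999, 0.49999), rareFraction = 0,
                    nGenes = 1L, seed = 32)
    x <- dosages(simulateGenotypes(d2))[1, ]
    expect_equal(mean(x), 1, tolerance = 0.02)
    expect_equal(var(x), 0.5, tolerance = 0.02)
})

test_that("the rare-variant regime reaches realistic carrier counts", {
    # MAF 0.002152 at n = 697: about 3 carrier alleles expected per SNP
    d <- simDesign(nIndividuals = 697L, nSnps = 200L,
                   mafRange = c(0.0021519, 0.0021521), rareFraction = 1,
                   nGenes = 1L, seed = 33)
    g <- simulateGenotypes(d)
    expect_equal(mean(rowSums(dosages(g))), 2 * 697 * 0.002152,
                 tolerance = 0.2)
})

test_that("a fixed seed reproduces genotypes and replicates bit-identically", {
    d <- gawPreset("q4", nSnps = 80, nIndividuals = 60, nReplicates = 4,
                   seed = 34)
    g1 <- simulateGenotypes(d); g2 <- simulateGenotypes(d)
    expect_identical(dosages(g1), dosages(g2))
    Y1 <- simulatePhenotypes(g1, d); Y2 <- simulatePhenotypes(g2, d)
    expect_identical(Y1, Y2)
    # replication structure: one genotype matrix, fresh noise per replicate
    expect_gt(min(dist(t(Y1))), 0)
    expect_false(identical(Y1[, 1], Y1[, 2]))
})

test_that("trait presets carry the advertised causal architecture", {
    g1 <- simulateGenotypes(gawPreset("q1", nIndividuals = 80, seed = 35))
    tt1 <- truthTable(g1)
    expect_identical(sum(tt1$is_causal), 39L)
    expect_identical(length(unique(tt1$gene[tt1$is_causal])), 9L)
    expect_true(all(tt1$true_beta[!tt1$is_causal] == 0))
    expect_true(all(tt1$true_beta[tt1$is_causal] != 0))

    g2 <- simulateGenotypes(gawPreset("q2", nIndividuals = 80, seed = 36))
    tt2 <- truthTable(g2)
    expect_identical(sum(tt2$is_causal), 72L)
    expect_identical(length(unique(tt2$gene[tt2$is_causal])), 13L)

    g4 <- simulateGenotypes(gawPreset("q4", nSnps = 50, nIndividuals = 40,
                                      seed = 37))
    expect_identical(sum(truthTable(g4)$is_causal), 0L)

    gs <- simulateGenotypes(gawPreset("q1scaled", seed = 38))
    tts <- truthTable(gs)
    expect_identical(sum(tts$is_causal), 10L)
    expect_identical(sum(tts$is_causal & tts$true_maf < 0.01), 5L)
})

test_that("phenotype replicates hit the target heritability on average", {
    d <- gawPreset("q1", nIndividuals = 300, nReplicates = 50, seed = 39)
    g <- simulateGenotypes(d)
    Y <- simulatePhenotypes(g, d)
    expect_identical(dim(Y), c(300L, 50L))
    expect_lt(abs(mean(attr(Y, "realizedH2")) - 0.4), 0.03)
})

test_that("null preset phenotypes are pure noise and design errors surface", {
    d <- gawPreset("q4", nSnps = 60, nIndividuals = 500, nReplicates = 3,
                   seed = 40)
    g <- simulateGenotypes(d)
    Y <- simulatePhenotypes(g, d)
    expect_equal(mean(Y), 0, tolerance = 0.1)
    expect_equal(var(Y[, 1]), 1, tolerance = 0.15)
    # h2 > 0 without causal SNPs is contradictory
    dBad <- simDesign(nIndividuals = 50, nSnps = 20, nGenes = 2, h2 = 0.4,
                      seed = 41)
    gBad <- simulateGenotypes(dBad)
    expect_error(simulatePhenotypes(gBad, dBad), "h2 > 0 requires")
    # rare fraction impossible when the MAF range excludes rare SNPs
    expect_error(simulateGenotypes(
        simDesign(nSnps = 10, mafRange = c(0.05, 0.4), rareFraction = 0.5,
                  nGenes = 1, seed = 42)), "rareFraction")
    expect_error(simDesign(mafRange = c(0.2, 0.1)), "mafRange")
    expect_error(simDesign(h2 = 1.2), "h2")
})

test_that("the duplicate-column injector creates a perfect-LD non-causal twin", {
    d <- gawPreset("q1scaled", nSnps = 200, seed = 43)
    d@causalSpec <- data.frame(gene = 5L, nCausal = 2L)
    g <- simulateGenotypes(d)
    causal <- rownames(g)[which(isCausal(g))[1]]
    g2 <- injectDuplicateColumn(g, causal)
    j <- match(causal, rownames(g2))
    expect_identical(nrow(g2), nrow(g) + 1L)
    expect_identical(unname(dosages(g2)[j, ]), unname(dosages(g2)[j + 1L, ]))
    expect_false(isCausal(g2)[j + 1L])
    expect_true(isCausal(g2)[j])
})
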