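# Shared fixtures and independent oracles for the test suite.

# small genotype matrix under HWE, individuals x SNPs
simGeno <- function(n, p, maf = runif(p, 0.05, 0.4)) {
    vapply(maf, function(m) rbinom(n, 2L, m), numeric(n))
}

# independent AUC oracle: brute-force pairwise concordance, ties = 1/2
concordanceAuc <- function(scores, truth) {
    truth <- as.logical(truth)
    pos <- scores[truth]
    neg <- scores[!truth]
    tot <- 0
    for (a in pos)
        for (b in neg)
            tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
}

# independent p = 1 enumeration: two-model Bayes factor from scalar
# normal densities via the matrix determinant lemma / Sherman-Morrison
ppaSingleSnp <- function(x, y, s2e, s2a, priorInc) {
    n <- length(y)
    y <- y - mean(y)
    c1 <- sum(x * x)
    ll0 <- sum(dnorm(y, 0, sqrt(s2e), log = TRUE))
    logdet <- (n - 1) * log(s2e) + log(s2e + s2a * c1)
    quad <- sum(y * y) / s2e -
        s2a * sum(x * y)^2 / (s2e * (s2e + s2a * c1))
    ll1 <- -0.5 * (n * log(2 * base::pi) + logdet + quad)
    num <- log(priorInc) + ll1
    den <- log(1 - priorInc) + ll0
    1 / (1 + exp(den - num))
}

# a tiny VCF: 3 biallelic sites (one with missing ID and a ./. call),
# 1 multi-allelic site that must be skipped
writeTestVcf <- function(path) {
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##contig=<ID=1,length=1000>",
        '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", "s1", "s2", "s3", sep = "\t"),
        paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
              "0/0", "0/1", "1/1", sep = "\t"),
        paste("1", "200", ".", "C", "T", ".", "PASS", ".", "GT",
              "0|0", "./.", "1|1", sep = "\t"),
        paste("1", "300", "rs3", "G", "A", ".", "PASS", ".", "GT",
              "1/0", "0/0", "0/0", sep = "\t"),
        paste("1", "400", "rs4", "T", "A,C", ".", "PASS", ".", "GT",
              "1/2", "0/0", "0/1", sep = "\t")), path)
    path
}

# assemble a BvsFit by hand (for evaluation-layer tests)
makeFit <- function(ppa, alphaMean, kPoint = 1L,
                    ids = paste0("s", seq_along(ppa))) {
    new("BvsFit", snpIds = ids, ppa = ppa, alphaMean = alphaMean,
        kSamples = rep(as.integer(kPoint), 10L),
        kPoint = as.integer(kPoint), nRetained = 10L,
        monomorphic = rep(FALSE, length(ppa)),
        hyperTrace = data.frame(),
        priors = bvsPriors(), config = bvsChainConfig())
}

# moments of the scaled inverse chi-square distribution
scInvChisqMean <- function(df, scale) df * scale / (df - 2)
scInvChisqVar <- function(df, scale)
    2 * df^2 * scale^2 / ((df - 2)^2 * (df - 4))
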