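#' Simulation design for a mini-exome with replicated phenotypes
#'
#' Describes a fixed genotype matrix of unrelated individuals (dosages
#' Binomial(2, MAF) under Hardy-Weinberg equilibrium, independent SNPs,
#' MAFs log-uniform over \code{mafRange} with a forced fraction of rare
#' SNPs below 1\%), SNPs partitioned into contiguous gene blocks, a causal
#' architecture (\code{causalSpec}: how many causal SNPs per gene, and how
#' many of them must be rare), and \code{nReplicates} phenotype vectors
#' re-drawn over the same genotypes: \eqn{y_r = X\beta + \epsilon_r},
#' with \eqn{\beta} scaled so that Var(X beta)/Var(y) equals \code{h2} in
#' expectation.
#'
#' @export
setClass("SimDesign", representation(
    nIndividuals = "integer", nSnps = "integer", mafRange = "numeric",
    rareFraction = "numeric", nGenes = "integer", causalSpec = "data.frame",
    h2 = "numeric", nReplicates = "integer", effectRange = "numeric",
    effectMode = "character", seed = "integer"))

setValidity("SimDesign", function(object) {
    msg <- character()
    mr <- object@mafRange
    if (length(mr) != 2L || mr[1] <= 0 || mr[1] > mr[2] || mr[2] >= 0.5)
        msg <- c(msg, "mafRange must satisfy 0 < lower <= upper < 0.5")
    if (object@rareFraction < 0 || object@rareFraction > 1)
        msg <- c(msg, "rareFraction must lie in [0, 1]")
    if (object@h2 < 0 || object@h2 >= 1)
        msg <- c(msg, "h2 must lie in [0, 1)")
    if (object@nIndividuals < 2L || object@nSnps < 1L || object@nGenes < 1L)
        msg <- c(msg, "need nIndividuals >= 2, nSnps >= 1, nGenes >= 1")
    if (object@nGenes > object@nSnps)
        msg <- c(msg, "more gene blocks than SNPs")
    cs <- object@causalSpec
    if (nrow(cs) &&
        !all(c("gene", "nCausal") %in% names(cs)))
        msg <- c(msg, "causalSpec needs columns gene, nCausal")
    if (nrow(cs) && any(cs$gene < 1L | cs$gene > object@nGenes))
        msg <- c(msg, "causalSpec gene indices out of range")
    if (!object@effectMode %in% c("loguniform", "invmaf"))
        msg <- c(msg, "effectMode must be 'loguniform' or 'invmaf'")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation design
#'
#' @param nIndividuals number of unrelated individuals (default 697).
#' @param nSnps number of SNPs (default 2000, a scaled mini-exome).
#' @param mafRange minor-allele-frequency range; defaults to
#'   0.000717..0.499283.
#' @param rareFraction fraction of SNPs forced to MAF < 0.01 (default 0.5).
#' @param nGenes number of contiguous gene blocks.
#' @param causalSpec data.frame with columns \code{gene} (block index),
#'   \code{nCausal} (causal SNPs in that block) and optionally
#'   \code{nRare} (how many of them must have MAF < 0.01).
#' @param h2 proportion of phenotypic variance explained by the causal
#'   SNPs (0 when there are none).
#' @param nReplicates phenotype replications over the fixed genotypes
#'   (default 200).
#' @param effectRange range of the raw absolute effect sizes (log-uniform).
#' @param effectMode "loguniform" draws |beta| independent of MAF;
#'   "invmaf" additionally scales |beta| by 1/sqrt(2 MAF (1-MAF)) so rare
#'   variants carry larger per-allele effects.
#' @param seed random seed; a fixed seed reproduces the genotype matrix
#'   and the replicate set bit-identically.
#' @return A \linkS4class{SimDesign}.
#' @export
simDesign <- function(nIndividuals = 697L, nSnps = 2000L,
                      mafRange = c(0.000717, 0.499283),
                      rareFraction = 0.5, nGenes = 40L,
                      causalSpec = data.frame(gene = integer(),
                                              nCausal = integer()),
                      h2 = 0, nReplicates = 200L,
                      effectRange = c(0.2, 0.8),
                      effectMode = c("loguniform", "invmaf"),
                      seed = 1L) {
    new("SimDesign", nIndividuals = as.integer(nIndividuals),
        nSnps = as.integer(nSnps), mafRange = as.numeric(mafRange),
        rareFraction = rareFraction, nGenes = as.integer(nGenes),
        causalSpec = as.data.frame(causalSpec), h2 = h2,
        nReplicates = as.integer(nReplicates),
        effectRange = as.numeric(effectRange),
        effectMode = match.arg(effectMode), seed = as.integer(seed))
}

# split m causal SNPs over g genes as evenly as possible
splitCausal <- function(m, g) {
    base <- m %/% g
    sizes <- rep(base, g)
    extra <- m - base * g
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    sizes
}

#' Preset simulation designs
#'
#' Trait presets mirroring the mini-exome benchmark architectures:
#' \describe{
#'   \item{q1}{39 causal SNPs spread over 9 gene blocks.}
#'   \item{q2}{72 causal SNPs over 13 gene blocks.}
#'   \item{q4}{a null trait: no causal SNPs, h2 = 0.}
#'   \item{q1scaled}{a desk-scale recovery benchmark: 500 individuals,
#'     1000 SNPs in 20 genes, 10 causal SNPs in 2 genes of which 5 are
#'     rare, inverse-MAF effect sizes, 20 replicates.}
#' }
#'
#' @param preset one of "q1", "q2", "q4", "q1scaled".
#' @param nSnps,nIndividuals,nReplicates,h2,seed overrides of the preset
#'   dimensions.
#' @param ... further arguments to [simDesign()].
#' @return A \linkS4class{SimDesign}.
#' @examples
#' gawPreset("q4", nSnps = 100, nIndividuals = 200, nReplicates = 5)
#' @export
gawPreset <- function(preset = c("q1", "q2", "q4", "q1scaled"),
                      nSnps = NULL, nIndividuals = NULL,
                      nReplicates = NULL, h2 = NULL, seed = 1L, ...) {
    preset <- match.arg(preset)
    defaults <- switch(preset,
        q1 = list(nInd = 697L, nSnps = 2000L, nGenes = 40L, nRep = 200L,
                  h2 = 0.4, mode = "loguniform", nCausal = 39L,
                  causalGenes = 9L, nRare = NULL),
        q2 = list(nInd = 697L, nSnps = 2000L, nGenes = 40L, nRep = 200L,
                  h2 = 0.4, mode = "loguniform", nCausal = 72L,
                  causalGenes = 13L, nRare = NULL),
        q4 = list(nInd = 697L, nSnps = 2000L, nGenes = 40L, nRep = 200L,
                  h2 = 0, mode = "loguniform", nCausal = 0L,
                  causalGenes = 0L, nRare = NULL),
        q1scaled = list(nInd = 500L, nSnps = 1000L, nGenes = 20L,
                        nRep = 20L, h2 = 0.4, mode = "invmaf",
                        nCausal = 10L, causalGenes = 2L, nRare = c(0L, 5L)))
    if (is.null(nSnps)) nSnps <- defaults$nSnps
    # gene blocks scale down with the SNP panel but must still host the
    # causal genes
    nGenes <- max(min(defaults$nGenes, nSnps), defaults$causalGenes, 1L)
    causal <- if (defaults$causalGenes > 0L) {
        cs <- data.frame(
            gene = as.integer(round(seq(1, nGenes,
                                        length.out = defaults$causalGenes))),
            nCausal = splitCausal(defaults$nCausal, defaults$causalGenes))
        if (!is.null(defaults$nRare)) cs$nRare <- defaults$nRare
        cs
    } else data.frame(gene = integer(), nCausal = integer())
    simDesign(nIndividuals = if (is.null(nIndividuals)) defaults$nInd
                             else nIndividuals,
              nSnps = nSnps, nGenes = nGenes, causalSpec = causal,
              h2 = if (is.null(h2)) defaults$h2 else h2,
              nReplicates = if (is.null(nReplicates)) defaults$nRep
                            else nReplicates,
              effectMode = defaults$mode, seed = seed, ...)
}

setMethod("show", "SimDesign", function(object) {
    cat(sprintf(
        "SimDesign: %d individuals x %d SNPs in %d genes, %d replicates\n",
        object@nIndividuals, object@nSnps, object@nGenes,
        object@nReplicates))
    cat(sprintf("  MAF in [%g, %g], rare fraction %.2f; h2 = %.2f; %s effects\n",
                object@mafRange[1], object@mafRange[2],
                object@rareFraction, object@h2, object@effectMode))
    if (nrow(object@causalSpec))
        cat(sprintf("  causal: %d SNPs in %d gene(s)\n",
                    sum(object@causalSpec$nCausal),
                    nrow(object@causalSpec)))
    invisible(NULL)
})

#' Simulate the genotype matrix and causal truth
#'
#' Draws per-SNP MAFs log-uniform over the design range, with the rare
#' fraction forced below 1\%, then dosages Binomial(2, MAF) per individual
#' under Hardy-Weinberg equilibrium.  Columns coming out monomorphic are
#' redrawn up to 10 times, then kept and flagged.  SNPs are partitioned
#' into contiguous gene blocks, causal SNPs are chosen inside their gene
#' blocks per \code{causalSpec} (honouring any \code{nRare} requirement),
#' and effect sizes are drawn (log-uniform magnitude, random sign, with
#' optional inverse-MAF scaling), then rescaled so that the genetic values
#' X beta have variance \code{h2} against unit residual-plus-genetic
#' phenotype variance.
#'
#' @param design a \linkS4class{SimDesign}.
#' @return A \linkS4class{SnpExperiment} with rowData columns maf (true),
#'   gene, isCausal, trueBeta (scaled) and monomorphic.
#' @examples
#' g <- simulateGenotypes(gawPreset("q4", nSnps = 50, nIndividuals = 100))
#' g
#' @export
simulateGenotypes <- function(design) {
    validObject(design)
    set.seed(design@seed)
    n <- design@nIndividuals; p <- design@nSnps
    lo <- design@mafRange[1]; hi <- design@mafRange[2]

    nRare <- round(design@rareFraction * p)
    if (nRare > 0 && lo >= 0.01)
        stop("rareFraction > 0 impossible: mafRange lower bound >= 0.01")
    if (nRare < p && hi < 0.01)
        stop("common SNPs impossible: mafRange upper bound < 0.01")
    rareHi <- min(hi, 0.01); commonLo <- max(lo, 0.01)
    rareCols <- if (nRare > 0) sort(sample.int(p, nRare)) else integer()
    maf <- numeric(p)
    isRareCol <- seq_len(p) %in% rareCols
    maf[isRareCol] <- exp(runif(nRare, log(lo), log(rareHi)))
    maf[!isRareCol] <- exp(runif(p - nRare, log(commonLo), log(hi)))

    dosage <- matrix(0, p, n)
    mono <- logical(p)
    for (j in seq_len(p)) {
        for (try in seq_len(10L)) {
            col <- rbinom(n, 2L, maf[j])
            if (length(unique(col)) > 1L) break
        }
        mono[j] <- length(unique(col)) == 1L
        dosage[j, ] <- col
    }
    rownames(dosage) <- sprintf("snp%05d", seq_len(p))
    colnames(dosage) <- sprintf("ind%04d", seq_len(n))

    geneSizes <- splitCausal(p, design@nGenes)
    gene <- rep(sprintf("gene%03d", seq_len(design@nGenes)), geneSizes)
    geneIdx <- rep(seq_len(design@nGenes), geneSizes)

    isCausal <- logical(p)
    cs <- design@causalSpec
    for (i in seq_len(nrow(cs))) {
        block <- which(geneIdx == cs$gene[i])
        constrained <- "nRare" %in% names(cs) && !is.na(cs$nRare[i])
        wantRare <- if (constrained) cs$nRare[i] else 0L
        rareInBlock <- block[maf[block] < 0.01]
        commonInBlock <- setdiff(block, rareInBlock)
        if (cs$nCausal[i] > length(block))
            stop("gene block ", cs$gene[i], " has only ", length(block),
                 " SNPs but ", cs$nCausal[i], " causal requested")
        if (wantRare > length(rareInBlock))
            stop("gene block ", cs$gene[i], " has only ",
                 length(rareInBlock), " rare SNPs but ", wantRare,
                 " rare causal requested")
        pick <- integer()
        if (wantRare > 0)
            pick <- sampleInt(rareInBlock, wantRare)
        rest <- cs$nCausal[i] - wantRare
        # an nRare constraint is exact: the remainder must be common
        pool <- if (constrained) commonInBlock else setdiff(block, pick)
        if (rest > length(pool))
            stop("gene block ", cs$gene[i],
                 ": not enough non-rare SNPs for the causal spec")
        pick <- c(pick, sampleInt(pool, rest))
        isCausal[pick] <- TRUE
    }

    beta <- numeric(p)
    ci <- which(isCausal)
    if (length(ci)) {
        mag <- exp(runif(length(ci), log(design@effectRange[1]),
                         log(design@effectRange[2])))
        if (design@effectMode == "invmaf")
            mag <- mag / sqrt(2 * maf[ci] * (1 - maf[ci]))
        sgn <- ifelse(runif(length(ci)) < 0.5, -1, 1)
        beta[ci] <- sgn * mag
        g <- drop(crossprod(dosage[ci, , drop = FALSE], beta[ci]))
        vg <- var(g)
        if (vg <= 0)
            stop("causal genetic values are constant; cannot scale to h2")
        # unit phenotypic variance: Var(X beta) = h2, residual 1 - h2
        beta[ci] <- beta[ci] * sqrt(design@h2 / vg)
    }

    se <- SnpExperiment(dosage, maf = maf, gene = gene,
                        isCausal = isCausal, trueBeta = beta)
    rowData(se)$monomorphic <- mono
    se
}

# sample.int-style draw that never misreads a length-1 vector as 1:x
sampleInt <- function(pool, size) {
    if (size == 0L) return(integer())
    pool[sample.int(length(pool), size)]
}

#' Simulate replicated phenotypes over fixed genotypes
#'
#' Each replicate is \eqn{y_r = X\beta + \epsilon_r} with fresh noise
#' \eqn{\epsilon_r \sim N(0, (1 - h2) I)}; the genetic values X beta come
#' from the scaled truth stored on the genotype object, so
#' Var(X beta)/Var(y) is h2 in expectation.  The noise stream is seeded
#' from the design seed with a fixed offset so the genotype matrix and the
#' replicate set are jointly reproducible.
#'
#' @param geno a simulated \linkS4class{SnpExperiment} (with trueBeta).
#' @param design the \linkS4class{SimDesign} used to simulate it.
#' @return numeric matrix, individuals x replicates (columns
#'   \code{replicate_1}..), with attributes \code{realizedH2} (per
#'   replicate Var(X beta)/Var(y_r)) and \code{sigma2E}.
#' @export
simulatePhenotypes <- function(geno, design) {
    stopifnot(is(geno, "SnpExperiment"))
    beta <- trueBeta(geno)
    if (all(is.na(beta))) stop("genotypes carry no truth (trueBeta missing)")
    anyCausal <- any(beta != 0, na.rm = TRUE)
    if (design@h2 > 0 && !anyCausal)
        stop("h2 > 0 requires at least one causal SNP ",
             "(a null preset needs h2 = 0)")
    n <- ncol(geno)
    g <- if (anyCausal)
        drop(crossprod(dosages(geno), beta)) else numeric(n)
    sigma2E <- if (anyCausal) 1 - design@h2 else 1

    set.seed(design@seed + 1000003L)
    Y <- matrix(0, n, design@nReplicates,
                dimnames = list(colnames(geno),
                    paste0("replicate_", seq_len(design@nReplicates))))
    h2real <- numeric(design@nReplicates)
    vg <- var(g)
    for (r in seq_len(design@nReplicates)) {
        Y[, r] <- g + rnorm(n, 0, sqrt(sigma2E))
        h2real[r] <- if (anyCausal) vg / var(Y[, r]) else 0
    }
    attr(Y, "realizedH2") <- h2real
    attr(Y, "sigma2E") <- sigma2E
    Y
}

#' Duplicate a SNP column to create a perfect-LD pair
#'
#' Appends an exact copy of one SNP immediately after the original,
#' producing the perfectly correlated pair that makes rank-based calling
#' produce a linked false positive.  The copy is flagged non-causal.
#'
#' @param geno a \linkS4class{SnpExperiment}.
#' @param snp SNP identifier or row index to duplicate.
#' @param newId identifier for the copy.
#' @return A \linkS4class{SnpExperiment} with one extra row.
#' @export
injectDuplicateColumn <- function(geno, snp, newId = NULL) {
    j <- if (is.character(snp)) match(snp, rownames(geno)) else as.integer(snp)
    if (is.na(j) || j < 1L || j > nrow(geno)) stop("unknown SNP: ", snp)
    if (is.null(newId)) newId <- paste0(rownames(geno)[j], "_dup")
    d <- dosages(geno)
    rd <- rowData(geno)
    ord <- append(seq_len(nrow(geno)), j, after = j)
    d2 <- d[ord, , drop = FALSE]
    rd2 <- rd[ord, , drop = FALSE]
    rownames(d2)[j + 1L] <- newId
    rownames(rd2)[j + 1L] <- newId
    if (!is.null(rd2$isCausal)) rd2$isCausal[j + 1L] <- FALSE
    if (!is.null(rd2$trueBeta)) rd2$trueBeta[j + 1L] <- 0
    se <- SummarizedExperiment(assays = list(dosage = d2), rowData = rd2)
    new("SnpExperiment", se)
}
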