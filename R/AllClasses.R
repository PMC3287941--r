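#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#'   rowData<- colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' SnpExperiment: genotype dosages with per-SNP metadata
#'
#' A \linkS4class{SummarizedExperiment} holding a single \code{"dosage"}
#' assay with SNPs as rows and individuals as columns.  Entries are
#' alternate-allele dosages 0, 1 or 2 (\code{NA} allowed on input; imputed
#' to the SNP mean dosage before model fitting).  Per-SNP metadata lives in
#' \code{rowData}: \code{maf} (minor allele frequency), \code{gene} (gene
#' block label), \code{isCausal} and \code{trueBeta} when the object comes
#' from the simulator and the truth is known.
#'
#' @export
setClass("SnpExperiment", contains = "SummarizedExperiment")

setValidity("SnpExperiment", function(object) {
    d <- assay(object, "dosage")
    if (is.null(d))
        return("assay 'dosage' is required")
    bad <- !is.na(d) & (d < 0 | d > 2)
    if (any(bad))
        return("dosage entries must lie in [0, 2] or be NA")
    if (anyDuplicated(rownames(object)))
        return("duplicate SNP identifiers")
    TRUE
})

#' Prior specification for the spike-and-slab regression
#'
#' Hyperparameters of the hierarchical model: scaled inverse chi-square
#' priors on the residual variance (scale \code{sEps}, df \code{vEps}) and
#' on the slab variance of included effects (scale \code{sAlpha}, df
#' \code{vAlpha}), and a Beta(\code{a0}, \code{b0}) prior on the inclusion
#' probability pi.  The \code{fix*} slots are testing hooks: a length-one
#' value freezes the corresponding parameter and disables its Gibbs update
#' (length-zero means "sample it").  \code{sharedSlab = TRUE} (default)
#' pools all included effects into one slab variance; \code{FALSE} gives
#' every locus its own slab variance.
#'
#' @export
setClass("BvsPriors", representation(
    sAlpha = "numeric", vAlpha = "numeric",
    sEps = "numeric", vEps = "numeric",
    a0 = "numeric", b0 = "numeric",
    fixSigma2Eps = "numeric", fixSigma2Alpha = "numeric",
    fixPi = "numeric", fixMu = "numeric",
    sharedSlab = "logical"))

setValidity("BvsPriors", function(object) {
    msg <- character()
    for (s in c("sAlpha", "vAlpha", "sEps", "vEps", "a0", "b0")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v) || v <= 0)
            msg <- c(msg, paste0(s, " must be a single positive number"))
    }
    for (s in c("fixSigma2Eps", "fixSigma2Alpha")) {
        v <- slot(object, s)
        if (length(v) > 1L || (length(v) == 1L && (!is.finite(v) || v <= 0)))
            msg <- c(msg, paste0(s, " must be empty or a positive number"))
    }
    fp <- object@fixPi
    if (length(fp) > 1L || (length(fp) == 1L && (fp <= 0 || fp >= 1)))
        msg <- c(msg, "fixPi must be empty or strictly inside (0, 1)")
    if (length(object@fixMu) > 1L ||
        (length(object@fixMu) == 1L && !is.finite(object@fixMu)))
        msg <- c(msg, "fixMu must be empty or a finite number")
    if (length(object@sharedSlab) != 1L)
        msg <- c(msg, "sharedSlab must be a single logical")
    if (length(msg)) msg else TRUE
})

#' MCMC chain configuration
#'
#' Run length and bookkeeping for one Gibbs chain: \code{nIter} total
#' iterations (default 15000), \code{burnIn} discarded iterations (default
#' 1000), \code{thin} keep-every stride, \code{seed} for the random stream,
#' \code{recomputeResidEvery} full residual recomputation period (guards
#' against incremental drift), and \code{engine} ("cpp" for the compiled
#' sampler, "R" for the pure-R reference implementation; both consume the
#' identical random stream).
#'
#' @export
setClass("BvsChainConfig", representation(
    nIter = "integer", burnIn = "integer", thin = "integer",
    seed = "integer", recomputeResidEvery = "integer",
    engine = "character"))

setValidity("BvsChainConfig", function(object) {
    msg <- character()
    if (object@burnIn < 0L || object@burnIn >= object@nIter)
        msg <- c(msg, "need 0 <= burnIn < nIter")
    if (object@thin < 1L)
        msg <- c(msg, "thin must be >= 1")
    if (object@recomputeResidEvery < 1L)
        msg <- c(msg, "recomputeResidEvery must be >= 1")
    if (!object@engine %in% c("cpp", "R"))
        msg <- c(msg, "engine must be 'cpp' or 'R'")
    if (length(msg)) msg else TRUE
})

#' Posterior summary of one fitted chain
#'
#' Per-SNP posterior probability of association (\code{ppa}: the proportion
#' of retained post-burn-in samples in which the SNP's inclusion indicator
#' is 1), posterior mean effect (\code{alphaMean}: average of theta * alpha
#' over retained samples, so exactly 0 contribution when excluded), the
#' retained draws of the model size k (\code{kSamples}), its posterior mode
#' (\code{kPoint}, ties broken toward the smaller k), the number of retained
#' samples, a per-sample trace of the hyperparameters (mu, sigma2_eps,
#' sigma2_alpha, pi), and the priors/config that produced the fit.
#'
#' @export
setClass("BvsFit", representation(
    snpIds = "character", ppa = "numeric", alphaMean = "numeric",
    kSamples = "integer", kPoint = "integer", nRetained = "integer",
    monomorphic = "logical", hyperTrace = "data.frame",
    priors = "BvsPriors", config = "BvsChainConfig"))

setValidity("BvsFit", function(object) {
    msg <- character()
    p <- length(object@snpIds)
    if (length(object@ppa) != p || length(object@alphaMean) != p ||
        length(object@monomorphic) != p)
        msg <- c(msg, "ppa, alphaMean, monomorphic must match snpIds length")
    if (any(object@ppa < 0 | object@ppa > 1))
        msg <- c(msg, "ppa entries must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Exact fixed-parameter posterior by model enumeration
#'
#' The posterior over all 2^p inclusion patterns at fixed residual
#' variance, slab variance and pi, for small p.  \code{models} is the
#' 2^p-by-p 0/1 matrix of inclusion patterns, \code{weights} the normalised
#' posterior model probabilities, \code{ppaExact} the exact per-SNP
#' inclusion probabilities and \code{kDist} the exact distribution of the
#' model size (named 0..p).
#'
#' @export
setClass("BvsOracle", representation(
    snpIds = "character", models = "matrix", weights = "numeric",
    ppaExact = "numeric", kDist = "numeric"))

setValidity("BvsOracle", function(object) {
    msg <- character()
    if (abs(sum(object@weights) - 1) > 1e-12)
        msg <- c(msg, "model weights must sum to 1")
    if (nrow(object@models) != length(object@weights))
        msg <- c(msg, "one weight per model required")
    if (length(msg)) msg else TRUE
})

#' ROC curve over score cutoffs
#'
#' Ordered (cutoff, FPR, TPR) points obtained by sweeping every distinct
#' score as a calling threshold (score >= cutoff is called), plus the area
#' under the curve by trapezoidal integration.
#'
#' @export
setClass("RocCurve", representation(points = "data.frame", auc = "numeric"))

setValidity("RocCurve", function(object) {
    msg <- character()
    if (!all(c("cutoff", "fpr", "tpr") %in% names(object@points)))
        msg <- c(msg, "points needs columns cutoff, fpr, tpr")
    if (object@auc < 0 || object@auc > 1)
        msg <- c(msg, "auc must lie in [0, 1]")
    if (is.unsorted(object@points$fpr) || is.unsorted(object@points$tpr))
        msg <- c(msg, "fpr and tpr must be non-decreasing along the sweep")
    if (length(msg)) msg else TRUE
})

#' Replicate-averaged scores and ranks
#'
#' Per-SNP mean absolute posterior effect and mean PPA across phenotype
#' replicates, the rank of each SNP under either score (1 = largest, ties
#' broken by SNP index), and the per-replicate point estimates of the
#' number of associated SNPs.
#'
#' @export
setClass("BvsAverages", representation(
    table = "data.frame", kPoints = "integer"))

setValidity("BvsAverages", function(object) {
    need <- c("snp_id", "mean_abs_coef", "mean_ppa", "rank_coef", "rank_ppa")
    if (!all(need %in% names(object@table)))
        return(paste("table needs columns:", paste(need, collapse = ", ")))
    p <- nrow(object@table)
    if (!identical(sort(object@table$rank_coef), seq_len(p)) ||
        !identical(sort(object@table$rank_ppa), seq_len(p)))
        return("ranks must each be a permutation of 1..p")
    TRUE
})
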