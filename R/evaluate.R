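#' Average posterior summaries over phenotype replicates
#'
#' Computes, per SNP, the arithmetic mean of the absolute posterior effect
#' and of the PPA across replicate fits, and ranks SNPs under each score
#' in decreasing order (rank 1 = largest; ties broken by ascending SNP
#' index).  Per-replicate point estimates of the number of associated SNPs
#' are carried along for the calling rule.
#'
#' @param fits list of \linkS4class{BvsFit} objects over the same SNP set
#'   and order (one per phenotype replicate).
#' @return A \linkS4class{BvsAverages}.
#' @export
averageOverReplicates <- function(fits) {
    if (!length(fits)) stop("no replicate summaries supplied")
    ids <- fits[[1L]]@snpIds
    for (f in fits)
        if (!identical(f@snpIds, ids))
            stop("replicate summaries disagree on the SNP set/order")
    coefMat <- vapply(fits, function(f) abs(f@alphaMean),
                      numeric(length(ids)))
    ppaMat <- vapply(fits, function(f) f@ppa, numeric(length(ids)))
    if (length(ids) == 1L) {
        coefMat <- matrix(coefMat, 1L); ppaMat <- matrix(ppaMat, 1L)
    }
    meanCoef <- rowMeans(coefMat)
    meanPpa <- rowMeans(ppaMat)
    tab <- data.frame(snp_id = ids,
                      mean_abs_coef = meanCoef,
                      mean_ppa = meanPpa,
                      rank_coef = rankDescending(meanCoef),
                      rank_ppa = rankDescending(meanPpa),
                      stringsAsFactors = FALSE)
    new("BvsAverages", table = tab,
        kPoints = vapply(fits, function(f) f@kPoint, integer(1)))
}

# rank 1 = largest; ties broken by ascending index
rankDescending <- function(score) {
    out <- integer(length(score))
    out[order(-score, seq_along(score))] <- seq_along(score)
    out
}

#' Call associated SNPs by the replicate k-range rule
#'
#' The per-replicate point estimates of the model size give a range
#' (min, max); a SNP is called associated when its rank is within the
#' range maximum under the required score(s) -- by default under BOTH the
#' mean absolute coefficient and the mean PPA rankings.
#'
#' @param avgs a \linkS4class{BvsAverages}.
#' @param rule "both" (default: rank within threshold under both scores),
#'   "ppa" or "coef" for a single-score rule.
#' @return list with \code{table} (data.frame snp_id, rank_coef, rank_ppa,
#'   called), \code{kRange} = c(min, max) of the per-replicate point
#'   estimates, and \code{threshold} (the rank cutoff used).
#' @export
callAssociated <- function(avgs, rule = c("both", "ppa", "coef")) {
    rule <- match.arg(rule)
    if (!length(avgs@kPoints)) stop("no per-replicate k point estimates")
    kRange <- range(avgs@kPoints)
    thr <- kRange[2L]
    tab <- avgs@table
    called <- switch(rule,
        both = tab$rank_coef <= thr & tab$rank_ppa <= thr,
        ppa = tab$rank_ppa <= thr,
        coef = tab$rank_coef <= thr)
    list(table = data.frame(snp_id = tab$snp_id,
                            rank_coef = tab$rank_coef,
                            rank_ppa = tab$rank_ppa,
                            called = called, stringsAsFactors = FALSE),
         kRange = kRange, threshold = thr)
}

#' ROC curve and AUC for a per-SNP score against the causal truth
#'
#' Sweeps every distinct score value as a cutoff (score >= cutoff is
#' called), preceded by a sentinel above the maximum so the curve starts
#' at (0, 0).  TPR = called causal / all causal; FPR = called non-causal /
#' all non-causal.  The AUC is the trapezoidal area, which equals the
#' concordance probability that a random causal SNP outscores a random
#' non-causal one, ties counted one half.
#'
#' @param scores numeric per-SNP scores (larger = more associated).
#' @param truth logical (or 0/1) causal flags, same length and order.
#' @return A \linkS4class{RocCurve}.
#' @examples
#' rocCurve(c(0.9, 0.8, 0.4, 0.2), c(TRUE, FALSE, TRUE, FALSE))
#' @export
rocCurve <- function(scores, truth) {
    truth <- as.logical(truth)
    if (length(scores) != length(truth))
        stop("scores and truth must have the same length")
    if (anyNA(scores) || anyNA(truth)) stop("scores/truth must not be NA")
    nPos <- sum(truth); nNeg <- sum(!truth)
    if (nPos == 0L || nNeg == 0L)
        stop("undefined ROC: need at least one causal and one ",
             "non-causal SNP")
    cuts <- c(max(scores) + 1, sort(unique(scores), decreasing = TRUE))
    tpr <- fpr <- numeric(length(cuts))
    for (i in seq_along(cuts)) {
        called <- scores >= cuts[i]
        tpr[i] <- sum(called & truth) / nPos
        fpr[i] <- sum(called & !truth) / nNeg
    }
    a <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
    new("RocCurve",
        points = data.frame(cutoff = cuts, fpr = fpr, tpr = tpr),
        auc = a)
}

#' ROC restricted to rare variants
#'
#' Keeps only SNPs with MAF below the threshold (default 1\%) and computes
#' the ROC/AUC within that subset -- both the TPR and FPR denominators
#' count subset SNPs only.
#'
#' @param scores,truth as in [rocCurve()].
#' @param maf per-SNP minor allele frequency.
#' @param threshold MAF cutoff defining "rare" (default 0.01).
#' @return A \linkS4class{RocCurve} on the rare subset.
#' @export
rareSubsetRoc <- function(scores, truth, maf, threshold = 0.01) {
    if (length(maf) != length(scores))
        stop("maf must be available for every SNP")
    keep <- maf < threshold
    if (!any(keep))
        stop("undefined ROC: no SNPs below the MAF threshold")
    rocCurve(scores[keep], as.logical(truth)[keep])
}

#' @describeIn rocCurve the area under the curve.
#' @param x a RocCurve.
#' @export
setMethod("auc", "RocCurve", function(x) x@auc)

#' @describeIn rocCurve the swept (cutoff, fpr, tpr) points.
#' @export
setMethod("rocPoints", "RocCurve", function(x) x@points)

setMethod("show", "RocCurve", function(object) {
    cat(sprintf("RocCurve: %d cutoffs, AUC = %.4f\n",
                nrow(object@points), object@auc))
    invisible(NULL)
})

setMethod("show", "BvsAverages", function(object) {
    cat(sprintf("BvsAverages over %d replicate(s), %d SNPs\n",
                length(object@kPoints), nrow(object@table)))
    cat(sprintf("  k point estimates: min %d, max %d\n",
                min(object@kPoints), max(object@kPoints)))
    top <- object@table[order(object@table$rank_ppa), ][
        seq_len(min(5L, nrow(object@table))), ]
    cat("  top by mean PPA:\n")
    for (i in seq_len(nrow(top)))
        cat(sprintf("    %-12s mean_ppa = %.3f  mean|coef| = %.3f\n",
                    top$snp_id[i], top$mean_ppa[i], top$mean_abs_coef[i]))
    invisible(NULL)
})
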