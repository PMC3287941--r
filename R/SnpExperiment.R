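#' Construct a SnpExperiment
#'
#' @param dosage numeric matrix of allele dosages with SNPs as rows and
#'   individuals as columns; entries 0/1/2 or NA.  A matrix with
#'   individuals as rows can be passed with \code{snpsAsRows = FALSE}.
#' @param maf optional numeric vector of per-SNP minor allele frequencies
#'   (true values when simulated).  When missing, the observed MAF is
#'   computed from the dosages.
#' @param gene optional per-SNP gene block label.
#' @param isCausal optional logical per-SNP causal flag.
#' @param trueBeta optional numeric per-SNP true effect size.
#' @param snpsAsRows logical; is \code{dosage} SNP-by-individual?
#' @return A \linkS4class{SnpExperiment}.
#' @examples
#' g <- SnpExperiment(matrix(c(0, 1, 2, 0), 2,
#'                    dimnames = list(c("s1", "s2"), c("i1", "i2"))))
#' dosages(g)
#' @export
SnpExperiment <- function(dosage, maf = NULL, gene = NULL, isCausal = NULL,
                          trueBeta = NULL, snpsAsRows = TRUE) {
    dosage <- as.matrix(dosage)
    if (!snpsAsRows) dosage <- t(dosage)
    if (is.null(rownames(dosage)))
        rownames(dosage) <- paste0("snp", seq_len(nrow(dosage)))
    if (is.null(colnames(dosage)))
        colnames(dosage) <- paste0("ind", seq_len(ncol(dosage)))
    if (is.null(maf)) maf <- observedMAF(dosage)
    rd <- DataFrame(maf = as.numeric(maf))
    if (!is.null(gene)) rd$gene <- gene
    if (!is.null(isCausal)) rd$isCausal <- as.logical(isCausal)
    if (!is.null(trueBeta)) rd$trueBeta <- as.numeric(trueBeta)
    rownames(rd) <- rownames(dosage)
    se <- SummarizedExperiment(assays = list(dosage = dosage), rowData = rd)
    new("SnpExperiment", se)
}

observedMAF <- function(dosage) {
    f <- rowMeans(dosage, na.rm = TRUE) / 2
    pmin(f, 1 - f)
}

#' @describeIn SnpExperiment the dosage matrix.  With
#'   \code{snpsAsRows = FALSE} (the regression orientation) individuals are
#'   rows and SNPs columns.
#' @param x a SnpExperiment.
#' @export
setMethod("dosages", "SnpExperiment", function(x, snpsAsRows = TRUE) {
    d <- assay(x, "dosage")
    if (snpsAsRows) d else t(d)
})

#' @describeIn SnpExperiment per-SNP minor allele frequency (the true MAF
#'   when the object was simulated, otherwise the observed one).
#' @export
setMethod("snpMAF", "SnpExperiment", function(x) {
    setNames(rowData(x)$maf, rownames(x))
})

#' @describeIn SnpExperiment logical causal flag per SNP (all NA when the
#'   truth is unknown).
#' @export
setMethod("isCausal", "SnpExperiment", function(x) {
    v <- rowData(x)$isCausal
    if (is.null(v)) v <- rep(NA, nrow(x))
    setNames(v, rownames(x))
})

#' @describeIn SnpExperiment true per-SNP effect size (0 iff not causal;
#'   NA when the truth is unknown).
#' @export
setMethod("trueBeta", "SnpExperiment", function(x) {
    v <- rowData(x)$trueBeta
    if (is.null(v)) v <- rep(NA_real_, nrow(x))
    setNames(v, rownames(x))
})

#' @describeIn SnpExperiment gene block label per SNP.
#' @export
setMethod("snpGene", "SnpExperiment", function(x) {
    v <- rowData(x)$gene
    if (is.null(v)) v <- rep(NA_character_, nrow(x))
    setNames(v, rownames(x))
})

setMethod("show", "SnpExperiment", function(object) {
    cat(sprintf("SnpExperiment: %d SNPs x %d individuals\n",
                nrow(object), ncol(object)))
    maf <- rowData(object)$maf
    cat(sprintf("  MAF range: %.4g .. %.4g; %d rare (MAF < 0.01)\n",
                min(maf), max(maf), sum(maf < 0.01)))
    cc <- rowData(object)$isCausal
    if (!is.null(cc))
        cat(sprintf("  causal SNPs: %d in %d gene block(s)\n", sum(cc),
                    length(unique(rowData(object)$gene[cc]))))
    invisible(NULL)
})

#' Truth table of a simulated SnpExperiment
#'
#' @param x a SnpExperiment carrying causal annotation.
#' @return data.frame with columns snp_id, gene, is_causal, true_beta,
#'   true_maf (one row per SNP; causal SNPs appear exactly once).
#' @export
truthTable <- function(x) {
    stopifnot(is(x, "SnpExperiment"))
    if (is.null(rowData(x)$isCausal))
        stop("no causal annotation on this SnpExperiment")
    data.frame(snp_id = rownames(x),
               gene = as.character(snpGene(x)),
               is_causal = as.logical(isCausal(x)),
               true_beta = as.numeric(trueBeta(x)),
               true_maf = as.numeric(snpMAF(x)),
               stringsAsFactors = FALSE, row.names = NULL)
}
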