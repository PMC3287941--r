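#' Read a genotype dosage TSV
#'
#' Expected dialect: tab-separated, header row of SNP identifiers, first
#' column individual identifiers, cells 0/1/2 or NA.  Any other cell is a
#' parse error naming the offending SNP and individual.  Missing dosages
#' are imputed to the SNP's mean observed dosage (logged via message).
#'
#' @param path file path.
#' @param transpose set TRUE when the file is SNP-major (SNPs as rows).
#' @param impute impute NA cells to the column mean dosage (default TRUE).
#' @return A \linkS4class{SnpExperiment}.
#' @export
readGenotypesTsv <- function(path, transpose = FALSE, impute = TRUE) {
    if (!file.exists(path)) stop("no such file: ", path)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             row.names = 1L, check.names = FALSE,
                             colClasses = "character",
                             na.strings = "NA")
    if (!nrow(tab) || !ncol(tab)) stop("empty genotype file: ", path)
    M <- as.matrix(tab)
    if (transpose) M <- t(M)       # now individuals x SNPs
    if (anyDuplicated(colnames(M)))
        stop("duplicate SNP identifiers in ", path)
    if (anyDuplicated(rownames(M)))
        stop("duplicate individual identifiers in ", path)
    bad <- !is.na(M) & !(M %in% c("0", "1", "2"))
    if (any(bad)) {
        w <- which(bad, arr.ind = TRUE)[1L, ]
        stop("invalid dosage '", M[w[1L], w[2L]], "' for SNP ",
             colnames(M)[w[2L]], ", individual ", rownames(M)[w[1L]],
             " (cells must be 0, 1, 2 or NA)")
    }
    X <- matrix(as.numeric(M), nrow(M), ncol(M), dimnames = dimnames(M))
    nMiss <- sum(is.na(X))
    if (nMiss && impute) {
        message("imputing ", nMiss, " missing dosage(s) to SNP mean")
        X <- imputeDosages(X)
    }
    SnpExperiment(X, snpsAsRows = FALSE)
}

#' Write a genotype dosage TSV
#'
#' Individuals as rows, SNP identifiers in the header -- the dialect
#' [readGenotypesTsv()] reads back bit-identically for integer dosages.
#'
#' @param geno a \linkS4class{SnpExperiment}.
#' @param path output path.
#' @export
writeGenotypesTsv <- function(geno, path) {
    X <- dosages(geno, snpsAsRows = FALSE)
    df <- data.frame(individual = rownames(X), X, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read genotypes from a VCF
#'
#' Converts GT calls of biallelic sites to alternate-allele dosage (0/0 ->
#' 0; 0/1 or 1/0 -> 1; 1/1 -> 2; ./. -> missing, imputed downstream).
#' Multi-allelic sites are skipped with a warning and counted in the
#' \code{skippedMultiallelic} attribute.  SNP identifiers come from the ID
#' column, falling back to CHROM:POS:REF:ALT.
#'
#' @param path a VCF file (plain or bgzipped).
#' @return A \linkS4class{SnpExperiment}.
#' @export
readGenotypesVcf <- function(path) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
        stop("package 'VariantAnnotation' is required to read VCF")
    vcf <- VariantAnnotation::readVcf(path)
    if (!nrow(vcf)) stop("VCF has no variant records: ", path)
    alt <- VariantAnnotation::alt(vcf)
    nAlt <- S4Vectors::elementNROWS(alt)
    multi <- nAlt != 1L
    if (any(multi))
        warning(sum(multi), " multi-allelic site(s) skipped")
    vcf1 <- vcf[!multi, ]
    if (!nrow(vcf1)) stop("no biallelic sites in ", path)
    gt <- VariantAnnotation::geno(vcf1)$GT
    if (is.null(gt)) stop("VCF lacks GT genotypes: ", path)
    dose <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    gtn <- gsub("|", "/", gt, fixed = TRUE)
    dose[gtn %in% c("0/0", "0")] <- 0
    dose[gtn %in% c("0/1", "1/0")] <- 1
    dose[gtn %in% c("1/1", "1")] <- 2
    unknown <- !(gtn %in% c("0/0", "0", "0/1", "1/0", "1/1", "1",
                            "./.", "."))
    if (any(unknown))
        stop("unrecognised GT value(s): ",
             paste(unique(gtn[unknown]), collapse = ", "))
    ids <- rownames(gt)
    if (is.null(ids)) ids <- rep(".", nrow(gt))
    rr <- SummarizedExperiment::rowRanges(vcf1)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    refA <- as.character(VariantAnnotation::ref(vcf1))
    altA <- vapply(as(alt[!multi], "CharacterList"), paste, character(1),
                   collapse = ",")
    # sites lacking an ID get CHROM:POS:REF:ALT (readVcf auto-names them
    # "chrom:pos_ref/alt"; treat those as missing too)
    fallback <- is.na(ids) | ids %in% c(".", "") |
        ids == paste0(chrom, ":", pos, "_", refA, "/", altA)
    ids[fallback] <- paste0(chrom, ":", pos, ":", refA, ":",
                            altA)[fallback]
    rownames(dose) <- ids
    out <- SnpExperiment(dose)
    attr(out, "skippedMultiallelic") <- sum(multi)
    out
}

#' Read a phenotype replicate table
#'
#' TSV with an individual identifier column followed by one column per
#' replicate.  When \code{individuals} is given, rows are realigned to
#' that order; individuals requested but absent are an error (no silent
#' dropping).
#'
#' @param path file path.
#' @param individuals optional character vector fixing the row order
#'   (typically the genotype individual order).
#' @return numeric matrix, individuals x replicates.
#' @export
readPhenotypes <- function(path, individuals = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE,
                             colClasses = "character")
    if (ncol(tab) < 2L)
        stop("phenotype file needs an ID column plus >= 1 replicate")
    ids <- tab[[1L]]
    if (anyDuplicated(ids)) stop("duplicate individual identifiers")
    M <- as.matrix(tab[, -1L, drop = FALSE])
    suppressWarnings(storage.mode(M) <- "double")
    if (anyNA(M)) {
        w <- which(is.na(M), arr.ind = TRUE)[1L, ]
        stop("non-numeric phenotype for individual ", ids[w[1L]],
             ", column ", colnames(M)[w[2L]])
    }
    rownames(M) <- ids
    if (!is.null(individuals)) {
        missing <- setdiff(individuals, ids)
        if (length(missing))
            stop("individuals present in genotypes but missing from ",
                 "phenotypes: ", paste(utils::head(missing, 5L),
                                       collapse = ", "))
        M <- M[individuals, , drop = FALSE]
    }
    M
}

#' Write a phenotype replicate table
#'
#' @param pheno numeric matrix, individuals x replicates, with rownames.
#' @param path output path.
#' @export
writePhenotypes <- function(pheno, path) {
    df <- data.frame(individual = rownames(pheno), pheno,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write / read a causal truth table
#'
#' Columns: snp_id, gene, is_causal, true_beta, true_maf.
#'
#' @param truth data.frame from [truthTable()].
#' @param path file path.
#' @return \code{readTruth} returns the data.frame.
#' @export
writeTruth <- function(truth, path) {
    utils::write.table(truth, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE,
                             stringsAsFactors = FALSE)
    need <- c("snp_id", "gene", "is_causal", "true_beta", "true_maf")
    if (!all(need %in% names(tab)))
        stop("truth table needs columns: ", paste(need, collapse = ", "))
    tab$is_causal <- as.logical(tab$is_causal)
    tab
}

#' Write / read a posterior summary TSV
#'
#' The summary TSV has columns snp_id, ppa, alpha_mean; chain metadata
#' (iterations, burn-in, seed, priors, k posterior quantiles) goes to a
#' JSON sidecar at \code{<path>.meta.json}.
#'
#' @param fit a \linkS4class{BvsFit}.
#' @param path output path for the TSV.
#' @return \code{readFitTsv} returns a data.frame (snp_id, ppa,
#'   alpha_mean).
#' @export
writeFitTsv <- function(fit, path) {
    utils::write.table(
        data.frame(snp_id = fit@snpIds, ppa = fit@ppa,
                   alpha_mean = fit@alphaMean, stringsAsFactors = FALSE),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    meta <- list(
        nIter = fit@config@nIter, burnIn = fit@config@burnIn,
        thin = fit@config@thin, seed = fit@config@seed,
        nRetained = fit@nRetained, kPoint = fit@kPoint,
        kQuantiles = as.list(stats::quantile(fit@kSamples,
                                             c(0.025, 0.5, 0.975))),
        priors = list(sAlpha = fit@priors@sAlpha,
                      vAlpha = fit@priors@vAlpha,
                      sEps = fit@priors@sEps, vEps = fit@priors@vEps,
                      a0 = fit@priors@a0, b0 = fit@priors@b0,
                      sharedSlab = fit@priors@sharedSlab))
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeFitTsv
#' @export
readFitTsv <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (!all(c("snp_id", "ppa", "alpha_mean") %in% names(tab)))
        stop("summary TSV needs columns snp_id, ppa, alpha_mean")
    tab
}

#' Write ROC points to TSV
#'
#' Columns cutoff, fpr, tpr, one row per swept cutoff.
#'
#' @param roc a \linkS4class{RocCurve}.
#' @param path output path.
#' @export
writeRocTsv <- function(roc, path) {
    utils::write.table(rocPoints(roc), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a pipeline run configuration
#'
#' A flat YAML key-value file mirroring the command-line flags of the
#' \code{bvs fit} wrapper: \code{genotypes}, \code{phenotypes},
#' \code{truth}, \code{out}, \code{iters}, \code{burn_in}, \code{seed},
#' \code{fix_pi}, \code{maf_threshold}.  Referenced input paths are
#' checked at validation time; command-line flags override config values.
#'
#' @param path YAML file.
#' @return named list of settings.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("no such config file: ", path)
    cfg <- yaml::read_yaml(path)
    if (!is.list(cfg)) stop("config must be a YAML mapping: ", path)
    known <- c("genotypes", "phenotypes", "truth", "out", "iters",
               "burn_in", "seed", "fix_pi", "maf_threshold")
    unknown <- setdiff(names(cfg), known)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    for (k in c("genotypes", "phenotypes", "truth"))
        if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
            stop("config ", k, " path does not exist: ", cfg[[k]])
    cfg
}
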