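#' Run the full per-replicate analysis pipeline
#'
#' Fits one Gibbs chain per phenotype replicate (per-replicate seeds
#' derived from the master seed by fixed offsets), averages the posterior
#' summaries across replicates, applies the k-range calling rule, and --
#' when a truth table is available -- computes ROC/AUC on all SNPs and on
#' the rare (MAF < threshold) subset for both scores.  All outputs are
#' written as TSV under \code{outDir} together with a machine-readable
#' JSON manifest (seed, priors, chain settings) sufficient to reproduce
#' the run.
#'
#' @param geno a \linkS4class{SnpExperiment} (or path to a genotype TSV).
#' @param pheno numeric matrix individuals x replicates (or path to a
#'   phenotype TSV).
#' @param truth optional truth data.frame as from [truthTable()] (or path
#'   to a truth TSV).
#' @param outDir output directory, created if needed.
#' @param priors optional \linkS4class{BvsPriors} (default:
#'   [defaultPriors()] per replicate).
#' @param nIter,burnIn chain length settings.
#' @param seed master seed; replicate r runs with seed + r.
#' @param mafThreshold rare-variant MAF cutoff for the subset ROC.
#' @param engine sampler engine, "cpp" or "R".
#' @param verbose log per-replicate progress via message().
#' @return (invisibly) a list with \code{fits}, \code{averages},
#'   \code{calls}, and when truth is given \code{roc} (a list of RocCurve
#'   objects by score and subset).
#' @export
runPipeline <- function(geno, pheno, truth = NULL, outDir,
                        priors = NULL, nIter = 15000L, burnIn = 1000L,
                        seed = 1L, mafThreshold = 0.01,
                        engine = "cpp", verbose = TRUE) {
    if (is.character(geno)) geno <- readGenotypesTsv(geno)
    if (is.character(pheno))
        pheno <- readPhenotypes(pheno, individuals = colnames(geno))
    if (is.character(truth)) truth <- readTruth(truth)
    stopifnot(is(geno, "SnpExperiment"), is.matrix(pheno))
    if (!is.null(rownames(pheno)) &&
        !identical(rownames(pheno), colnames(geno)))
        pheno <- pheno[colnames(geno), , drop = FALSE]
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    R <- ncol(pheno)
    fits <- vector("list", R)
    for (r in seq_len(R)) {
        cfg <- bvsChainConfig(nIter = nIter, burnIn = burnIn,
                              seed = seed + r, engine = engine)
        fits[[r]] <- tryCatch(
            runChain(geno, pheno[, r], priors = priors, config = cfg),
            error = function(e) stop("fit stage failed for replicate ", r,
                                     ": ", conditionMessage(e)))
        writeFitTsv(fits[[r]],
                    file.path(outDir, sprintf("summary_replicate_%03d.tsv",
                                              r)))
        if (verbose)
            message(sprintf("[%s] replicate %d/%d done (k = %d)",
                            format(Sys.time(), "%H:%M:%S"), r, R,
                            kPoint(fits[[r]])))
    }

    avgs <- averageOverReplicates(fits)
    calls <- callAssociated(avgs)
    utils::write.table(avgs@table, file.path(outDir, "averages.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(calls$table, file.path(outDir, "called_snps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    roc <- NULL
    if (!is.null(truth)) {
        tt <- truth[match(avgs@table$snp_id, truth$snp_id), ]
        if (anyNA(tt$snp_id))
            stop("evaluation stage: truth table does not cover the SNP set")
        roc <- list()
        for (sc in c("ppa", "coef")) {
            s <- if (sc == "ppa") avgs@table$mean_ppa
                 else avgs@table$mean_abs_coef
            all <- tryCatch(rocCurve(s, tt$is_causal), error = identity)
            rare <- tryCatch(
                rareSubsetRoc(s, tt$is_causal, tt$true_maf, mafThreshold),
                error = identity)
            for (nm in c("all", "rare")) {
                obj <- get(nm)
                key <- paste0(sc, "_", nm)
                if (inherits(obj, "error")) {
                    if (verbose)
                        message("ROC (", key, ") not computed: ",
                                conditionMessage(obj))
                } else {
                    roc[[key]] <- obj
                    writeRocTsv(obj, file.path(outDir,
                                               paste0("roc_", key, ".tsv")))
                }
            }
        }
        if (length(roc)) {
            aucTab <- data.frame(
                score_subset = names(roc),
                auc = vapply(roc, auc, numeric(1)),
                stringsAsFactors = FALSE)
            utils::write.table(aucTab, file.path(outDir, "auc.tsv"),
                               sep = "\t", quote = FALSE,
                               row.names = FALSE)
        }
    }

    manifest <- list(
        package = as.character(utils::packageVersion("snpBVS")),
        seed = seed, nIter = nIter, burnIn = burnIn,
        nReplicates = R, nSnps = nrow(geno),
        nIndividuals = ncol(geno), mafThreshold = mafThreshold,
        engine = engine, kRange = calls$kRange,
        rVersion = as.character(getRversion()))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)

    invisible(list(fits = fits, averages = avgs, calls = calls, roc = roc))
}
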