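#' @import methods
#' @importFrom stats rnorm runif rchisq rbeta dnorm var sd setNames
NULL

#' Accessor generics
#'
#' Accessors for the core objects: posterior summaries (\code{ppa},
#' \code{effectMean}, \code{kSamples}, \code{kPoint}), genotype containers
#' (\code{dosages}, \code{snpMAF}, \code{isCausal}, \code{trueBeta},
#' \code{snpGene}) and ROC curves (\code{auc}, \code{rocPoints}).
#'
#' @param x an object.
#' @param ... further arguments passed to methods.
#' @return The corresponding slot or derived vector; see the class pages.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("ppa", function(x, ...) standardGeneric("ppa"))

#' @rdname accessors
#' @export
setGeneric("effectMean", function(x, ...) standardGeneric("effectMean"))

#' @rdname accessors
#' @export
setGeneric("kSamples", function(x, ...) standardGeneric("kSamples"))

#' @rdname accessors
#' @export
setGeneric("kPoint", function(x, ...) standardGeneric("kPoint"))

#' @rdname accessors
#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setGeneric("snpMAF", function(x, ...) standardGeneric("snpMAF"))

#' @rdname accessors
#' @export
setGeneric("isCausal", function(x, ...) standardGeneric("isCausal"))

#' @rdname accessors
#' @export
setGeneric("trueBeta", function(x, ...) standardGeneric("trueBeta"))

#' @rdname accessors
#' @export
setGeneric("snpGene", function(x, ...) standardGeneric("snpGene"))

#' @rdname accessors
#' @export
setGeneric("hyperTrace", function(x, ...) standardGeneric("hyperTrace"))

#' @rdname accessors
#' @export
setGeneric("auc", function(x, ...) standardGeneric("auc"))

#' @rdname accessors
#' @export
setGeneric("rocPoints", function(x, ...) standardGeneric("rocPoints"))
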