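#' Accessors for PerturbationExperiment
#'
#' @param x a \linkS4class{PerturbationExperiment}.
#' @return \code{doses}: the N x M dose matrix; \code{perturbationNames}:
#'   the M perturbation names; \code{covariateSchemas}: named list of level
#'   vectors; \code{covariateAssignments}: data.frame of per-cell covariate
#'   levels; \code{conditionIds}: per-cell condition keys;
#'   \code{splitLabels}: per-cell split labels; \code{cellMatrix}: the
#'   expression matrix oriented cells x genes.
#' @name perturbation-accessors
NULL

#' @rdname perturbation-accessors
#' @export
doses <- function(x) colData(x)$dose

#' @rdname perturbation-accessors
#' @export
perturbationNames <- function(x) {
    if (is(x, "CPAModel")) x@perturbations else metadata(x)$perturbations
}

#' @rdname perturbation-accessors
#' @export
covariateSchemas <- function(x) {
    if (is(x, "CPAModel")) x@covariateSchemas
    else if (is(x, "SyntheticTruth")) x@covariateSchemas
    else metadata(x)$covariateSchemas
}

#' @rdname perturbation-accessors
#' @export
covariateAssignments <- function(x) {
    sch <- metadata(x)$covariateSchemas
    out <- as.data.frame(colData(x)[, names(sch), drop = FALSE])
    rownames(out) <- colnames(x)
    out
}

#' @rdname perturbation-accessors
#' @export
conditionIds <- function(x) colData(x)$condition

#' @rdname perturbation-accessors
#' @export
splitLabels <- function(x) colData(x)$split

#' @rdname perturbation-accessors
#' @param value replacement split labels.
#' @export
`splitLabels<-` <- function(x, value) {
    stopifnot(all(value %in% c("train", "test", "ood") | is.na(value)))
    colData(x)$split <- as.character(value)
    x
}

#' @rdname perturbation-accessors
#' @export
cellMatrix <- function(x) t(assay(x))

setMethod("show", "PerturbationExperiment", function(object) {
    callNextMethod()
    md <- metadata(object)
    cat(sprintf("perturbations(%d): %s\n", length(md$perturbations),
                paste(utils::head(md$perturbations, 8), collapse = " ")))
    cat(sprintf("covariates(%d): %s\n", length(md$covariateSchemas),
                paste(names(md$covariateSchemas), collapse = " ")))
    sp <- splitLabels(object)
    if (!all(is.na(sp))) {
        tb <- table(sp, useNA = "no")
        cat("split: ", paste(sprintf("%s=%d", names(tb), tb), collapse = " "),
            "\n", sep = "")
    }
})

setMethod("show", "SplitPlan", function(object) {
    cat(sprintf("SplitPlan: %d ood condition(s), testFraction=%.2f, seed=%d\n",
                length(object@oodConditions), object@testFraction, object@seed))
})

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf(
        "SyntheticTruth: latentDim=%d, %d genes, %d perturbations, %s decoder, noiseSd=%.3g\n",
        object@latentDim, object@nGenes, length(object@perturbations),
        object@decoderKind, object@noiseSd))
    if (length(object@interactions))
        cat("planted interactions:",
            paste(names(object@interactions), collapse = " "), "\n")
})

setMethod("show", "CPAModel", function(object) {
    cat(sprintf(
        "CPAModel: %d genes, %d perturbations, %d covariate(s), latentDim=%d (%s)\n",
        length(object@genes), length(object@perturbations),
        length(object@covariateSchemas), object@latentDim,
        if (object@trained) "trained" else "untrained"))
})

setMethod("show", "GaussianPrediction", function(object) {
    cat(sprintf("GaussianPrediction: %d cell(s) x %d gene(s)\n",
                nrow(object@mean), ncol(object@mean)))
})

#' Predicted mean / variance of a GaussianPrediction
#' @param object a \linkS4class{GaussianPrediction}.
#' @export
predictedMean <- function(object) object@mean

#' @rdname predictedMean
#' @export
predictedVariance <- function(object) object@variance
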