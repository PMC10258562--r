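# Counterfactual prediction by embedding swap, condition-level aggregation,
# and distance-based uncertainty.

#' Predict counterfactual expression for a cell
#'
#' Three steps: encode the observed expression into the estimated basal
#' state; recompose it with the scaled target doses \code{dPrime} and the
#' cell's covariate embeddings; decode the counterfactual Gaussian. With
#' \code{dPrime} equal to the observed doses this reduces exactly to the
#' model's reconstruction; with \code{dPrime = 0} the perturbation term is
#' exactly zero (control counterfactual).
#'
#' @param model a \linkS4class{CPAModel}.
#' @param x observed expression vector (length G) or n x G matrix.
#' @param covariates named list/vector of covariate levels (must have been
#'   seen in training), or a data.frame with one row per cell.
#' @param dPrime target dose vector of length M (elementwise >= 0), or an
#'   n x M matrix.
#' @return a \linkS4class{GaussianPrediction}.
#' @export
predictCounterfactual <- function(model, x, covariates, dPrime) {
    X <- .asMatrixRow(x, length(model@genes))
    n <- nrow(X)
    Dp <- if (is.matrix(dPrime)) dPrime else
        matrix(dPrime, n, length(model@perturbations), byrow = TRUE)
    if (any(Dp < 0)) stop("dPrime must be >= 0")
    covDf <- if (is.data.frame(covariates)) covariates else
        as.data.frame(as.list(covariates), stringsAsFactors = FALSE)
    if (nrow(covDf) == 1 && n > 1) covDf <- covDf[rep(1, n), , drop = FALSE]
    basal <- encodeBasal(model, X)
    scaled <- .scaleDoseMatrix(model@params, Dp)
    oh <- .covOnehots(model, covDf)
    Z <- composeLatent(basal, scaled, oh, model@params$Vpert,
                       unname(model@params$Vcov))
    decodeGaussian(model, Z)
}

#' Counterfactual prediction aggregated to a condition
#'
#' Applies \code{\link{predictCounterfactual}} to a batch of cells sharing
#' one covariate assignment and returns the across-cell mean of the
#' predicted means and of the predicted variances, plus the per-cell
#' predictions. Invariant to the order of cells in the batch.
#'
#' @param model a \linkS4class{CPAModel}.
#' @param cells n x G expression matrix (n >= 1), all cells sharing the
#'   same covariates.
#' @param covariates the shared covariate assignment (named vector/list or
#'   a 1-row or n-row data.frame with identical rows).
#' @param dPrime target dose vector of length M.
#' @return list with \code{mean} (length-G), \code{variance} (length-G) and
#'   \code{cells} (a \linkS4class{GaussianPrediction}).
#' @export
predictCondition <- function(model, cells, covariates, dPrime) {
    X <- .asMatrixRow(cells, length(model@genes))
    if (nrow(X) == 0) stop("empty batch")
    covDf <- if (is.data.frame(covariates)) covariates else
        as.data.frame(as.list(covariates), stringsAsFactors = FALSE)
    if (nrow(covDf) > 1) {
        if (nrow(unique(covDf)) != 1)
            stop("cells in a condition batch must share covariates")
        covDf <- unique(covDf)
    }
    pred <- predictCounterfactual(model, X, covDf, dPrime)
    list(mean = colMeans(pred@mean), variance = colMeans(pred@variance),
         cells = pred)
}

#' Basal-free condition embedding
#'
#' The dictionary part of the latent composition,
#' \code{Vpert . [f_1(d_1) ... f_M(d_M)] + sum_j Vcov_j . c_j}, with no
#' encoder involvement; identical to \code{\link{composeLatent}} applied to
#' a zero basal state.
#'
#' @param model a \linkS4class{CPAModel}.
#' @param d dose vector of length M.
#' @param covariates named list/vector of covariate levels.
#' @return latent vector of length \code{latentDim}.
#' @export
conditionEmbedding <- function(model, d, covariates) {
    scaled <- scaleDoses(model, d)
    covDf <- as.data.frame(as.list(covariates), stringsAsFactors = FALSE)
    oh <- .covOnehots(model, covDf)
    drop(composeLatent(matrix(0, 1, model@latentDim), scaled, oh,
                       model@params$Vpert, unname(model@params$Vcov)))
}

.cosineDistance <- function(a, b) {
    if (identical(a, b)) return(0)       # exact zero for identical embeddings
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 && nb == 0) return(0)
    if (na == 0 || nb == 0) return(1)  # zero-norm: orthogonal-equivalent
    1 - sum(a * b) / (na * nb)
}

#' Distance-based uncertainty of a queried condition
#'
#' Embeds the query and every training condition with
#' \code{\link{conditionEmbedding}} and returns the minimum cosine distance,
#' the minimum euclidean distance, and the euclidean arg-min condition. A
#' condition observed in training scores exactly 0 under both distances;
#' cosine ignores magnitude while euclidean does not, so the two can rank
#' queries differently. A zero-norm embedding is treated as cosine distance
#' 1 to any nonzero vector (and 0 to another zero vector). All cells of the
#' same query share one uncertainty value by construction.
#'
#' @param model a \linkS4class{CPAModel}.
#' @param d,covariates the queried condition.
#' @param trainingConditions nonempty character vector of training
#'   condition ids (parsed with \code{\link{parseConditionId}}), or a
#'   \linkS4class{PerturbationExperiment} whose train-split conditions are
#'   used.
#' @return list with \code{uCosine}, \code{uEuclidean},
#'   \code{nearestCondition}.
#' @export
conditionUncertainty <- function(model, d, covariates, trainingConditions) {
    if (is(trainingConditions, "PerturbationExperiment")) {
        sp <- splitLabels(trainingConditions)
        cond <- conditionIds(trainingConditions)
        trainingConditions <- unique(cond[!is.na(sp) & sp == "train"])
    }
    if (length(trainingConditions) == 0)
        stop("trainingConditions must be nonempty")
    zq <- conditionEmbedding(model, d, covariates)
    covNames <- names(model@covariateSchemas)
    uCos <- Inf; uEuc <- Inf; nearest <- NA_character_
    for (cid in trainingConditions) {
        pc <- parseConditionId(cid, model@perturbations, covNames)
        zt <- conditionEmbedding(model, pc$dose, pc$covariates)
        dc <- .cosineDistance(zq, zt)
        de <- sqrt(sum((zq - zt)^2))
        uCos <- min(uCos, dc)
        if (de < uEuc) { uEuc <- de; nearest <- cid }
    }
    list(uCosine = uCos, uEuclidean = uEuc, nearestCondition = nearest)
}
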