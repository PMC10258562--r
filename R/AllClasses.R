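#' @importFrom methods new validObject is setClass setGeneric setMethod show slot
#' @importFrom stats rnorm runif var sd median quantile setNames optim
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' PerturbationExperiment: annotated expression under perturbations
#'
#' A \linkS4class{SummarizedExperiment} subclass holding a log-normalized
#' cells-by-genes expression matrix (stored genes-by-cells, Bioconductor
#' convention) together with the per-cell perturbation dose vector, the
#' categorical covariate assignments, a canonical condition identifier and
#' a train/test/ood split label.
#'
#' Column (cell) annotations carried in \code{colData}:
#' \itemize{
#'   \item \code{dose}: an N x M matrix, \code{dose[i, j] >= 0}; perturbation
#'     \code{j} counts as applied to cell \code{i} iff its dose is positive.
#'   \item one factor column per covariate, levels fixed by the schema.
#'   \item \code{condition}: canonical condition key, a pure function of the
#'     dose row and covariate row (see \code{\link{conditionId}}).
#'   \item \code{split}: one of \code{"train"}, \code{"test"}, \code{"ood"},
#'     or \code{NA} before \code{\link{makeSplit}} is applied.
#' }
#' Metadata carries \code{perturbations} (the M perturbation names) and
#' \code{covariateSchemas} (named list of level vectors).
#'
#' @export
setClass("PerturbationExperiment", contains = "SummarizedExperiment")

.validPerturbationExperiment <- function(object) {
    msg <- character()
    md <- metadata(object)
    perts <- md$perturbations
    schemas <- md$covariateSchemas
    cd <- colData(object)
    if (is.null(perts) || !is.character(perts) || anyDuplicated(perts))
        msg <- c(msg, "metadata$perturbations must be unique character names")
    if (!is.list(schemas) || is.null(names(schemas)))
        msg <- c(msg, "metadata$covariateSchemas must be a named list of level vectors")
    if (!"dose" %in% colnames(cd)) {
        msg <- c(msg, "colData must contain a 'dose' matrix column")
    } else {
        d <- cd$dose
        if (!is.matrix(d) || ncol(d) != length(perts))
            msg <- c(msg, "dose matrix must have one column per perturbation")
        else if (any(!is.finite(d)) || any(d < 0))
            msg <- c(msg, "doses must be finite and >= 0")
    }
    for (cv in names(schemas)) {
        if (!cv %in% colnames(cd)) {
            msg <- c(msg, sprintf("missing covariate column '%s'", cv))
        } else {
            lv <- as.character(cd[[cv]])
            bad <- !lv %in% schemas[[cv]]
            if (any(bad))
                msg <- c(msg, sprintf(
                    "covariate '%s' has values outside its schema: %s", cv,
                    paste(unique(lv[bad]), collapse = ", ")))
        }
    }
    if (!"condition" %in% colnames(cd))
        msg <- c(msg, "colData must contain a 'condition' column")
    if (length(msg)) msg else TRUE
}

setValidity("PerturbationExperiment", .validPerturbationExperiment)

#' Construct a PerturbationExperiment
#'
#' @param X numeric matrix of expression, cells in rows and genes in columns
#'   (transposed internally to the genes-by-cells assay layout). Row names
#'   become cell names, column names gene names.
#' @param doses numeric N x M matrix of doses (0 = not applied); column
#'   names must equal \code{perturbations}.
#' @param covariates data.frame (N rows) of categorical covariate
#'   assignments, one column per covariate.
#' @param perturbations character vector of the M perturbation names.
#' @param covariateSchemas named list giving the allowed levels of each
#'   covariate; defaults to the observed levels.
#' @param assayName assay label, default \code{"logcounts"}.
#' @return a validated \linkS4class{PerturbationExperiment}.
#' @export
PerturbationExperiment <- function(X, doses, covariates,
                                   perturbations = colnames(doses),
                                   covariateSchemas = NULL,
                                   assayName = "logcounts") {
    X <- as.matrix(X)
    doses <- as.matrix(doses)
    if (is.null(perturbations))
        stop("perturbations must be supplied (or doses must have column names)")
    if (nrow(X) != nrow(doses))
        stop("X and doses disagree on the number of cells")
    if (ncol(doses) != length(perturbations))
        stop("doses must have one column per perturbation")
    if (any(!is.finite(doses)) || any(doses < 0))
        stop("doses must be finite and >= 0")
    covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
    if (nrow(covariates) != nrow(X))
        stop("covariates and X disagree on the number of cells")
    if (is.null(covariateSchemas))
        covariateSchemas <- lapply(covariates, function(v) sort(unique(as.character(v))))
    colnames(doses) <- perturbations
    if (is.null(rownames(X)))
        rownames(X) <- sprintf("cell%d", seq_len(nrow(X)))
    if (is.null(colnames(X)))
        colnames(X) <- sprintf("gene%d", seq_len(ncol(X)))
    cond <- conditionId(doses, covariates, perturbations)
    cd <- DataFrame(row.names = rownames(X))
    cd$dose <- doses
    for (cv in names(covariateSchemas))
        cd[[cv]] <- factor(as.character(covariates[[cv]]),
                           levels = covariateSchemas[[cv]])
    cd$condition <- cond
    cd$split <- rep(NA_character_, nrow(X))
    se <- SummarizedExperiment(
        assays = setNames(list(t(X)), assayName),
        colData = cd)
    metadata(se)$perturbations <- perturbations
    metadata(se)$covariateSchemas <- covariateSchemas
    out <- new("PerturbationExperiment", se)
    validObject(out)
    out
}

#' SplitPlan: condition-level holdout plus a seeded train/test partition
#'
#' @slot oodConditions character vector of condition ids held out entirely.
#' @slot testFraction fraction of the remaining cells, drawn per condition,
#'   labelled \code{"test"}.
#' @slot seed integer seed making the partition reproducible.
#' @export
setClass("SplitPlan", representation(
    oodConditions = "character",
    testFraction = "numeric",
    seed = "integer"))

#' @rdname SplitPlan-class
#' @param oodConditions,testFraction,seed see slots.
#' @export
SplitPlan <- function(oodConditions = character(), testFraction = 0.2,
                      seed = 1L) {
    if (length(testFraction) != 1 || testFraction <= 0 || testFraction >= 1)
        stop("testFraction must lie in (0, 1)")
    new("SplitPlan", oodConditions = as.character(oodConditions),
        testFraction = testFraction, seed = as.integer(seed))
}

#' SyntheticTruth: hidden parameters of the synthetic generator
#'
#' The generator mirrors the assumed data-generating process: a basal latent
#' state drawn from a small Gaussian mixture, shifted additively by
#' per-perturbation latent embeddings scaled through saturating Hill
#' dose-response curves and by covariate embeddings, then pushed through a
#' fixed nonlinear decoder map with Gaussian noise on the log-expression
#' scale. Optional pairwise latent offsets plant non-additive interactions.
#'
#' @slot latentDim latent dimensionality of the truth.
#' @slot perturbations,covariateSchemas vocabularies.
#' @slot Vpert latentDim x M true perturbation embeddings.
#' @slot Vcov list of latentDim x K_j true covariate embeddings.
#' @slot hillK,hillN per-perturbation Hill half-max (> 0) and exponent (> 0);
#'   the curve h(d) = d^n / (k^n + d^n) satisfies h(0) = 0, is strictly
#'   increasing and saturates at 1.
#' @slot decoder list of weight matrices of the fixed latent-to-expression
#'   map (either linear or a 2-hidden-layer tanh network).
#' @slot decoderKind "tanh" or "linear".
#' @slot noiseSd observation noise standard deviation (> 0).
#' @slot basalMeans list of mixture component means (latent vectors).
#' @slot basalSd within-component standard deviation.
#' @slot interactions named list of latent offset vectors, keyed by the
#'   sorted pair key "A+B"; empty for a purely additive truth.
#' @slot nGenes number of genes G.
#' @slot seed generator seed for the fixed maps.
#' @export
setClass("SyntheticTruth", representation(
    latentDim = "integer",
    perturbations = "character",
    covariateSchemas = "list",
    Vpert = "matrix",
    Vcov = "list",
    hillK = "numeric",
    hillN = "numeric",
    decoder = "list",
    decoderKind = "character",
    noiseSd = "numeric",
    basalMeans = "list",
    basalSd = "numeric",
    interactions = "list",
    nGenes = "integer",
    seed = "integer"))

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    if (ncol(object@Vpert) != length(object@perturbations))
        msg <- c(msg, "Vpert needs one column per perturbation")
    if (any(object@hillK <= 0) || any(object@hillN <= 0))
        msg <- c(msg, "Hill parameters must be positive")
    if (object@noiseSd <= 0)
        msg <- c(msg, "noiseSd must be > 0")
    if (length(msg)) msg else TRUE
})

#' GaussianPrediction: per-gene predicted mean and variance
#'
#' @slot mean,variance numeric matrices (cells x genes); variances are
#'   strictly positive after the variance link.
#' @export
setClass("GaussianPrediction", representation(
    mean = "matrix", variance = "matrix"))

setValidity("GaussianPrediction", function(object) {
    if (!all(dim(object@mean) == dim(object@variance)))
        return("mean and variance must have equal dimensions")
    if (any(object@variance <= 0))
        return("variances must be strictly positive")
    TRUE
})

#' CPAModel: the compositional perturbation autoencoder
#'
#' Holds the encoder, the Gaussian decoder (shared trunk with mean and
#' variance heads), the perturbation and covariate embedding dictionaries,
#' the per-perturbation dose scalers (constrained to vanish at dose zero),
#' and the adversarial discriminators used to strip perturbation/covariate
#' information from the basal state.
#'
#' @slot genes gene names the model was built for.
#' @slot perturbations,covariateSchemas vocabularies.
#' @slot latentDim embedding dimension.
#' @slot params list of network parameter blocks (see \code{R/nn.R}).
#' @slot advPert adversary target mode for the perturbation head:
#'   \code{"softmax"} (single perturbations only, control its own class) or
#'   \code{"multilabel"} (binary cross-entropy on applied indicators).
#' @slot config training configuration (list, see \code{\link{cpaConfig}}).
#' @slot history per-epoch loss records (data.frame).
#' @slot trained logical.
#' @export
setClass("CPAModel", representation(
    genes = "character",
    perturbations = "character",
    covariateSchemas = "list",
    latentDim = "integer",
    params = "list",
    advPert = "character",
    config = "list",
    history = "data.frame",
    trained = "logical"))

#' InteractionMetrics: pairwise genetic-interaction summary
#'
#' @slot pair character(2): the two single perturbations.
#' @slot c1,c2 no-intercept regression coefficients of the double-delta on
#'   the two single deltas.
#' @slot fitDcor distance correlation between fitted and observed double
#'   deltas.
#' @slot magnitude sqrt(c1^2 + c2^2).
#' @slot dominance log10(|c1| / |c2|), clipped to +/- 6 when a coefficient
#'   is zero.
#' @slot dcorSingles dcor(delta_a, delta_b).
#' @slot dcorJointDouble dcor([delta_a delta_b], delta_ab).
#' @slot equalContrib min(dcor(delta_a, delta_ab), dcor(delta_b, delta_ab))
#'   / max(...).
#' @export
setClass("InteractionMetrics", representation(
    pair = "character",
    c1 = "numeric", c2 = "numeric", fitDcor = "numeric",
    magnitude = "numeric", dominance = "numeric",
    dcorSingles = "numeric", dcorJointDouble = "numeric",
    equalContrib = "numeric"))
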