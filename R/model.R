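#' Training configuration with the method's reference defaults
#'
#' Returns the hyperparameter set used for training, with the CPA
#' reference default values: embedding dimension 256, batch size 128, learning-rate
#' decay every 45 epochs, autoencoder lr 1e-3 / weight decay 1e-6, dose
#' scaler lr 1e-3 / weight decay 1e-7 (hidden 64 x 2 layers), discriminator
#' lr 3e-4 / weight decay 1e-4 (hidden 128 x 3 layers), adversary
#' regularization strength lambda = 5, gradient penalty coefficient 3, and
#' 3 discriminator steps per autoencoder step. Encoder and decoder are MLPs
#' with 4 hidden layers of 512 units (ReLU). Synthetic desk-scale runs
#' shrink the sizes through the arguments.
#'
#' @param embeddingDim latent/embedding dimension.
#' @param batchSize minibatch size.
#' @param epochs training epochs.
#' @param lrAE,wdAE autoencoder (encoder/decoder/dictionaries) Adam rate and
#'   weight decay.
#' @param lrDoser,wdDoser dose-scaler Adam rate and weight decay.
#' @param lrDisc,wdDisc discriminator Adam rate and weight decay.
#' @param lambdaAdv adversary regularization strength (lambda).
#' @param gradPenaltyCoef gradient-penalty coefficient (gamma).
#' @param discSteps discriminator updates per autoencoder update.
#' @param lrDecayEpochs decay interval: every this many epochs all learning
#'   rates are multiplied by \code{lrDecayFactor}.
#' @param lrDecayFactor multiplicative decay factor.
#' @param encoderHidden,encoderLayers encoder/decoder MLP width and depth.
#' @param doserHidden,doserLayers dose-scaler MLP width and depth.
#' @param discHidden,discLayers discriminator MLP width and depth.
#' @param seed integer seed controlling initialization and batching.
#' @return a named list.
#' @export
cpaConfig <- function(embeddingDim = 256L, batchSize = 128L, epochs = 100L,
                      lrAE = 1e-3, wdAE = 1e-6,
                      lrDoser = 1e-3, wdDoser = 1e-7,
                      lrDisc = 3e-4, wdDisc = 1e-4,
                      lambdaAdv = 5, gradPenaltyCoef = 3,
                      discSteps = 3L, lrDecayEpochs = 45L,
                      lrDecayFactor = 0.1,
                      encoderHidden = 512L, encoderLayers = 4L,
                      doserHidden = 64L, doserLayers = 2L,
                      discHidden = 128L, discLayers = 3L,
                      seed = 1L) {
    cfg <- list(embeddingDim = as.integer(embeddingDim),
                batchSize = as.integer(batchSize), epochs = as.integer(epochs),
                lrAE = lrAE, wdAE = wdAE, lrDoser = lrDoser, wdDoser = wdDoser,
                lrDisc = lrDisc, wdDisc = wdDisc, lambdaAdv = lambdaAdv,
                gradPenaltyCoef = gradPenaltyCoef,
                discSteps = as.integer(discSteps),
                lrDecayEpochs = as.integer(lrDecayEpochs),
                lrDecayFactor = lrDecayFactor,
                encoderHidden = as.integer(encoderHidden),
                encoderLayers = as.integer(encoderLayers),
                doserHidden = as.integer(doserHidden),
                doserLayers = as.integer(doserLayers),
                discHidden = as.integer(discHidden),
                discLayers = as.integer(discLayers),
                seed = as.integer(seed))
    stopifnot(cfg$lrAE > 0, cfg$lrDisc > 0, cfg$lrDoser > 0,
              cfg$lambdaAdv >= 0, cfg$gradPenaltyCoef >= 0,
              cfg$discSteps >= 1L, cfg$batchSize >= 2L)
    cfg
}

#' Construct an untrained compositional perturbation autoencoder
#'
#' Initializes the encoder, the Gaussian decoder (shared ReLU trunk with
#' linear mean and raw-variance heads; hidden layers of both are
#' batch-normalized, which also keeps the basal state on a bounded scale so
#' the adversarial game cannot be evaded by inflating its norm), the
#' perturbation dictionary
#' (latentDim x M), one covariate dictionary per covariate, one dose-scaler
#' network per perturbation (applied as \code{g(d) - g(0)} so the
#' zero-dose constraint holds exactly at any parameter value), and the
#' adversarial discriminators.
#'
#' @param genes character vector of gene names (length G).
#' @param perturbations character vector of perturbation names (length M).
#' @param covariateSchemas named list of covariate level vectors.
#' @param config a \code{\link{cpaConfig}} list.
#' @param advPert \code{"softmax"} (single perturbations; control is its own
#'   class) or \code{"multilabel"} (binary indicator per perturbation, for
#'   combinatorial data).
#' @return an untrained \linkS4class{CPAModel}.
#' @export
cpaModel <- function(genes, perturbations, covariateSchemas,
                     config = cpaConfig(),
                     advPert = c("softmax", "multilabel")) {
    advPert <- match.arg(advPert)
    G <- length(genes); M <- length(perturbations)
    d <- config$embeddingDim
    stopifnot(G > 0, M > 0)
    params <- withSeed(config$seed, {
        encSizes <- c(G, rep(config$encoderHidden, config$encoderLayers), d)
        encActs <- c(rep("relu", config$encoderLayers), "linear")
        encBn <- c(rep(TRUE, config$encoderLayers), FALSE)
        decSizes <- c(d, rep(config$encoderHidden, config$encoderLayers))
        decActs <- rep("relu", config$encoderLayers)
        decBn <- rep(TRUE, config$encoderLayers)
        dHid <- if (config$encoderLayers == 0L) d else config$encoderHidden
        doserSizes <- c(1, rep(config$doserHidden, config$doserLayers), 1)
        doserActs <- c(rep("tanh", config$doserLayers), "linear")
        nPertClasses <- if (advPert == "softmax") M + 1L else M
        discP <- c(d, rep(config$discHidden, config$discLayers), nPertClasses)
        discActs <- c(rep("relu", config$discLayers), "linear")
        list(
            encoder = nnInit(encSizes, encActs, encBn),
            decTrunk = nnInit(decSizes, decActs, decBn),
            decMu = nnInit(c(dHid, G), "linear"),
            decVar = nnInit(c(dHid, G), "linear"),
            Vpert = matrix(rnorm(d * M, sd = 1 / sqrt(d)), d, M,
                           dimnames = list(NULL, perturbations)),
            Vcov = lapply(covariateSchemas, function(lv)
                matrix(rnorm(d * length(lv), sd = 1 / sqrt(d)), d,
                       length(lv), dimnames = list(NULL, lv))),
            dosers = setNames(lapply(seq_len(M), function(j)
                nnInit(doserSizes, doserActs)), perturbations),
            discPert = nnInit(discP, discActs),
            discCov = lapply(covariateSchemas, function(lv)
                nnInit(c(d, rep(config$discHidden, config$discLayers),
                         length(lv)), discActs))
        )
    })
    new("CPAModel", genes = as.character(genes),
        perturbations = perturbations,
        covariateSchemas = covariateSchemas,
        latentDim = as.integer(d), params = params, advPert = advPert,
        config = config, history = data.frame(), trained = FALSE)
}

#' Encode expression into the estimated basal state
#'
#' @param model a \linkS4class{CPAModel}.
#' @param x expression vector of length G, or an n x G matrix.
#' @return latent vector (or n x latentDim matrix) of the estimated basal
#'   state; deterministic given fixed weights.
#' @export
encodeBasal <- function(model, x) {
    vec <- !is.matrix(x)
    X <- .asMatrixRow(x, length(model@genes))
    if (ncol(X) != length(model@genes))
        stop(sprintf("expression has %d genes, model expects %d", ncol(X),
                     length(model@genes)))
    Z <- nnForward(model@params$encoder, X)
    if (vec) drop(Z) else Z
}

# Internal: doser output for a dose matrix (n x M); f_j(d) = g_j(d) - g_j(0).
.scaleDoseMatrix <- function(params, D) {
    M <- ncol(D)
    out <- D * 0
    for (j in seq_len(M)) {
        g <- params$dosers[[j]]
        gd <- nnForward(g, matrix(D[, j], ncol = 1))
        g0 <- nnForward(g, matrix(0, 1, 1))
        out[, j] <- gd - as.numeric(g0)
    }
    out
}

#' Apply the learned dose-response scalers
#'
#' Component j of the output is \code{f_j(d_j) = g_j(d_j) - g_j(0)} for the
#' unconstrained scalar network \code{g_j}, so a zero dose maps to exactly 0
#' at any parameter value.
#'
#' @param model a \linkS4class{CPAModel}.
#' @param d dose vector of length M (or n x M matrix), elementwise >= 0.
#' @return scaled dose vector/matrix of the same shape.
#' @export
scaleDoses <- function(model, d) {
    vec <- !is.matrix(d)
    D <- .asMatrixRow(d, length(model@perturbations))
    if (ncol(D) != length(model@perturbations))
        stop("dose vector length does not match the model's perturbations")
    if (any(D < 0)) stop("doses must be >= 0")
    out <- .scaleDoseMatrix(model@params, D)
    if (vec) drop(out) else out
}

#' Compose the perturbed latent state
#'
#' Exact linear composition
#' \code{z = z_basal + Vpert \%*\% scaled + sum_j Vcov[[j]] \%*\% onehot_j};
#' additive in every term.
#'
#' @param basal latent vector (or n x d matrix) of basal states.
#' @param scaled scaled dose vector of length M (or n x M matrix).
#' @param covOnehots list over covariates of one-hot vectors (length K_j) or
#'   n x K_j matrices; may be an empty list.
#' @param Vpert d x M perturbation dictionary.
#' @param Vcov list of d x K_j covariate dictionaries (same order as
#'   \code{covOnehots}).
#' @return composed latent, same shape as \code{basal}.
#' @export
composeLatent <- function(basal, scaled, covOnehots, Vpert, Vcov = list()) {
    vec <- !is.matrix(basal)
    B <- .asMatrixRow(basal, length(basal))
    S <- .asMatrixRow(scaled, ncol(Vpert))
    if (ncol(B) != nrow(Vpert)) stop("basal dimension does not match Vpert")
    if (ncol(S) != ncol(Vpert)) stop("scaled dose length does not match Vpert")
    Z <- B + S %*% t(Vpert)
    if (length(covOnehots) != length(Vcov))
        stop("covOnehots and Vcov must have equal length")
    for (j in seq_along(Vcov)) {
        C <- .asMatrixRow(covOnehots[[j]], ncol(Vcov[[j]]))
        if (ncol(C) != ncol(Vcov[[j]]))
            stop(sprintf("one-hot %d has wrong length", j))
        Z <- Z + C %*% t(Vcov[[j]])
    }
    if (vec) drop(Z) else Z
}

#' Variance link: softplus plus a stability floor
#'
#' \code{s(v) = log(1 + exp(v)) + 1e-3}: strictly positive, monotone
#' increasing, asymptote 1e-3 as \code{v -> -Inf} and \code{s(v) ~ v} for
#' large \code{v}. Applied elementwise to the decoder's raw variance head.
#'
#' @param v numeric (finite).
#' @return linked variance, same shape.
#' @export
varianceLink <- function(v) {
    if (any(!is.finite(v))) stop("variance link requires finite input")
    softplus(v) + 1e-3
}

#' Decode a latent state into a Gaussian prediction
#'
#' @param model a \linkS4class{CPAModel}.
#' @param z latent vector (length latentDim) or n x latentDim matrix.
#' @return a \linkS4class{GaussianPrediction} with per-gene means and
#'   post-link (strictly positive) variances.
#' @export
decodeGaussian <- function(model, z) {
    Z <- .asMatrixRow(z, model@latentDim)
    if (ncol(Z) != model@latentDim)
        stop(sprintf("latent has dimension %d, model expects %d", ncol(Z),
                     model@latentDim))
    H <- nnForward(model@params$decTrunk, Z)
    mu <- nnForward(model@params$decMu, H)
    rawVar <- nnForward(model@params$decVar, H)
    colnames(mu) <- colnames(rawVar) <- model@genes
    new("GaussianPrediction", mean = mu, variance = varianceLink(rawVar))
}

# Internal: one-hot matrices for the covariate assignment of a batch.
.covOnehots <- function(model, covDf) {
    sch <- model@covariateSchemas
    lapply(names(sch), function(cv) {
        lv <- as.character(covDf[[cv]])
        bad <- setdiff(unique(lv), sch[[cv]])
        if (length(bad))
            stop(sprintf("covariate '%s' has unseen level(s): %s", cv,
                         paste(bad, collapse = ", ")))
        idx <- match(lv, sch[[cv]])
        oh <- matrix(0, length(lv), length(sch[[cv]]))
        oh[cbind(seq_along(lv), idx)] <- 1
        oh
    })
}

# Internal full forward pass on a batch: returns prediction plus latents.
.modelForward <- function(model, X, D, covDf) {
    basal <- encodeBasal(model, X)
    scaled <- .scaleDoseMatrix(model@params, D)
    oh <- .covOnehots(model, covDf)
    Z <- composeLatent(basal, scaled, oh, model@params$Vpert,
                       unname(model@params$Vcov))
    pred <- decodeGaussian(model, Z)
    list(pred = pred, basal = basal, z = Z, scaled = scaled, onehots = oh)
}
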