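# Losses and the two-phase adversarial optimization loop.

#' Gaussian negative log-likelihood reconstruction loss
#'
#' Mean over cells and genes of
#' \code{0.5 * log(var) + (mean - x)^2 / (2 * var)} with \code{var} the
#' post-link decoder variance. Zero when the prediction matches exactly
#' with unit variance; for a single gene the minimum over \code{var} sits
#' at \code{var = residual^2}.
#'
#' @param pred a \linkS4class{GaussianPrediction}.
#' @param x observed expression, same shape as \code{predictedMean(pred)}
#'   (vector or matrix).
#' @return scalar loss.
#' @export
reconstructionLoss <- function(pred, x) {
    mu <- pred@mean
    v <- pred@variance
    if (!is.matrix(x) && length(x) != length(mu))
        stop("shape mismatch between pred and x")
    X <- .asMatrixRow(x, ncol(mu))
    if (!all(dim(X) == dim(mu))) stop("shape mismatch between pred and x")
    if (any(v <= 0)) stop("variances must be positive")
    mean(0.5 * log(v) + (mu - X)^2 / (2 * v))
}

# ---- adversary internals --------------------------------------------------

# Class targets for the perturbation head. softmax: one class per
# perturbation plus a final control class; multilabel: applied indicator.
.pertTargets <- function(advPert, D) {
    if (advPert == "multilabel") return((D > 0) * 1)
    applied <- rowSums(D > 0)
    if (any(applied > 1))
        stop("softmax perturbation adversary requires single perturbations; use multilabel")
    idx <- apply(D > 0, 1, function(r) if (any(r)) which(r)[1] else 0L)
    ifelse(idx == 0L, ncol(D) + 1L, idx)
}

.covTargets <- function(schemas, covDf) {
    lapply(names(schemas), function(cv) {
        y <- match(as.character(covDf[[cv]]), schemas[[cv]])
        if (any(is.na(y)))
            stop(sprintf("covariate '%s' has labels outside the vocabulary", cv))
        y
    })
}

# Forward one discriminator head; returns per-sample losses + caches.
.headForward <- function(net, basal, target, type) {
    fw <- nnForward(net, basal, cache = TRUE)
    if (type == "multilabel") {
        ls <- bceLogits(fw$out, target)
    } else {
        ls <- softmaxCE(fw$out, target)
    }
    list(fw = fw, loss = ls$loss, dlogits = ls$dlogits, prob = ls$prob)
}

#' Adversary cross-entropy losses on a basal batch
#'
#' The covariate heads use softmax cross-entropy against the one-hot level;
#' the perturbation head uses either a softmax over perturbation identities
#' (control as its own class) or, for combinatorial data, a multi-label
#' binary cross-entropy on the applied-perturbation indicator
#' \code{1[d > 0]}.
#'
#' @param model a \linkS4class{CPAModel}.
#' @param basal n x latentDim matrix of basal states.
#' @param targets list with \code{doses} (n x M dose matrix) and
#'   \code{covariates} (data.frame of covariate levels).
#' @return list with elements \code{pert}, \code{cov} (named numeric) and
#'   \code{total}.
#' @export
adversaryLosses <- function(model, basal, targets) {
    basal <- .asMatrixRow(basal, model@latentDim)
    D <- .asMatrixRow(targets$doses, length(model@perturbations))
    covDf <- as.data.frame(targets$covariates)
    p <- model@params
    pt <- .pertTargets(model@advPert, D)
    type <- if (model@advPert == "multilabel") "multilabel" else "softmax"
    hp <- .headForward(p$discPert, basal, pt, type)
    ct <- .covTargets(model@covariateSchemas, covDf)
    covLoss <- numeric(0)
    for (j in seq_along(ct)) {
        hc <- .headForward(p$discCov[[j]], basal, ct[[j]], "softmax")
        covLoss[names(model@covariateSchemas)[j]] <- mean(hc$loss)
    }
    list(pert = mean(hp$loss), cov = covLoss,
         total = mean(hp$loss) + sum(covLoss))
}

#' Gradient penalty of a discriminator head
#'
#' The coefficient-weighted mean squared L2 norm of the gradient of the
#' per-sample head loss with respect to its basal input, computed exactly
#' by reverse-mode differentiation. Zero for a constant head; always
#' non-negative.
#'
#' @param net a discriminator network (list with \code{W}, \code{b},
#'   \code{act}), e.g. \code{model@params$discPert}.
#' @param basal n x d input batch.
#' @param targets class index vector (softmax) or n x M indicator matrix
#'   (multilabel).
#' @param type \code{"softmax"} or \code{"multilabel"}.
#' @param coef penalty coefficient gamma.
#' @return scalar penalty.
#' @export
gradientPenalty <- function(net, basal, targets,
                            type = c("softmax", "multilabel"), coef = 1) {
    type <- match.arg(type)
    h <- .headForward(net, basal, targets, type)
    g <- nnBackward(net, h$fw, h$dlogits)$dX   # row i = grad of loss_i
    coef * mean(rowSums(g^2))
}

# Penalty parameter-gradient via a random-projection central difference:
# E_u[d * ((l(z+eps*u) - l(z-eps*u)) / (2*eps))^2] -> |grad_z l|^2 for unit
# u; the estimator's theta-gradient only needs ordinary backprop through the
# two shifted passes. Adds grads into `acc` (same structure as net W/b).
.penaltyGrads <- function(net, basal, target, type, coef) {
    n <- nrow(basal); d <- ncol(basal)
    eps <- 1e-2
    u <- matrix(rnorm(n * d), n, d)
    u <- u / sqrt(rowSums(u^2))
    hp <- .headForward(net, basal + eps * u, target, type)
    hm <- .headForward(net, basal - eps * u, target, type)
    delta <- (hp$loss - hm$loss) / (2 * eps)
    value <- coef * d * mean(delta^2)
    w <- coef * d * 2 * delta / (n * 2 * eps)
    gp <- nnBackward(net, hp$fw, hp$dlogits * w)
    gm <- nnBackward(net, hm$fw, hm$dlogits * (-w))
    grads <- list(W = Map(`+`, gp$W, gm$W), b = Map(`+`, gp$b, gm$b),
                  g = Map(`+`, gp$g, gm$g), be = Map(`+`, gp$be, gm$be))
    list(value = value, grads = grads)
}

# ---- parameter-group plumbing --------------------------------------------

.wb <- function(net) list(W = net$W, b = net$b, g = net$g, be = net$be)

.setWb <- function(net, wb) {
    net$W <- wb$W; net$b <- wb$b; net$g <- wb$g; net$be <- wb$be
    net
}

.aeGroup <- function(p) list(encoder = .wb(p$encoder),
                             decTrunk = .wb(p$decTrunk),
                             decMu = .wb(p$decMu), decVar = .wb(p$decVar),
                             Vpert = p$Vpert, Vcov = p$Vcov)

.setAeGroup <- function(p, g) {
    p$encoder <- .setWb(p$encoder, g$encoder)
    p$decTrunk <- .setWb(p$decTrunk, g$decTrunk)
    p$decMu <- .setWb(p$decMu, g$decMu)
    p$decVar <- .setWb(p$decVar, g$decVar)
    p$Vpert <- g$Vpert
    p$Vcov <- g$Vcov
    p
}

.doserGroup <- function(p) lapply(p$dosers, .wb)

.setDoserGroup <- function(p, g) {
    p$dosers <- Map(.setWb, p$dosers, g)
    p
}

.discGroup <- function(p) list(discPert = .wb(p$discPert),
                               discCov = lapply(p$discCov, .wb))

.setDiscGroup <- function(p, g) {
    p$discPert <- .setWb(p$discPert, g$discPert)
    p$discCov <- Map(.setWb, p$discCov, g$discCov)
    p
}

.zeroLike <- function(x) rapply(x, function(v) v * 0, how = "replace")

# ---- the two optimization phases -----------------------------------------

# batch: list(X = n x G, D = n x M, cov = data.frame).
# Returns list(params, opt, record).
.discStepCore <- function(params, opt, batch, cfg, advPert, schemas) {
    basal <- nnForward(params$encoder, batch$X)
    n <- nrow(basal)
    type <- if (advPert == "multilabel") "multilabel" else "softmax"
    pt <- .pertTargets(advPert, batch$D)
    ct <- .covTargets(schemas, batch$cov)
    grads <- .zeroLike(.discGroup(params))
    hp <- .headForward(params$discPert, basal, pt, type)
    bk <- nnBackward(params$discPert, hp$fw, hp$dlogits / n)
    pen <- .penaltyGrads(params$discPert, basal, pt, type,
                         cfg$gradPenaltyCoef)
    grads$discPert <- list(W = Map(`+`, bk$W, pen$grads$W),
                           b = Map(`+`, bk$b, pen$grads$b),
                           g = Map(`+`, bk$g, pen$grads$g),
                           be = Map(`+`, bk$be, pen$grads$be))
    lossPert <- mean(hp$loss)
    penalty <- pen$value
    lossCov <- numeric(0)
    for (j in seq_along(ct)) {
        hc <- .headForward(params$discCov[[j]], basal, ct[[j]], "softmax")
        bkc <- nnBackward(params$discCov[[j]], hc$fw, hc$dlogits / n)
        penC <- .penaltyGrads(params$discCov[[j]], basal, ct[[j]], "softmax",
                              cfg$gradPenaltyCoef)
        grads$discCov[[j]] <- list(W = Map(`+`, bkc$W, penC$grads$W),
                                   b = Map(`+`, bkc$b, penC$grads$b),
                                   g = Map(`+`, bkc$g, penC$grads$g),
                                   be = Map(`+`, bkc$be, penC$grads$be))
        lossCov[names(schemas)[j]] <- mean(hc$loss)
        penalty <- penalty + penC$value
    }
    upd <- adamStep(.discGroup(params), grads, opt$disc,
                    lr = cfg$lrDisc * opt$decay, wd = cfg$wdDisc)
    params <- .setDiscGroup(params, upd$params)
    opt$disc <- upd$opt
    list(params = params, opt = opt,
         record = list(advPert = lossPert, advCov = lossCov,
                       penalty = penalty))
}

.aeStepCore <- function(params, opt, batch, cfg, advPert, schemas, onehots) {
    n <- nrow(batch$X)
    G <- ncol(batch$X)
    M <- ncol(batch$D)
    encFw <- nnForward(params$encoder, batch$X, cache = TRUE, train = TRUE)
    basal <- encFw$out
    scaled <- matrix(0, n, M)
    doserFw <- vector("list", M)
    doser0Fw <- vector("list", M)
    for (j in seq_len(M)) {
        doserFw[[j]] <- nnForward(params$dosers[[j]],
                                  matrix(batch$D[, j], ncol = 1), cache = TRUE)
        doser0Fw[[j]] <- nnForward(params$dosers[[j]], matrix(0, 1, 1),
                                   cache = TRUE)
        scaled[, j] <- doserFw[[j]]$out - as.numeric(doser0Fw[[j]]$out)
    }
    Z <- basal + scaled %*% t(params$Vpert)
    for (j in seq_along(params$Vcov))
        Z <- Z + onehots[[j]] %*% t(params$Vcov[[j]])
    trunkFw <- nnForward(params$decTrunk, Z, cache = TRUE, train = TRUE)
    muFw <- nnForward(params$decMu, trunkFw$out, cache = TRUE)
    varFw <- nnForward(params$decVar, trunkFw$out, cache = TRUE)
    v <- softplus(varFw$out) + 1e-3
    resid <- muFw$out - batch$X
    recon <- mean(0.5 * log(v) + resid^2 / (2 * v))
    dMu <- resid / v / (n * G)
    sig <- 1 / (1 + exp(-varFw$out))
    dRawVar <- (0.5 / v - resid^2 / (2 * v^2)) * sig / (n * G)
    muBk <- nnBackward(params$decMu, muFw, dMu)
    varBk <- nnBackward(params$decVar, varFw, dRawVar)
    trunkBk <- nnBackward(params$decTrunk, trunkFw, muBk$dX + varBk$dX)
    dZ <- trunkBk$dX
    # adversary losses enter with weight -lambda; discriminators are frozen
    type <- if (advPert == "multilabel") "multilabel" else "softmax"
    pt <- .pertTargets(advPert, batch$D)
    ct <- .covTargets(schemas, batch$cov)
    hp <- .headForward(params$discPert, basal, pt, type)
    dBasalAdv <- nnBackward(params$discPert, hp$fw, hp$dlogits / n)$dX
    advTotal <- mean(hp$loss)
    for (j in seq_along(ct)) {
        hc <- .headForward(params$discCov[[j]], basal, ct[[j]], "softmax")
        dBasalAdv <- dBasalAdv +
            nnBackward(params$discCov[[j]], hc$fw, hc$dlogits / n)$dX
        advTotal <- advTotal + mean(hc$loss)
    }
    dBasal <- dZ - cfg$lambdaAdv * dBasalAdv
    encBk <- nnBackward(params$encoder, encFw, dBasal)
    dVpert <- crossprod(dZ, scaled)           # d x M
    dScaled <- dZ %*% params$Vpert            # n x M
    dVcov <- vector("list", length(params$Vcov))
    names(dVcov) <- names(params$Vcov)
    for (j in seq_along(params$Vcov))
        dVcov[[j]] <- t(crossprod(onehots[[j]], dZ))  # d x K_j
    gradOf <- function(bk) list(W = bk$W, b = bk$b, g = bk$g, be = bk$be)
    aeGrads <- list(encoder = gradOf(encBk),
                    decTrunk = gradOf(trunkBk),
                    decMu = gradOf(muBk),
                    decVar = gradOf(varBk),
                    Vpert = dVpert, Vcov = dVcov)
    doserGrads <- vector("list", M)
    for (j in seq_len(M)) {
        bkd <- nnBackward(params$dosers[[j]], doserFw[[j]],
                          matrix(dScaled[, j], ncol = 1))
        bk0 <- nnBackward(params$dosers[[j]], doser0Fw[[j]],
                          matrix(-sum(dScaled[, j]), 1, 1))
        doserGrads[[j]] <- list(W = Map(`+`, bkd$W, bk0$W),
                                b = Map(`+`, bkd$b, bk0$b),
                                g = Map(`+`, bkd$g, bk0$g),
                                be = Map(`+`, bkd$be, bk0$be))
    }
    names(doserGrads) <- names(params$dosers)
    updA <- adamStep(.aeGroup(params), aeGrads, opt$ae,
                     lr = cfg$lrAE * opt$decay, wd = cfg$wdAE)
    params <- .setAeGroup(params, updA$params)
    opt$ae <- updA$opt
    updD <- adamStep(.doserGroup(params), doserGrads, opt$doser,
                     lr = cfg$lrDoser * opt$decay, wd = cfg$wdDoser)
    params <- .setDoserGroup(params, updD$params)
    opt$doser <- updD$opt
    params$encoder <- nnUpdateRunning(params$encoder, encFw)
    params$decTrunk <- nnUpdateRunning(params$decTrunk, trunkFw)
    list(params = params, opt = opt,
         record = list(reconstruction = recon, adversary = advTotal))
}

.freshOpt <- function(params, decay = 1) {
    list(ae = adamInit(.aeGroup(params)),
         doser = adamInit(.doserGroup(params)),
         disc = adamInit(.discGroup(params)),
         decay = decay)
}

.batchOf <- function(X, D, covDf, idx)
    list(X = X[idx, , drop = FALSE], D = D[idx, , drop = FALSE],
         cov = covDf[idx, , drop = FALSE])

#' One discriminator update on a batch
#'
#' Minimizes the adversary cross-entropies plus the gradient penalty by
#' updating only the discriminator parameters; encoder, decoder,
#' dictionaries and dose scalers are untouched.
#'
#' @param model a \linkS4class{CPAModel}.
#' @param batch list with \code{X} (n x G), \code{doses} (n x M) and
#'   \code{covariates} (data.frame).
#' @param cfg a \code{\link{cpaConfig}}; defaults to the model's.
#' @return list with the updated \code{model} and the \code{losses} record.
#' @export
discriminatorStep <- function(model, batch, cfg = model@config) {
    b <- list(X = .asMatrixRow(batch$X, length(model@genes)),
              D = .asMatrixRow(batch$doses, length(model@perturbations)),
              cov = as.data.frame(batch$covariates))
    opt <- .freshOpt(model@params)
    r <- .discStepCore(model@params, opt, b, cfg, model@advPert,
                       model@covariateSchemas)
    model@params <- r$params
    list(model = model, losses = r$record)
}

#' One autoencoder update on a batch
#'
#' Minimizes reconstruction minus \code{lambda} times the adversary losses
#' by updating the encoder, decoder, embedding dictionaries and dose
#' scalers; discriminator parameters are untouched, and the dose scalers
#' keep \code{f_j(0) = 0} exactly by construction.
#'
#' @inheritParams discriminatorStep
#' @return list with the updated \code{model} and the \code{losses} record.
#' @export
autoencoderStep <- function(model, batch, cfg = model@config) {
    b <- list(X = .asMatrixRow(batch$X, length(model@genes)),
              D = .asMatrixRow(batch$doses, length(model@perturbations)),
              cov = as.data.frame(batch$covariates))
    oh <- .covOnehots(model, b$cov)
    opt <- .freshOpt(model@params)
    r <- .aeStepCore(model@params, opt, b, cfg, model@advPert,
                     model@covariateSchemas, oh)
    model@params <- r$params
    list(model = model, losses = r$record)
}

# Head accuracies on a basal batch, used as the disentanglement diagnostic.
.headAccuracies <- function(params, advPert, schemas, basal, D, covDf) {
    type <- if (advPert == "multilabel") "multilabel" else "softmax"
    pt <- .pertTargets(advPert, D)
    hp <- .headForward(params$discPert, basal, pt, type)
    accP <- if (type == "softmax") {
        mean(max.col(hp$prob, ties.method = "first") == pt)
    } else {
        mean((hp$prob > 0.5) == (pt > 0))
    }
    ct <- .covTargets(schemas, covDf)
    accC <- numeric(0)
    for (j in seq_along(ct)) {
        hc <- .headForward(params$discCov[[j]], basal, ct[[j]], "softmax")
        accC[names(schemas)[j]] <- mean(max.col(hc$prob,
            ties.method = "first") == ct[[j]])
    }
    list(pert = accP, cov = accC)
}

#' Train a compositional perturbation autoencoder
#'
#' Runs the two-phase adversarial loop: per iteration,
#' \code{cfg$discSteps} discriminator updates (adversary cross-entropy plus
#' gradient penalty, discriminator parameters only) followed by one
#' autoencoder update (Gaussian reconstruction minus \code{lambda} times
#' the adversary losses; encoder, decoder, dictionaries, dose scalers).
#' Learning rates are multiplied by \code{cfg$lrDecayFactor} every
#' \code{cfg$lrDecayEpochs} epochs. After each epoch the test-split
#' reconstruction loss is evaluated and the best-scoring parameters are
#' kept (model selection on the test split). Fully deterministic for a
#' fixed seed under single-threaded execution.
#'
#' @param ds a \linkS4class{PerturbationExperiment} with split labels (see
#'   \code{\link{makeSplit}}); ood cells are never visited.
#' @param cfg a \code{\link{cpaConfig}}.
#' @param advPert \code{"auto"} (multilabel iff some cell carries more than
#'   one applied perturbation), \code{"softmax"} or \code{"multilabel"}.
#' @param verbose print per-epoch progress.
#' @return a trained \linkS4class{CPAModel} with a per-epoch \code{history}
#'   data.frame (reconstruction, adversary losses, penalty, discriminator
#'   accuracies, test reconstruction).
#' @export
trainCpa <- function(ds, cfg = cpaConfig(), advPert = "auto",
                     verbose = FALSE) {
    sp <- splitLabels(ds)
    if (all(is.na(sp)))
        stop("dataset has no split labels; run makeSplit() first")
    trainIdx <- which(sp == "train")
    testIdx <- which(sp == "test")
    if (length(trainIdx) == 0) stop("empty train split")
    X <- cellMatrix(ds)
    D <- doses(ds)
    covDf <- covariateAssignments(ds)
    visited <- c(trainIdx, testIdx)
    if (advPert == "auto")
        advPert <- if (any(rowSums(D[visited, , drop = FALSE] > 0) > 1))
            "multilabel" else "softmax"
    model <- cpaModel(colnames(X), perturbationNames(ds),
                      covariateSchemas(ds), cfg, advPert)
    schemas <- model@covariateSchemas
    params <- model@params
    opt <- .freshOpt(params)
    Xtr <- X[trainIdx, , drop = FALSE]
    Dtr <- D[trainIdx, , drop = FALSE]
    Ctr <- covDf[trainIdx, , drop = FALSE]
    evalIdx <- if (length(testIdx)) testIdx else trainIdx
    Xte <- X[evalIdx, , drop = FALSE]
    Dte <- D[evalIdx, , drop = FALSE]
    Cte <- covDf[evalIdx, , drop = FALSE]
    n <- nrow(Xtr)
    bs <- min(cfg$batchSize, n)
    history <- list()
    best <- list(loss = Inf, params = params)
    tmp <- model
    withSeed(cfg$seed, {
        discPerm <- sample.int(n)
        discPos <- 1L
        nextDiscBatch <- function() {
            if (discPos + bs - 1L > n) {
                discPerm <<- sample.int(n)
                discPos <<- 1L
            }
            idx <- discPerm[discPos:(discPos + bs - 1L)]
            discPos <<- discPos + bs
            idx
        }
        for (epoch in seq_len(cfg$epochs)) {
            opt$decay <- cfg$lrDecayFactor^((epoch - 1) %/% cfg$lrDecayEpochs)
            perm <- sample.int(n)
            nIter <- max(1L, n %/% bs)
            epRecon <- epAdv <- epPen <- 0
            for (it in seq_len(nIter)) {
                for (s in seq_len(cfg$discSteps)) {
                    bi <- nextDiscBatch()
                    r <- .discStepCore(params, opt,
                                       .batchOf(Xtr, Dtr, Ctr, bi),
                                       cfg, advPert, schemas)
                    params <- r$params; opt <- r$opt
                }
                epPen <- epPen + r$record$penalty
                lo <- (it - 1L) * bs + 1L
                hi <- min(it * bs, n)
                bi <- perm[lo:hi]
                if (length(bi) < 2L) next
                batch <- .batchOf(Xtr, Dtr, Ctr, bi)
                oh <- .covOnehots(model, batch$cov)
                r <- .aeStepCore(params, opt, batch, cfg, advPert, schemas, oh)
                params <- r$params; opt <- r$opt
                epRecon <- epRecon + r$record$reconstruction
                epAdv <- epAdv + r$record$adversary
            }
            tmp@params <- params
            fwTe <- .modelForward(tmp, Xte, Dte, Cte)
            teLoss <- reconstructionLoss(fwTe$pred, Xte)
            acc <- .headAccuracies(params, advPert, schemas, fwTe$basal,
                                   Dte, Cte)
            stopifnot(max(abs(scaleDoses(tmp,
                numeric(length(model@perturbations))))) == 0)
            if (teLoss < best$loss) best <- list(loss = teLoss, params = params)
            rec <- c(epoch = epoch, reconstruction = epRecon / nIter,
                     adversary = epAdv / nIter, penalty = epPen / nIter,
                     testReconstruction = teLoss, accPert = acc$pert)
            for (cv in names(acc$cov))
                rec[paste0("accCov_", cv)] <- acc$cov[[cv]]
            history[[epoch]] <- rec
            if (verbose)
                message(sprintf(
                    "epoch %3d  recon %.4f  adv %.4f  test %.4f  accPert %.3f",
                    epoch, epRecon / nIter, epAdv / nIter, teLoss, acc$pert))
        }
    })
    model@params <- best$params
    model@history <- as.data.frame(do.call(rbind, history))
    model@trained <- TRUE
    model
}
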