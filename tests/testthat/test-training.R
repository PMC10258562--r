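test_that("Gaussian NLL matches hand values and its variance trade-off", {
    gp <- function(mu, v) new("GaussianPrediction",
                              mean = matrix(mu, 1), variance = matrix(v, 1))
    x <- c(1, 2, 3)
    expect_equal(reconstructionLoss(gp(x, rep(1, 3)), x), 0)
    # single gene, residual 2, unit variance -> 0.5*log(1) + 4/2 = 2
    expect_equal(reconstructionLoss(gp(4, 1), 2), 2)
    # at fixed residual the loss is minimized at var = residual^2
    vGrid <- seq(0.5, 20, by = 0.01)
    losses <- vapply(vGrid, function(v) reconstructionLoss(gp(4, v), 2),
                     numeric(1))
    expect_equal(vGrid[which.min(losses)], 4, tolerance = 0.02)
    expect_error(reconstructionLoss(gp(1, 1), c(1, 2)), "shape")
})

test_that("adversary cross-entropies reproduce the closed forms", {
    cfg <- cpaConfig(embeddingDim = 4, encoderHidden = 8, encoderLayers = 1,
                     doserHidden = 4, doserLayers = 1, discHidden = 8,
                     discLayers = 1, seed = 5)
    m <- cpaModel(sprintf("g%d", 1:6), c("A", "B"),
                  list(tissue = c("t1", "t2", "t3", "t4")), cfg, "softmax")
    # zero the final discriminator layers -> uniform probabilities
    zeroHead <- function(net) {
        L <- length(net$W)
        net$W[[L]] <- net$W[[L]] * 0
        net$b[[L]] <- net$b[[L]] * 0
        net
    }
    m@params$discPert <- zeroHead(m@params$discPert)
    m@params$discCov[[1]] <- zeroHead(m@params$discCov[[1]])
    basal <- matrix(rnorm(12), 3, 4)
    targets <- list(doses = cbind(A = c(1, 0, 0), B = c(0, 1, 0)),
                    covariates = data.frame(tissue = c("t1", "t3", "t2")))
    al <- adversaryLosses(m, basal, targets)
    expect_equal(unname(al$cov["tissue"]), log(4))  # uniform over 4 levels
    expect_equal(al$pert, log(3))                   # uniform over A, B, ctrl
    expect_equal(al$total, log(3) + log(4))
    # multilabel mode: probs 0.5 on both labels, applied = (1,0) -> log 2
    m2 <- cpaModel(sprintf("g%d", 1:6), c("A", "B"),
                   list(tissue = c("t1", "t2", "t3", "t4")), cfg, "multilabel")
    m2@params$discPert <- zeroHead(m2@params$discPert)
    al2 <- adversaryLosses(m2, basal[1, , drop = FALSE],
                           list(doses = cbind(A = 1, B = 0),
                                covariates = data.frame(tissue = "t1")))
    expect_equal(al2$pert, log(2))
    expect_error(adversaryLosses(m, basal,
        list(doses = targets$doses,
             covariates = data.frame(tissue = c("t1", "bad", "t2")))),
        "vocabulary")
})

test_that("gradient penalty: zero for constant heads, analytic for linear BCE", {
    d <- 3
    basal <- matrix(rnorm(15), 5, d)
    # constant head: all weights zero -> no input gradient
    net0 <- cpae:::nnInit(c(d, 4, 2), c("relu", "linear"))
    net0$W <- lapply(net0$W, function(w) w * 0)
    expect_equal(gradientPenalty(net0, basal, c(1, 2, 1, 2, 1), "softmax",
                                 coef = 3), 0)
    # linear head w.z with BCE: |grad|^2 = (p - y)^2 * |w|^2
    w <- c(0.5, -1, 2)
    netL <- list(W = list(matrix(w, d, 1)), b = list(0.3), act = "linear",
                 bn = FALSE, g = list(numeric(0)), be = list(numeric(0)),
                 rm = list(numeric(0)), rv = list(numeric(0)))
    y <- matrix(c(1, 0, 1, 0, 1), 5, 1)
    logits <- basal %*% matrix(w, d, 1) + 0.3
    p <- 1 / (1 + exp(-logits))
    expected <- 2 * mean((p - y)^2 * sum(w^2))
    expect_equal(gradientPenalty(netL, basal, y, "multilabel", coef = 2),
                 expected)
    # non-negativity on random heads
    for (s in 1:5) {
        net <- withr::with_seed(s, cpae:::nnInit(c(d, 6, 3),
                                                 c("relu", "linear")))
        expect_gte(gradientPenalty(net, basal, c(1, 2, 3, 1, 2), "softmax"),
                   0)
    }
})

test_that("each optimization phase touches exactly its declared parameters", {
    m <- tinyModel()
    sd <- smallDataset()
    batch <- randomBatch(sd$ds, n = 48, seed = 6)
    before <- m@params
    afterD <- discriminatorStep(m, batch)$model@params
    # discriminator phase: AE side bit-identical, discriminators changed
    expect_identical(cpae:::.aeGroup(afterD), cpae:::.aeGroup(before))
    expect_identical(cpae:::.doserGroup(afterD), cpae:::.doserGroup(before))
    expect_false(identical(cpae:::.discGroup(afterD),
                           cpae:::.discGroup(before)))
    afterA <- autoencoderStep(m, batch)$model@params
    # autoencoder phase: discriminators bit-identical, AE side changed
    expect_identical(cpae:::.discGroup(afterA), cpae:::.discGroup(before))
    expect_false(identical(cpae:::.aeGroup(afterA), cpae:::.aeGroup(before)))
    expect_false(identical(cpae:::.doserGroup(afterA),
                           cpae:::.doserGroup(before)))
    # zero-dose constraint survives the update
    M <- length(perturbationNames(m))
    m2 <- m; m2@params <- afterA
    expect_identical(scaleDoses(m2, numeric(M)), numeric(M))
})

test_that("with lambda = 0 the autoencoder step ignores the discriminators", {
    m <- tinyModel()
    sd <- smallDataset()
    batch <- randomBatch(sd$ds, n = 48, seed = 8)
    cfg0 <- m@config; cfg0$lambdaAdv <- 0
    r1 <- autoencoderStep(m, batch, cfg0)
    # mangle the discriminators; at lambda = 0 the update must not change
    m2 <- m
    m2@params$discPert$W <- lapply(m2@params$discPert$W, function(w) w + 1)
    r2 <- autoencoderStep(m2, batch, cfg0)
    expect_identical(cpae:::.aeGroup(r1$model@params),
                     cpae:::.aeGroup(r2$model@params))
    expect_true(is.finite(r1$losses$reconstruction))
})

test_that("training is seed-deterministic and records finite losses", {
    sd <- smallDataset()
    cfg <- cpaConfig(embeddingDim = 6, encoderHidden = 24, encoderLayers = 1,
                     doserHidden = 8, doserLayers = 1, discHidden = 12,
                     discLayers = 1, epochs = 3, batchSize = 64, seed = 202)
    m1 <- trainCpa(sd$ds, cfg)
    m2 <- trainCpa(sd$ds, cfg)
    expect_identical(m1@history$testReconstruction,
                     m2@history$testReconstruction)
    expect_true(all(is.finite(as.matrix(m1@history))))
    expect_identical(nrow(m1@history), 3L)
    # empty train split errors
    dsBad <- sd$ds
    colData(dsBad)$split <- rep("ood", ncol(dsBad))
    expect_error(trainCpa(dsBad, cfg), "train")
})

test_that("a frozen-encoder discriminator learns planted separable basal labels", {
    # planted: two covariate groups with well-separated basal states
    set.seed(77)
    n <- 120
    basal <- rbind(matrix(rnorm(n / 2 * 4, mean = 2), n / 2, 4),
                   matrix(rnorm(n / 2 * 4, mean = -2), n / 2, 4))
    lab <- rep(1:2, each = n / 2)
    net <- cpae:::nnInit(c(4, 16, 2), c("relu", "linear"))
    opt <- cpae:::adamInit(list(W = net$W, b = net$b, g = net$g, be = net$be))
    for (i in 1:150) {
        h <- cpae:::.headForward(net, basal, lab, "softmax")
        bk <- cpae:::nnBackward(net, h$fw, h$dlogits / n)
        upd <- cpae:::adamStep(list(W = net$W, b = net$b, g = net$g,
                                    be = net$be),
                               list(W = bk$W, b = bk$b, g = bk$g, be = bk$be),
                               opt, lr = 1e-2)
        net$W <- upd$params$W; net$b <- upd$params$b
        opt <- upd$opt
    }
    h <- cpae:::.headForward(net, basal, lab, "softmax")
    expect_gt(mean(max.col(h$prob) == lab), 0.99)
})

test_that("trained scalers keep the zero-dose constraint through an epoch", {
    m <- trainedSmall()
    M <- length(perturbationNames(m))
    expect_identical(scaleDoses(m, numeric(M)), numeric(M))
    expect_true(m@trained)
})

test_that("learned dictionary similarity mirrors a planted cluster structure", {
    # linear-decoder truth, no interactions; the true dictionary has two
    # tight clusters of three perturbations. The comparison uses the
    # dose-scaled columns Vhat[, j] * f_j(1): the raw column direction is
    # only identified up to the sign/scale absorbed by the dose scaler.
    truth <- syntheticTruth(nGenes = 100, latentDim = 8,
                            perturbations = LETTERS[1:6],
                            covariateSchemas = list(line = "l1"),
                            decoderKind = "linear", seed = 71)
    set.seed(72)
    mkCluster <- function(k) {
        base <- rnorm(8); base <- base / sqrt(sum(base^2))
        sapply(seq_len(k), function(i) {
            v <- sqrt(0.95) * base + sqrt(0.05) * rnorm(8)
            v / sqrt(sum(v^2)) * 3
        })
    }
    Vt <- cbind(mkCluster(3), mkCluster(3))
    colnames(Vt) <- LETTERS[1:6]
    truth@Vpert <- Vt
    design <- basicDesign(truth, nPerCondition = 200)
    gen <- generateDataset(truth, design, seed = 73)
    ds <- makeSplit(gen$dataset, SplitPlan(testFraction = 0.15, seed = 74))
    cfg <- cpaConfig(embeddingDim = 12, encoderHidden = 96,
                     encoderLayers = 2, doserHidden = 16, doserLayers = 2,
                     discHidden = 64, discLayers = 2, epochs = 80,
                     batchSize = 96, seed = 75, discSteps = 5,
                     lambdaAdv = 5, lrAE = 1e-3, lrDisc = 1e-3)
    m <- trainCpa(ds, cfg)
    cosSim <- function(V) {
        nrm <- sqrt(colSums(V^2))
        S <- crossprod(V) / outer(nrm, nrm)
        S[upper.tri(S)]
    }
    eff <- sweep(m@params$Vpert, 2,
                 scaleDoses(m, setNames(rep(1, 6), LETTERS[1:6])), `*`)
    expect_gte(cor(cosSim(truth@Vpert), cosSim(eff)), 0.7)
})
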