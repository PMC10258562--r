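test_that("pair regression solves the normal equations and the collinear case", {
    d <- list(deltaA = c(1, 0), deltaB = c(0, 1), deltaAB = c(2, 3))
    fit <- fitPairRegression(d)
    expect_equal(fit$c1, 2)
    expect_equal(fit$c2, 3)
    # collinear singles: minimal-norm pseudoinverse solution
    d2 <- list(deltaA = c(1, 1), deltaB = c(1, 1), deltaAB = c(2, 2))
    fit2 <- fitPairRegression(d2)
    expect_equal(fit2$c1, 1)
    expect_equal(fit2$c2, 1)
    # orthogonal projection: deltaAB = deltaA
    d3 <- list(deltaA = c(1, 0, 2), deltaB = c(0, 3, 0), deltaAB = c(1, 0, 2))
    expect_equal(fitPairRegression(d3)$c1, 1)
    expect_equal(fitPairRegression(d3)$c2, 0)
    expect_error(fitPairRegression(list(deltaA = c(0, 0), deltaB = c(0, 0),
                                        deltaAB = c(1, 1))), "zero")
})

test_that("noise-free coefficients are recovered to 6 decimals and match a grid oracle", {
    set.seed(12)
    dA <- rnorm(50); dB <- rnorm(50)
    truth <- c(0.7, -1.3)
    d <- list(deltaA = dA, deltaB = dB,
              deltaAB = truth[1] * dA + truth[2] * dB)
    fit <- fitPairRegression(d)
    expect_equal(fit$c1, truth[1], tolerance = 1e-7)
    expect_equal(fit$c2, truth[2], tolerance = 1e-7)
    # independent oracle: 2-parameter grid search with iterative refinement
    sse <- function(c1, c2) sum((d$deltaAB - c1 * dA - c2 * dB)^2)
    ctr <- c(0, 0); width <- 4
    for (it in 1:40) {
        g1 <- seq(ctr[1] - width, ctr[1] + width, length.out = 11)
        g2 <- seq(ctr[2] - width, ctr[2] + width, length.out = 11)
        grid <- expand.grid(g1, g2)
        best <- grid[which.min(mapply(sse, grid[, 1], grid[, 2])), ]
        ctr <- as.numeric(best); width <- width / 2.5
    }
    expect_equal(fit$c1, ctr[1], tolerance = 1e-6)
    expect_equal(fit$c2, ctr[2], tolerance = 1e-6)
})

test_that("distance correlation has its fixed points and independence limit", {
    set.seed(5)
    x <- rnorm(100)
    expect_equal(distanceCorrelation(x, x), 1)
    expect_equal(distanceCorrelation(x, 2 - 3 * x), 1)  # affine, reflected
    expect_equal(distanceCorrelation(x, rep(1, 100)), 0) # constant -> 0
    y <- withr::with_seed(6, rnorm(2000))
    z <- withr::with_seed(7, rnorm(2000))
    expect_lt(distanceCorrelation(y, z), 0.1)
    # two-column input: perfectly explained double
    A <- matrix(rnorm(60), 30, 2)
    expect_gt(distanceCorrelation(A, A[, 1] + A[, 2]), 0.85)
    expect_error(distanceCorrelation(x, rnorm(5)), "unequal")
})

test_that("the metric panel matches hand arithmetic", {
    d <- list(deltaA = c(1, 0), deltaB = c(0, 1), deltaAB = c(2, 3))
    m <- interactionMetrics(d, pair = c("A", "B"))
    expect_equal(m@magnitude, sqrt(13))
    expect_equal(m@magnitude, sqrt(m@c1^2 + m@c2^2))
    expect_equal(m@dominance, log10(2 / 3))
    expect_true(m@fitDcor >= 0 && m@fitDcor <= 1)
    expect_true(m@equalContrib >= 0 && m@equalContrib <= 1)
    # c1 = c2 -> dominance 0; equal symmetric construction -> equalContrib 1
    d2 <- list(deltaA = c(1, 0, 0.5), deltaB = c(0, 1, -0.5),
               deltaAB = c(1, 1, 0))
    m2 <- interactionMetrics(d2)
    expect_equal(m2@dominance, 0)
    expect_equal(m2@c1, m2@c2)
    # zero coefficient clips dominance at +/- 6
    d3 <- list(deltaA = c(1, 0, 2), deltaB = c(0, 3, 0), deltaAB = c(1, 0, 2))
    expect_equal(interactionMetrics(d3)@dominance, 6)
})

test_that("mode rules fire as printed and multi-matches stay unassigned", {
    mk <- function(c1, c2, dAB, dJD)
        new("InteractionMetrics", pair = c("a", "b"), c1 = c1, c2 = c2,
            fitDcor = 0.9, magnitude = sqrt(c1^2 + c2^2),
            dominance = log10(abs(c1) / abs(c2)),
            dcorSingles = dAB, dcorJointDouble = dJD, equalContrib = 0.8)
    # unique epistatic: dominant coefficient, magnitude away from 1, dcors mid
    r <- classifyMode(mk(0.7, 0.25, 0.6, 0.6))
    expect_identical(r$mode, "epistatic")
    # epistatic rule fires whenever min > 0.2 with a 2x dominance
    r2 <- classifyMode(mk(1, 0.3, 0.95, 0.95))
    expect_true("epistatic" %in% r2$matchedRules)
    # additive and redundant both fire -> unassigned
    c1 <- 1 / sqrt(2)
    r3 <- classifyMode(mk(c1, c1, 0.99, 0.99))
    expect_identical(r3$mode, "unassigned")
    expect_setequal(r3$matchedRules, c("additive", "redundant"))
    # magnitude just below 1, no other rule satisfied -> additive
    r4 <- classifyMode(mk(0.8, 0.55, 0.7, 0.7))
    expect_identical(r4$mode, "additive")
    # magnitude > 1 with dissimilar singles -> potentiation (+ synergy overlap)
    r5 <- classifyMode(mk(1.2, 1.1, 0.3, 0.3))
    expect_true(all(c("potentiation", "strong_synergy_similar",
                      "strong_synergy_different") %in% r5$matchedRules))
    expect_identical(r5$mode, "unassigned")
    # nothing fires -> unassigned with empty rule list
    r6 <- classifyMode(mk(0.15, 0.1, 0.5, 0.5))
    expect_identical(r6$mode, "unassigned")
    expect_true(!"epistatic" %in% r6$matchedRules)
})

test_that("missing-pair counting matches brute-force enumeration", {
    got <- countMissingPairs(105, 131)
    expect_identical(got$missing, 5329L)
    expect_identical(got$percentMissing, 97.6)
    expect_identical(countMissingPairs(3, 0),
                     list(missing = 3L, percentMissing = 100))
    expect_identical(countMissingPairs(105, choose(105, 2))$missing, 0L)
    for (n in c(4, 11, 23, 50)) {
        total <- nrow(t(utils::combn(n, 2)))     # brute-force enumeration
        k <- sample(0:total, 1)
        expect_identical(countMissingPairs(n, k)$missing,
                         as.integer(total - k))
    }
    expect_error(countMissingPairs(4, 10), "more measured")
})

test_that("deltas subtract the shared control and respect invariants", {
    sd <- smallDataset()
    ds <- sd$ds
    conds <- unique(conditionIds(ds))
    a <- grep("^A@1\\|lineA", conds, value = TRUE)
    b <- grep("^B@1\\|lineA", conds, value = TRUE)
    ctrl <- grep("^ctrl\\|lineA", conds, value = TRUE)
    d <- computeDeltas(ds, a, b, b, ctrl)   # reuse b as the "double"
    X <- cellMatrix(ds); cond <- conditionIds(ds)
    expect_equal(d$deltaA,
                 colMeans(X[cond == a, ]) - colMeans(X[cond == ctrl, ]))
    # identical condition minus itself -> zero vector
    d0 <- computeDeltas(ds, ctrl, ctrl, ctrl, ctrl)
    expect_equal(max(abs(d0$deltaA)), 0)
    # constant shifts cancel: profile-matrix interface
    prof <- rbind(a = colMeans(X[cond == a, ]),
                  b = colMeans(X[cond == b, ]),
                  ab = colMeans(X[cond == b, ]),
                  ctrl = colMeans(X[cond == ctrl, ]))
    d1 <- computeDeltas(prof, "a", "b", "ab", "ctrl")
    d2 <- computeDeltas(prof + 7, "a", "b", "ab", "ctrl")
    expect_equal(d1$deltaA, d2$deltaA)
    expect_error(computeDeltas(ds, a, b, "missing@1|x", ctrl), "missing")
})

test_that("imputation covers exactly the unmeasured pairs with positive uncertainty", {
    truth <- syntheticTruth(nGenes = 30, perturbations = LETTERS[1:6],
                            latentDim = 4,
                            covariateSchemas = list(line = "l1"), seed = 61)
    design <- basicDesign(truth, nPerCondition = 8,
                          pairs = list(c("A", "B"), c("C", "D"), c("E", "F")))
    gen <- generateDataset(truth, design, seed = 62)
    ds <- makeSplit(gen$dataset, SplitPlan(testFraction = 0.2, seed = 63))
    cfg <- cpaConfig(embeddingDim = 6, encoderHidden = 16, encoderLayers = 1,
                     doserHidden = 4, doserLayers = 1, discHidden = 8,
                     discLayers = 1, epochs = 2, batchSize = 32, seed = 64)
    m <- trainCpa(ds, cfg)
    imp <- imputeAllPairs(m, ds, nCellsPerPair = 5)
    expect_equal(nrow(imp), choose(6, 2) - 3)        # 12 imputed rows
    expect_false(any(c("A+B", "C+D", "E+F") %in% imp$pair))
    expect_true(all(imp$uEuclidean > 0))
    expect_identical(ncol(imp$mean), 30L)
})
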