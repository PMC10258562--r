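test_that("r2Score matches its definition and hand example", {
    y <- c(1, 2, 3)
    expect_equal(r2Score(y, y), 1)
    expect_equal(r2Score(y, rep(mean(y), 3)), 0)
    expect_equal(r2Score(y, c(1, 2, 2)), 0.5)
    expect_error(r2Score(c(1, 1, 1), y), "constant")
    expect_error(r2Score(y, c(1, 2)), "mismatch")
})

test_that("DEG selection finds planted shifts, is nested and tie-stable", {
    set.seed(31)
    n <- 300; G <- 40
    X <- matrix(rnorm(2 * n * G), 2 * n, G)
    X[1:n, 1:10] <- X[1:n, 1:10] + 1.5          # planted shift, genes 1-10
    D <- matrix(c(rep(1, n), rep(0, n)), ncol = 1,
                dimnames = list(NULL, "P"))
    ds <- PerturbationExperiment(X, D, data.frame(line = rep("l", 2 * n)))
    degs <- selectTopDegs(ds, "P@1|l", "ctrl|l", 10)
    expect_setequal(degs, 1:10)
    # nesting: growing n never drops earlier selections
    expect_identical(selectTopDegs(ds, "P@1|l", "ctrl|l", 5),
                     selectTopDegs(ds, "P@1|l", "ctrl|l", 10)[1:5])
    # identical condition vs itself: pure index tie-break
    expect_identical(selectTopDegs(ds, "P@1|l", "P@1|l", 4), 1:4)
    expect_error(selectTopDegs(ds, "P@1|l", "ctrl|l", G + 1), "exceeds")
})

test_that("random baseline is seeded and degenerate-stable", {
    sd <- smallDataset()
    ds <- sd$ds
    target <- conditionIds(ds)[1]
    b1 <- randomBaseline(ds, target, seed = 3)
    b2 <- randomBaseline(ds, target, seed = 3)
    expect_identical(b1$cells, b2$cells)
    expect_identical(b1$mean, b2$mean)
    expect_false(identical(b1$cells, randomBaseline(ds, target, seed = 4)$cells))
    # identical training cells: baseline mean equals that cell
    X <- matrix(rep(c(1, 2, 3), each = 8), 8, 3)
    D <- matrix(c(rep(0, 4), rep(1, 4)), ncol = 1,
                dimnames = list(NULL, "P"))
    ds2 <- PerturbationExperiment(X, D, data.frame(line = rep("l", 8)))
    splitLabels(ds2) <- rep("train", 8)
    expect_equal(randomBaseline(ds2, "P@1|l", seed = 1)$mean, c(1, 2, 3),
                 ignore_attr = TRUE)
})

test_that("linear baseline is the symmetric pseudobulk average", {
    expect_equal(linearBaseline(c(0, 2), c(2, 0)), c(1, 1))
    a <- rnorm(10); b <- rnorm(10)
    expect_equal(linearBaseline(a, b), linearBaseline(b, a))
    expect_equal(linearBaseline(a, a), a)
    expect_error(linearBaseline(a, b[1:5]), "mismatch")
})

test_that("gene-wise Wasserstein has its closed-form and translation behavior", {
    x <- matrix(c(0, 0, 0), 3, 1)
    y <- matrix(c(1, 1, 1), 3, 1)
    expect_equal(geneWiseWasserstein(x, y), 1)   # point masses at 0 and 1
    expect_equal(geneWiseWasserstein(x, x), 0)
    set.seed(4)
    A <- matrix(rnorm(200), 50, 4)
    expect_equal(geneWiseWasserstein(A, A + 3), 3)  # disjoint translates
    expect_equal(geneWiseWasserstein(A, A + 3), geneWiseWasserstein(A + 3, A))
    # unequal sample sizes agree with the cdf-integral definition
    expect_equal(geneWiseWasserstein(matrix(c(0, 1), 2, 1),
                                     matrix(c(0, 0.5, 1), 3, 1)),
                 cpae:::.w1(c(0, 1), c(0, 0.5, 1)))
})

test_that("clustering agreement is perfect on separated blobs and low on noise", {
    set.seed(9)
    emb <- rbind(matrix(rnorm(60, mean = 0, sd = 0.1), 15, 4),
                 matrix(rnorm(60, mean = 4, sd = 0.1), 15, 4),
                 matrix(rnorm(60, mean = -4, sd = 0.1), 15, 4))
    lab <- rep(1:3, each = 15)
    ca <- clusteringAgreement(emb, lab)
    expect_equal(ca$homogeneity, 1)
    expect_equal(ca$nmi, 1, tolerance = 1e-6)
    # random labels on unstructured embeddings: NMI near zero at the optimum
    emb2 <- matrix(rnorm(70 * 4), 70, 4)
    lab2 <- sample(1:3, 70, replace = TRUE)
    ca2 <- clusteringAgreement(emb2, lab2)
    expect_lt(ca2$nmi, 0.35)
    # degenerate grid equals the single clustering it contains
    ca3 <- clusteringAgreement(emb, lab, kGrid = 5, resolutionGrid = 0.8)
    expect_identical(ca3$k, 5)
    expect_identical(ca3$resolution, 0.8)
    expect_error(clusteringAgreement(emb[1:3, ], c(1, 2, 1)), "smallest k")
    expect_error(clusteringAgreement(emb, rep(1, 45)), "distinct")
})

test_that("scoreCondition produces the per-condition metric panel", {
    m <- trainedSmall()
    sd <- smallDataset()
    conds <- unique(conditionIds(sd$ds))
    target <- grep("^A@", conds, value = TRUE)[1]
    ctrl <- grep("^ctrl\\|lineA", conds, value = TRUE)[1]
    sc <- scoreCondition(sd$ds, m, target, ctrl, nDegs = 10)
    expect_identical(nrow(sc), 1L)
    expect_true(all(c("r2MeanAll", "r2VarAll", "r2MeanDegs", "r2VarDegs",
                      "nCellsReal", "wassersteinMean") %in% colnames(sc)))
    expect_lte(sc$r2MeanAll, 1)
    expect_gte(sc$wassersteinMean, 0)
    expect_identical(sc$nCellsReal, 40L)
})
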