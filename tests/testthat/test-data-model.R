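test_that("condition ids canonicalize combinations and round-trip", {
    perts <- c("A", "B", "C")
    cov <- list(cell_line = "lineX")
    idAB <- conditionId(c(A = 1, B = 1, C = 0), cov, perts)
    idBA <- conditionId(c(A = 1, B = 1, C = 0)[c(2, 1, 3)], cov,
                        perts[c(2, 1, 3)])
    expect_identical(idAB, "A+B@1+1|lineX")
    expect_identical(idAB, idBA)
    expect_identical(conditionId(c(0, 0, 0), cov, perts), "ctrl|lineX")

    pc <- parseConditionId("A+C@0.5+2|lineX", perts, "cell_line")
    expect_equal(pc$dose, c(A = 0.5, B = 0, C = 2))
    expect_identical(unname(pc$covariates), "lineX")

    # round trip through arbitrary dose/covariate rows
    for (i in 1:20) {
        d <- withr::with_seed(i, round(runif(3) * (runif(3) > 0.4), 3))
        id <- conditionId(d, cov, perts)
        back <- parseConditionId(id, perts, "cell_line")
        expect_equal(unname(back$dose), unname(d))
    }
    expect_error(conditionId(c(-1, 0, 0), cov, perts), ">= 0")
    expect_error(parseConditionId("Z@1|lineX", perts, "cell_line"), "unknown")
})

test_that("normalize-then-log1p matches the hand computation and keeps zeros", {
    counts <- rbind(c(2, 0, 2), c(1, 2, 1), c(0, 1, 3))
    out <- preprocessExpression(counts, nHvg = 3)
    # all cell totals are 4 = median, so normalization is the identity
    expect_equal(unname(out[1, ]), c(log(3), 0, log(3)))
    expect_identical(out == 0, counts == 0)

    # duplicated cells stay identical
    dup <- counts[c(1, 1, 2, 3), ]
    out2 <- preprocessExpression(dup, nHvg = 3)
    expect_identical(out2[1, ], out2[2, ])
})

test_that("HVG selection is a dispersion-ranked top-n with errors on bad input", {
    set.seed(42)
    n <- 60
    X <- matrix(rpois(n * 6, lambda = 5), n, 6)
    X[, 3] <- rpois(n, lambda = 5) * rbinom(n, 1, 0.5) * 4  # overdispersed
    full <- preprocessExpression(X, nHvg = 6)
    expect_identical(attr(full, "hvg"), 1:6)        # nHvg = G keeps all genes
    top2 <- preprocessExpression(X, nHvg = 2)
    expect_length(attr(top2, "hvg"), 2)
    expect_true(3 %in% attr(top2, "hvg"))
    expect_error(preprocessExpression(X, nHvg = 7), "exceeds")
    X0 <- X; X0[4, ] <- 0
    expect_error(preprocessExpression(X0, nHvg = 2), "index: 4")
    expect_error(preprocessExpression(-X, nHvg = 2), ">= 0")
})

test_that("dataset writer/reader round-trips matrix and annotations", {
    sd <- smallDataset()
    dir <- withr::local_tempdir()
    writePerturbDataset(sd$ds, dir)
    back <- readPerturbDataset(dir)
    expect_lt(max(abs(cellMatrix(back) - cellMatrix(sd$ds))), 1e-6)
    expect_identical(conditionIds(back), conditionIds(sd$ds))
    expect_identical(splitLabels(back), splitLabels(sd$ds))
    expect_equal(doses(back), doses(sd$ds), ignore_attr = TRUE)
    expect_identical(perturbationNames(back), perturbationNames(sd$ds))
    expect_identical(covariateSchemas(back), covariateSchemas(sd$ds))
})

test_that("reader rejects malformed annotation tables", {
    sd <- smallDataset()
    dir <- withr::local_tempdir()
    writePerturbDataset(sd$ds, dir)
    obs <- read.table(file.path(dir, "obs.tsv"), sep = "\t", header = TRUE,
                      colClasses = "character")
    # negative dose
    bad <- obs
    bad$dose[which(bad$perturbation != "ctrl")[1]] <- "-1"
    write.table(bad, file.path(dir, "obs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    expect_error(readPerturbDataset(dir), ">= 0")
    # missing annotation column
    write.table(obs[, setdiff(colnames(obs), "dose")],
                file.path(dir, "obs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    expect_error(readPerturbDataset(dir), "missing column")
})

test_that("h5 dialect round-trips when rhdf5 is available", {
    skip_if_not_installed("rhdf5")
    sd <- smallDataset()
    path <- file.path(withr::local_tempdir(), "ds.h5")
    writePerturbDataset(sd$ds, path, dialect = "h5-annotated")
    back <- readPerturbDataset(path)
    expect_lt(max(abs(cellMatrix(back) - cellMatrix(sd$ds))), 1e-6)
    expect_identical(conditionIds(back), conditionIds(sd$ds))
})

test_that("makeSplit holds out ood conditions and is seed-deterministic", {
    sd <- smallDataset()
    ds <- sd$ds
    oodId <- conditionIds(ds)[1]
    plan <- SplitPlan(oodConditions = oodId, testFraction = 0.25, seed = 9)
    s1 <- makeSplit(ds, plan)
    s2 <- makeSplit(ds, plan)
    expect_identical(splitLabels(s1), splitLabels(s2))
    expect_true(all(splitLabels(s1)[conditionIds(ds) == oodId] == "ood"))
    expect_true(all(splitLabels(s1)[conditionIds(ds) != oodId] != "ood"))
    # per-condition test fraction
    tab <- table(splitLabels(s1), conditionIds(s1))
    other <- setdiff(colnames(tab), oodId)
    expect_true(all(tab["test", other] == round(40 * 0.25)))
    # empty ood set: only train/test
    s3 <- makeSplit(ds, SplitPlan(testFraction = 0.2, seed = 1))
    expect_setequal(unique(splitLabels(s3)), c("train", "test"))
    expect_error(makeSplit(ds, SplitPlan(oodConditions = "nope@1|x",
                                         testFraction = 0.2, seed = 1)),
                 "nope")
})
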