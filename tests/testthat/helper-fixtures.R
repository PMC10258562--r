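# Shared fixtures, built once per test run and memoised in this
# environment. Everything is generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

memoFixture <- function(name, builder) {
    if (is.null(.fixtures[[name]]))
        .fixtures[[name]] <- builder()
    .fixtures[[name]]
}

# Small single-perturbation dataset (3 perturbations, 2 cell lines).
smallDataset <- function() memoFixture("smallDataset", function() {
    truth <- syntheticTruth(nGenes = 60, perturbations = c("A", "B", "C"),
                            latentDim = 6, seed = 101)
    design <- basicDesign(truth, nPerCondition = 40)
    gen <- generateDataset(truth, design, seed = 102)
    ds <- makeSplit(gen$dataset, SplitPlan(testFraction = 0.2, seed = 103))
    list(ds = ds, truth = truth)
})

# Tiny untrained model matched to smallDataset (cheap, deterministic).
tinyModel <- function() memoFixture("tinyModel", function() {
    sd <- smallDataset()
    cfg <- cpaConfig(embeddingDim = 8, encoderHidden = 32, encoderLayers = 2,
                     doserHidden = 8, doserLayers = 1, discHidden = 16,
                     discLayers = 2, epochs = 2, batchSize = 64, seed = 104)
    cpaModel(colnames(cellMatrix(sd$ds)), perturbationNames(sd$ds),
             covariateSchemas(sd$ds), cfg, "softmax")
})

# A model with identity-like dictionaries for hand-computable embeddings:
# latentDim 2, two perturbations, linear dose scalers f_j(d) = d, Vpert = I,
# no covariates.
handModel <- function() memoFixture("handModel", function() {
    cfg <- cpaConfig(embeddingDim = 2, encoderHidden = 8, encoderLayers = 1,
                     doserHidden = 4, doserLayers = 0, discHidden = 8,
                     discLayers = 1, seed = 7)
    m <- cpaModel(sprintf("g%d", 1:5), c("A", "B"), list(), cfg, "softmax")
    m@params$Vpert <- diag(2)
    colnames(m@params$Vpert) <- c("A", "B")
    for (j in 1:2) {                      # g_j(d) = d  =>  f_j(d) = d
        m@params$dosers[[j]]$W[[1]] <- matrix(1, 1, 1)
        m@params$dosers[[j]]$b[[1]] <- 0
    }
    m
})

# Short real training run on the small dataset, reused by several suites.
trainedSmall <- function() memoFixture("trainedSmall", function() {
    sd <- smallDataset()
    cfg <- cpaConfig(embeddingDim = 8, encoderHidden = 32, encoderLayers = 2,
                     doserHidden = 8, doserLayers = 1, discHidden = 16,
                     discLayers = 2, epochs = 5, batchSize = 64, seed = 105)
    trainCpa(sd$ds, cfg)
})

randomBatch <- function(ds, n = 32, seed = 1) {
    idx <- withr::with_seed(seed, sample(ncol(ds), n))
    list(X = cellMatrix(ds)[idx, , drop = FALSE],
         doses = doses(ds)[idx, , drop = FALSE],
         covariates = covariateAssignments(ds)[idx, , drop = FALSE])
}

# Checksum over every numeric leaf of a nested parameter list.
paramChecksum <- function(x) {
    tot <- 0
    walk <- function(p) {
        if (is.list(p)) lapply(p, walk)
        else if (is.numeric(p) && length(p)) tot <<- tot + sum(abs(p))
        invisible(NULL)
    }
    walk(x)
    tot
}
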