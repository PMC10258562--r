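#' Create the hidden truth of a synthetic perturbation experiment
#'
#' Draws the fixed parameters of a generative process with exactly the
#' structure the model assumes: latent basal states from a small Gaussian
#' mixture (components independent of perturbation and covariate), additive
#' latent perturbation effects scaled by saturating Hill dose-response
#' curves, additive covariate embeddings, a fixed nonlinear (2-hidden-layer
#' tanh) or linear decoder map to gene space, and Gaussian observation
#' noise on the log-expression scale. Optional pairwise latent offsets
#' plant non-additive interactions that an additive latent model cannot
#' represent.
#'
#' @param latentDim latent dimension of the truth (default 8).
#' @param nGenes number of genes G (default 200).
#' @param perturbations perturbation names (default \code{LETTERS[1:4]}).
#' @param covariateSchemas named list of covariate levels (default one
#'   covariate \code{cell_line} with two levels).
#' @param decoderKind \code{"tanh"} (2 hidden layers, 64 units) or
#'   \code{"linear"}.
#' @param noiseSd observation noise sd (default 0.2).
#' @param effectSize norm of each true perturbation embedding column
#'   (default 3).
#' @param covEffectSize norm of each covariate embedding column (default 1.5).
#' @param hillK,hillN Hill half-max and exponent, recycled over
#'   perturbations (defaults 0.5 and 2: dose 1 yields ~0.89 of saturation).
#' @param pertCorrelation in [0, 1): fraction of each perturbation
#'   embedding's squared norm contributed by a shared latent program
#'   direction. 0 (default) gives independent random directions; values
#'   near 1 emulate perturbations driving a common transcriptional program,
#'   as is typical of real response deltas.
#' @param basalComponents number of basal mixture components (default 2).
#' @param basalSd within-component sd (default 0.5).
#' @param interactionPairs list of character pairs, e.g.
#'   \code{list(c("A","B"))}, that receive a planted latent interaction
#'   offset when applied jointly.
#' @param interactionStrength norm of each planted offset (default 2).
#' @param seed seed fixing all hidden parameters.
#' @return a \linkS4class{SyntheticTruth}.
#' @export
syntheticTruth <- function(latentDim = 8L, nGenes = 200L,
                           perturbations = LETTERS[1:4],
                           covariateSchemas = list(cell_line = c("lineA", "lineB")),
                           decoderKind = c("tanh", "linear"),
                           noiseSd = 0.2, effectSize = 3, covEffectSize = 1.5,
                           hillK = 0.5, hillN = 2, pertCorrelation = 0,
                           basalComponents = 2L, basalSd = 0.5,
                           interactionPairs = list(),
                           interactionStrength = 2, seed = 1L) {
    decoderKind <- match.arg(decoderKind)
    M <- length(perturbations)
    d <- as.integer(latentDim)
    G <- as.integer(nGenes)
    withSeed(seed, {
        unitCols <- function(n, k, scale) {
            m <- matrix(rnorm(n * k), n, k)
            sweep(m, 2, sqrt(colSums(m^2)) / scale, `/`)
        }
        Vpert <- unitCols(d, M, effectSize)
        if (pertCorrelation > 0) {
            shared <- unitCols(d, 1, effectSize)
            Vpert <- sqrt(pertCorrelation) * shared[, rep(1, M)] +
                sqrt(1 - pertCorrelation) * Vpert
        }
        colnames(Vpert) <- perturbations
        Vcov <- lapply(covariateSchemas, function(lv) {
            m <- unitCols(d, length(lv), covEffectSize)
            colnames(m) <- lv
            m
        })
        decoder <- if (decoderKind == "linear") {
            list(W = matrix(rnorm(d * G, sd = 1 / sqrt(d)), d, G),
                 b = rnorm(G, mean = 2, sd = 1))
        } else {
            h <- 64L
            list(W1 = matrix(rnorm(d * h, sd = 1.2 / sqrt(d)), d, h),
                 b1 = rnorm(h, sd = 0.3),
                 W2 = matrix(rnorm(h * h, sd = 1.2 / sqrt(h)), h, h),
                 b2 = rnorm(h, sd = 0.3),
                 W3 = matrix(rnorm(h * G, sd = 2 / sqrt(h)), h, G),
                 b3 = rnorm(G, mean = 2, sd = 1))
        }
        basalMeans <- lapply(seq_len(basalComponents), function(i)
            rnorm(d, sd = 1))
        interactions <- list()
        for (pr in interactionPairs) {
            stopifnot(all(pr %in% perturbations), length(pr) == 2)
            key <- paste(sort(pr), collapse = "+")
            w <- rnorm(d)
            interactions[[key]] <- w / sqrt(sum(w^2)) * interactionStrength
        }
        new("SyntheticTruth", latentDim = d, perturbations = perturbations,
            covariateSchemas = covariateSchemas, Vpert = Vpert, Vcov = Vcov,
            hillK = rep_len(hillK, M), hillN = rep_len(hillN, M),
            decoder = decoder, decoderKind = decoderKind, noiseSd = noiseSd,
            basalMeans = basalMeans, basalSd = basalSd,
            interactions = interactions, nGenes = G, seed = as.integer(seed))
    })
}

#' True Hill dose-response of the generator
#'
#' \code{h_j(x) = x^n_j / (k_j^n_j + x^n_j)}: zero at zero dose, strictly
#' increasing, saturating at 1.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param D dose vector of length M or an n x M matrix.
#' @return the scaled doses, same shape.
#' @export
hillResponse <- function(truth, D) {
    vec <- !is.matrix(D)
    D <- .asMatrixRow(D, length(truth@perturbations))
    out <- D * 0
    for (j in seq_len(ncol(D))) {
        n <- truth@hillN[j]; k <- truth@hillK[j]
        out[, j] <- D[, j]^n / (k^n + D[, j]^n)
    }
    out[D == 0] <- 0
    if (vec) drop(out) else out
}

#' Decode latent states through the generator's fixed map
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param Z latent vector or n x latentDim matrix.
#' @return noiseless expression (n x G matrix).
#' @export
decodeLatent <- function(truth, Z) {
    Z <- .asMatrixRow(Z, truth@latentDim)
    dec <- truth@decoder
    if (truth@decoderKind == "linear")
        return(sweep(Z %*% dec$W, 2, dec$b, `+`))
    H1 <- tanh(sweep(Z %*% dec$W1, 2, dec$b1, `+`))
    H2 <- tanh(sweep(H1 %*% dec$W2, 2, dec$b2, `+`))
    sweep(H2 %*% dec$W3, 2, dec$b3, `+`)
}

# Internal: latent offset for the applied-perturbation set, if planted.
.interactionOffset <- function(truth, doseRow) {
    applied <- truth@perturbations[doseRow > 0]
    if (length(applied) != 2) return(numeric(truth@latentDim))
    key <- paste(sort(applied), collapse = "+")
    off <- truth@interactions[[key]]
    if (is.null(off)) numeric(truth@latentDim) else off
}

#' Compose true latent states for a block of identical conditions
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param doseRow length-M dose vector of the condition.
#' @param covRow named character vector of covariate levels.
#' @param n number of cells.
#' @return n x latentDim matrix of perturbed latent states (basal mixture
#'   draw plus deterministic condition shift); uses the current RNG stream.
#' @keywords internal
.composeTrueLatent <- function(truth, doseRow, covRow, n) {
    d <- truth@latentDim
    comp <- sample.int(length(truth@basalMeans), n, replace = TRUE)
    basal <- do.call(rbind, lapply(comp, function(k) truth@basalMeans[[k]])) +
        matrix(rnorm(n * d, sd = truth@basalSd), n, d)
    shift <- drop(truth@Vpert %*% hillResponse(truth, doseRow))
    for (cv in names(truth@covariateSchemas))
        shift <- shift + truth@Vcov[[cv]][, covRow[[cv]]]
    shift <- shift + .interactionOffset(truth, doseRow)
    sweep(basal, 2, shift, `+`)
}

#' Generate a synthetic dataset from a truth and a design
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param design data.frame with columns \code{perturbation} (\code{"ctrl"}
#'   or delimited names like \code{"A+B"}), \code{dose} (delimited values
#'   like \code{"1+1"}), one column per covariate, and \code{n} (cells per
#'   row, > 0). See \code{\link{basicDesign}}.
#' @param seed seed for the cell-level draws; two runs with the same seed
#'   produce identical datasets.
#' @return list with \code{dataset} (a \linkS4class{PerturbationExperiment}
#'   carrying log-scale expression) and \code{truth}.
#' @export
generateDataset <- function(truth, design, seed = 1L) {
    perts <- truth@perturbations
    covNames <- names(truth@covariateSchemas)
    need <- c("perturbation", "dose", covNames, "n")
    miss <- setdiff(need, colnames(design))
    if (length(miss))
        stop(sprintf("design is missing column(s): %s",
                     paste(miss, collapse = ", ")))
    if (any(design$n <= 0)) stop("design cell counts must be > 0")
    withSeed(seed, {
        rows <- list()
        for (r in seq_len(nrow(design))) {
            pstr <- design$perturbation[r]
            doseRow <- setNames(numeric(length(perts)), perts)
            if (pstr != "ctrl") {
                ps <- strsplit(pstr, "+", fixed = TRUE)[[1]]
                dv <- as.numeric(strsplit(as.character(design$dose[r]), "+",
                                          fixed = TRUE)[[1]])
                unknown <- setdiff(ps, perts)
                if (length(unknown))
                    stop(sprintf("design row %d: unknown perturbation(s): %s",
                                 r, paste(unknown, collapse = ", ")))
                doseRow[ps] <- dv
            }
            covRow <- vapply(covNames, function(cv)
                as.character(design[[cv]][r]), character(1))
            n <- design$n[r]
            Z <- .composeTrueLatent(truth, doseRow, covRow, n)
            X <- decodeLatent(truth, Z) +
                matrix(rnorm(n * truth@nGenes, sd = truth@noiseSd), n,
                       truth@nGenes)
            rows[[r]] <- list(X = X,
                              dose = matrix(doseRow, n, length(perts),
                                            byrow = TRUE),
                              cov = as.data.frame(as.list(covRow),
                                                  stringsAsFactors = FALSE)[
                                  rep(1, n), , drop = FALSE])
        }
        X <- do.call(rbind, lapply(rows, `[[`, "X"))
        D <- do.call(rbind, lapply(rows, `[[`, "dose"))
        covs <- do.call(rbind, lapply(rows, `[[`, "cov"))
        colnames(D) <- perts
        rownames(X) <- sprintf("cell%d", seq_len(nrow(X)))
        colnames(X) <- sprintf("gene%d", seq_len(ncol(X)))
        ds <- PerturbationExperiment(X, D, covs, perturbations = perts,
                                     covariateSchemas = truth@covariateSchemas)
        list(dataset = ds, truth = truth)
    })
}

#' Standard condition design: control, singles, and selected pairs
#'
#' Crosses the requested conditions with every combination of covariate
#' levels.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param nPerCondition cells per (condition, covariate combination).
#' @param dose dose applied to every active perturbation (default 1).
#' @param pairs list of character pairs to include as double
#'   perturbations; \code{"all"} for every unordered pair.
#' @return a design data.frame for \code{\link{generateDataset}}.
#' @export
basicDesign <- function(truth, nPerCondition = 100L, dose = 1,
                        pairs = list()) {
    perts <- truth@perturbations
    if (identical(pairs, "all"))
        pairs <- utils::combn(perts, 2, simplify = FALSE)
    conds <- data.frame(perturbation = "ctrl", dose = "0",
                        stringsAsFactors = FALSE)
    conds <- rbind(conds, data.frame(perturbation = perts,
                                     dose = .formatDose(rep(dose, length(perts))),
                                     stringsAsFactors = FALSE))
    for (pr in pairs) {
        stopifnot(all(pr %in% perts))
        conds <- rbind(conds, data.frame(
            perturbation = paste(sort(pr), collapse = "+"),
            dose = paste(.formatDose(c(dose, dose)), collapse = "+"),
            stringsAsFactors = FALSE))
    }
    covGrid <- expand.grid(truth@covariateSchemas, stringsAsFactors = FALSE,
                           KEEP.OUT.ATTRS = FALSE)
    out <- merge(conds, covGrid, by = NULL)
    out$n <- as.integer(nPerCondition)
    out
}

#' Split plan holding out double-perturbation conditions
#'
#' Marks every cell whose applied perturbation set equals one of the held
#' pairs as out-of-distribution.
#'
#' @param ds a \linkS4class{PerturbationExperiment}.
#' @param heldPairs list of character pairs, e.g. \code{list(c("A","B"))};
#'   empty list gives an empty ood set.
#' @param testFraction,seed passed to \code{\link{SplitPlan}}.
#' @return a \linkS4class{SplitPlan}.
#' @export
holdoutDesign <- function(ds, heldPairs, testFraction = 0.2, seed = 1L) {
    perts <- perturbationNames(ds)
    D <- doses(ds)
    cond <- conditionIds(ds)
    applied <- apply(D > 0, 1, function(r) paste(sort(perts[r]), collapse = "+"))
    ood <- character()
    for (pr in heldPairs) {
        key <- paste(sort(pr), collapse = "+")
        hit <- unique(cond[applied == key])
        if (length(hit) == 0)
            stop(sprintf("held pair %s has no cells in the dataset", key))
        ood <- c(ood, hit)
    }
    SplitPlan(oodConditions = unique(ood), testFraction = testFraction,
              seed = seed)
}
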