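# Pairwise genetic-interaction analysis: delta profiles, two-coefficient
# regression, distance-correlation metrics, rule-based mode classification,
# and full-pair imputation bookkeeping.

#' Expression deltas of a perturbation pair versus control
#'
#' Per-gene condition means minus the per-gene control mean, for the two
#' singles and the double, all against the same control and gene order.
#'
#' @param x a \linkS4class{PerturbationExperiment}, or a numeric matrix of
#'   condition mean profiles with rownames containing the four condition
#'   ids.
#' @param a,b,ab,control condition ids of the two singles, the double and
#'   the control.
#' @return list with \code{deltaA}, \code{deltaB}, \code{deltaAB}
#'   (length-G vectors).
#' @export
computeDeltas <- function(x, a, b, ab, control) {
    want <- c(a = a, b = b, ab = ab, control = control)
    if (is(x, "PerturbationExperiment")) {
        cond <- conditionIds(x)
        X <- cellMatrix(x)
        prof <- lapply(want, function(cc) {
            i <- which(cond == cc)
            if (length(i) == 0) stop(sprintf("condition '%s' absent", cc))
            colMeans(X[i, , drop = FALSE])
        })
    } else {
        miss <- setdiff(want, rownames(x))
        if (length(miss))
            stop(sprintf("condition(s) absent from profile matrix: %s",
                         paste(miss, collapse = ", ")))
        prof <- lapply(want, function(cc) x[cc, ])
    }
    list(deltaA = prof$a - prof$control,
         deltaB = prof$b - prof$control,
         deltaAB = prof$ab - prof$control)
}

#' No-intercept regression of the double delta on the single deltas
#'
#' Least squares for \code{deltaAB = c1 * deltaA + c2 * deltaB}. A
#' rank-deficient predictor pair (collinear singles) is solved by the
#' minimal-norm pseudoinverse solution. \code{fitDcor} is the distance
#' correlation between fitted and observed double deltas.
#'
#' @param deltas list as returned by \code{\link{computeDeltas}}.
#' @return list with \code{c1}, \code{c2}, \code{fitDcor}.
#' @export
fitPairRegression <- function(deltas) {
    A <- cbind(deltas$deltaA, deltas$deltaB)
    y <- deltas$deltaAB
    if (nrow(A) < 2) stop("need at least two genes")
    if (all(A == 0)) stop("both single deltas are exactly zero")
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-10
    cf <- sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    fitted <- drop(A %*% cf)
    list(c1 = cf[1], c2 = cf[2],
         fitDcor = distanceCorrelation(fitted, y))
}

#' Distance correlation (Szekely)
#'
#' Sample distance correlation between two samples of equal length, via
#' double-centered pairwise euclidean distance matrices. Lies in [0, 1];
#' equals 1 for non-constant \code{x} against itself or any non-degenerate
#' affine image, and approaches 0 for independent samples. A constant
#' (zero-variance) input is defined to have distance correlation 0.
#'
#' @param u numeric vector, or a matrix whose rows are observations.
#' @param v numeric vector (or matrix) with the same number of
#'   observations.
#' @return scalar in [0, 1].
#' @export
distanceCorrelation <- function(u, v) {
    U <- if (is.matrix(u)) u else matrix(u, ncol = 1)
    V <- if (is.matrix(v)) v else matrix(v, ncol = 1)
    if (nrow(U) != nrow(V)) stop("unequal number of observations")
    if (nrow(U) < 2) stop("need at least two observations")
    dc <- function(M) {
        D <- as.matrix(stats::dist(M))
        D - outer(rowMeans(D), colMeans(D), `+`) + mean(D)
    }
    A <- dc(U); B <- dc(V)
    dcov2 <- mean(A * B)
    dvarU <- mean(A * A); dvarV <- mean(B * B)
    if (dvarU <= 0 || dvarV <= 0) return(0)
    r <- dcov2 / sqrt(dvarU * dvarV)
    if (r <= 0) 0 else min(sqrt(r), 1)
}

#' All pairwise interaction metrics for one gene pair
#'
#' Regression coefficients \code{c1}, \code{c2} and the goodness of the
#' two-coefficient fit; \code{magnitude = sqrt(c1^2 + c2^2)};
#' \code{dominance = log10(|c1| / |c2|)} (clipped to +/- 6 when a
#' coefficient is zero); the distance correlations between the single
#' transcriptome deltas, between the joint two-column single matrix and
#' the double delta, and the equal-contribution ratio
#' \code{min(dcor(dA, dAB), dcor(dB, dAB)) / max(...)}.
#'
#' @param deltas list from \code{\link{computeDeltas}}.
#' @param pair optional character(2) pair label.
#' @return an \linkS4class{InteractionMetrics}.
#' @export
interactionMetrics <- function(deltas, pair = c(NA_character_, NA_character_)) {
    fit <- fitPairRegression(deltas)
    c1 <- fit$c1; c2 <- fit$c2
    dom <- if (c1 == 0 && c2 == 0) 0
        else if (c2 == 0) 6
        else if (c1 == 0) -6
        else max(-6, min(6, log10(abs(c1) / abs(c2))))
    dAab <- distanceCorrelation(deltas$deltaA, deltas$deltaAB)
    dBab <- distanceCorrelation(deltas$deltaB, deltas$deltaAB)
    eq <- if (max(dAab, dBab) == 0) 0 else min(dAab, dBab) / max(dAab, dBab)
    new("InteractionMetrics", pair = as.character(pair),
        c1 = c1, c2 = c2, fitDcor = fit$fitDcor,
        magnitude = sqrt(c1^2 + c2^2), dominance = dom,
        dcorSingles = distanceCorrelation(deltas$deltaA, deltas$deltaB),
        dcorJointDouble = distanceCorrelation(
            cbind(deltas$deltaA, deltas$deltaB), deltas$deltaAB),
        equalContrib = eq)
}

#' Rule-based genetic-interaction mode
#'
#' Evaluates the six annotation rules on the metric panel; if exactly one
#' rule fires its mode is assigned, otherwise (zero or two or more matches)
#' the pair is left unassigned, with the matched rules recorded. The
#' printed thresholds compare a distance correlation against 1; since dcor
#' never exceeds 1, the comparisons are interpreted as dissimilarity
#' \code{|dcor - 1|} exceeding (or staying below) the threshold:
#' \itemize{
#'   \item epistatic: \code{min(|c1|, |c2|) > 0.2} and one coefficient more
#'     than twice the other (in absolute value).
#'   \item potentiation: \code{magnitude > 1} and \code{|dcor(dA, dB) - 1| > 0.2}.
#'   \item strong synergy (similar phenotypes): \code{magnitude > 1} and
#'     \code{|dcor([dA dB], dAB) - 1| > 0.2}.
#'   \item strong synergy (different phenotypes): \code{magnitude > 1} and
#'     \code{|dcor(dA, dB) - 1| > 0.5}.
#'   \item additive: \code{|magnitude - 1| < 0.1}.
#'   \item redundant: \code{|dcor([dA dB], dAB) - 1| < 0.2} and
#'     \code{|dcor(dA, dB) - 1| < 0.2}.
#' }
#'
#' @param m an \linkS4class{InteractionMetrics}.
#' @return list with \code{mode} (one of epistatic, potentiation,
#'   strong_synergy_similar, strong_synergy_different, additive, redundant,
#'   unassigned) and \code{matchedRules}.
#' @export
classifyMode <- function(m) {
    a1 <- abs(m@c1); a2 <- abs(m@c2)
    dAB <- m@dcorSingles
    dJD <- m@dcorJointDouble
    fired <- character()
    if (min(a1, a2) > 0.2 && (a1 > 2 * a2 || a2 > 2 * a1))
        fired <- c(fired, "epistatic")
    if (m@magnitude > 1 && abs(dAB - 1) > 0.2)
        fired <- c(fired, "potentiation")
    if (m@magnitude > 1 && abs(dJD - 1) > 0.2)
        fired <- c(fired, "strong_synergy_similar")
    if (m@magnitude > 1 && abs(dAB - 1) > 0.5)
        fired <- c(fired, "strong_synergy_different")
    if (abs(m@magnitude - 1) < 0.1)
        fired <- c(fired, "additive")
    if (abs(dJD - 1) < 0.2 && abs(dAB - 1) < 0.2)
        fired <- c(fired, "redundant")
    mode <- if (length(fired) == 1) fired else "unassigned"
    list(mode = mode, matchedRules = fired)
}

#' Count unmeasured perturbation pairs
#'
#' Out of \code{choose(n, 2)} possible unordered pairs of \code{n} single
#' perturbations, how many were not measured, and which percentage of all
#' possibilities that is (one decimal).
#'
#' @param nSingleGenes number of single perturbations n.
#' @param nMeasuredPairs number of measured unordered pairs
#'   (<= choose(n, 2)).
#' @return list with \code{missing} and \code{percentMissing}.
#' @export
countMissingPairs <- function(nSingleGenes, nMeasuredPairs) {
    total <- choose(nSingleGenes, 2)
    if (nMeasuredPairs > total)
        stop("more measured pairs than possible pairs")
    missing <- total - nMeasuredPairs
    if (missing < 0) stop("negative missing count")
    list(missing = as.integer(missing),
         percentMissing = round(100 * missing / total, 1))
}

#' Impute all unmeasured perturbation pairs
#'
#' Iterates every unordered pair of single perturbations whose combination
#' is absent from the dataset, predicts the condition mean counterfactually
#' from \code{nCellsPerPair} control cells, and attaches the
#' condition-level uncertainty (one row per pair). Measured pairs are
#' excluded.
#'
#' @param model a trained \linkS4class{CPAModel}.
#' @param ds the training \linkS4class{PerturbationExperiment}.
#' @param nCellsPerPair number of control cells whose basal states are
#'   recombined per pair (default 50).
#' @param dose dose applied to both members of each imputed pair
#'   (default 1).
#' @param covariates covariate assignment for the imputed conditions;
#'   default: the most frequent assignment among control cells.
#' @param seed seed for drawing the control cells.
#' @return data.frame with pair id, predicted per-gene means (matrix
#'   column \code{mean}), uncertainty scores and nearest training
#'   condition.
#' @export
imputeAllPairs <- function(model, ds, nCellsPerPair = 50L, dose = 1,
                           covariates = NULL, seed = 1L) {
    perts <- model@perturbations
    D <- doses(ds)
    applied <- apply(D > 0, 1, function(r) paste(sort(perts[r]), collapse = "+"))
    measured <- unique(applied[rowSums(D > 0) == 2])
    allPairs <- utils::combn(perts, 2, simplify = FALSE)
    keys <- vapply(allPairs, function(p) paste(sort(p), collapse = "+"),
                   character(1))
    todo <- which(!keys %in% measured)
    ctrlIdx <- which(rowSums(D > 0) == 0)
    if (length(ctrlIdx) == 0) stop("no control cells in the dataset")
    covDf <- covariateAssignments(ds)
    if (is.null(covariates)) {
        cc <- covDf[ctrlIdx, , drop = FALSE]
        key <- do.call(paste, c(as.list(cc), sep = "\r"))
        covariates <- cc[which(key == names(which.max(table(key))))[1], ,
                         drop = FALSE]
    }
    covariates <- as.data.frame(covariates)
    ctrlKey <- do.call(paste, c(as.list(covDf[ctrlIdx, , drop = FALSE]),
                                sep = "\r"))
    wantKey <- do.call(paste, c(as.list(covariates), sep = "\r"))
    pool <- ctrlIdx[ctrlKey == wantKey]
    if (length(pool) == 0) pool <- ctrlIdx
    X <- cellMatrix(ds)
    sp <- splitLabels(ds)
    trainConds <- if (all(is.na(sp))) unique(conditionIds(ds)) else
        unique(conditionIds(ds)[!is.na(sp) & sp == "train"])
    rows <- vector("list", length(todo))
    withSeed(seed, {
        for (ii in seq_along(todo)) {
            pr <- allPairs[[todo[ii]]]
            dv <- setNames(numeric(length(perts)), perts)
            dv[pr] <- dose
            cells <- X[sample(pool, min(nCellsPerPair, length(pool))), ,
                       drop = FALSE]
            pred <- predictCondition(model, cells, covariates, dv)
            unc <- conditionUncertainty(model, dv, unlist(covariates),
                                        trainConds)
            rows[[ii]] <- list(pair = keys[todo[ii]], mean = pred$mean,
                               uCosine = unc$uCosine,
                               uEuclidean = unc$uEuclidean,
                               nearestCondition = unc$nearestCondition)
        }
    })
    out <- data.frame(
        pair = vapply(rows, `[[`, character(1), "pair"),
        uCosine = vapply(rows, `[[`, numeric(1), "uCosine"),
        uEuclidean = vapply(rows, `[[`, numeric(1), "uEuclidean"),
        nearestCondition = vapply(rows, `[[`, character(1),
                                  "nearestCondition"),
        stringsAsFactors = FALSE)
    out$mean <- do.call(rbind, lapply(rows, `[[`, "mean"))
    out
}
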