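# Scoring harness: R2 on condition means/variances, DEG subsets, random and
# linear baselines, gene-wise Wasserstein distance, clustering agreement.

#' Coefficient of determination
#'
#' \code{1 - SS_res / SS_tot} with the total sum of squares taken about the
#' mean of \code{yTrue}. Equals 1 for a perfect prediction, 0 for the
#' constant mean predictor, and can be arbitrarily negative.
#'
#' @param yTrue,yPred numeric vectors of equal length >= 2; \code{yTrue}
#'   must not be constant.
#' @return scalar R2.
#' @export
r2Score <- function(yTrue, yPred) {
    if (length(yTrue) != length(yPred)) stop("length mismatch")
    if (length(yTrue) < 2) stop("need at least two observations")
    sst <- sum((yTrue - mean(yTrue))^2)
    if (sst == 0) stop("R2 undefined for constant yTrue")
    1 - sum((yTrue - yPred)^2) / sst
}

# Vectorized two-sample Wilcoxon rank-sum z-statistics (normal
# approximation with tie correction), one per gene (column).
.rankSumZ <- function(A, B) {
    n1 <- nrow(A); n2 <- nrow(B); N <- n1 + n2
    vapply(seq_len(ncol(A)), function(g) {
        v <- c(A[, g], B[, g])
        r <- rank(v)
        W <- sum(r[seq_len(n1)])
        muW <- n1 * (N + 1) / 2
        ties <- table(v)
        tieCorr <- sum(ties^3 - ties) / (N * (N - 1))
        s2 <- n1 * n2 / 12 * ((N + 1) - tieCorr)
        if (s2 <= 0) return(0)
        (W - muW) / sqrt(s2)
    }, numeric(1))
}

#' Select top differentially expressed genes versus control
#'
#' Per-gene two-sample Wilcoxon rank-sum statistic between the cells of
#' \code{condition} and \code{control}; genes are ranked by the absolute
#' standardized statistic, ties broken by gene index, and the top \code{n}
#' returned. The ranking is nested: growing \code{n} never drops a
#' previously selected gene.
#'
#' @param ds a \linkS4class{PerturbationExperiment}.
#' @param condition,control condition ids, each with >= 2 cells.
#' @param n number of genes to return (<= G).
#' @return integer vector of gene indices (columns of
#'   \code{cellMatrix(ds)}), in rank order.
#' @export
selectTopDegs <- function(ds, condition, control, n) {
    X <- cellMatrix(ds)
    if (n > ncol(X)) stop(sprintf("n (%d) exceeds gene count (%d)", n, ncol(X)))
    cond <- conditionIds(ds)
    iA <- which(cond == condition)
    iB <- which(cond == control)
    if (length(iA) < 2 || length(iB) < 2)
        stop("both conditions need at least 2 cells")
    z <- .rankSumZ(X[iA, , drop = FALSE], X[iB, , drop = FALSE])
    ord <- order(-abs(z), seq_along(z))
    ord[seq_len(n)]
}

#' Random baseline: statistics of a random training subset
#'
#' Draws a seeded random subset of training cells of the same size as the
#' target condition (capped at the train-split size) and returns its
#' per-gene mean and unbiased variance. R2 of a model prediction should
#' beat the R2 of this baseline if the model learned more than the average
#' training profile.
#'
#' @param ds a split \linkS4class{PerturbationExperiment}.
#' @param targetCondition condition id whose cell count sets the subset
#'   size.
#' @param seed integer seed.
#' @return list with \code{mean} and \code{variance} (length-G vectors)
#'   and \code{cells} (the drawn row indices).
#' @export
randomBaseline <- function(ds, targetCondition, seed = 1L) {
    sp <- splitLabels(ds)
    trainIdx <- which(!is.na(sp) & sp == "train")
    if (length(trainIdx) == 0) stop("empty train split")
    nTarget <- sum(conditionIds(ds) == targetCondition)
    if (nTarget == 0)
        stop(sprintf("condition '%s' not present", targetCondition))
    size <- min(nTarget, length(trainIdx))
    idx <- withSeed(seed, sample(trainIdx, size))
    X <- cellMatrix(ds)[idx, , drop = FALSE]
    list(mean = colMeans(X), variance = apply(X, 2, var), cells = idx)
}

#' Linear baseline for a combination: average of the two pseudobulks
#'
#' \code{(meanA + meanB) / 2}, elementwise; symmetric in its arguments.
#'
#' @param meanA,meanB per-gene mean expression of the two single
#'   perturbations (equal lengths).
#' @return the averaged profile.
#' @export
linearBaseline <- function(meanA, meanB) {
    if (length(meanA) != length(meanB)) stop("length mismatch")
    (meanA + meanB) / 2
}

# Exact 1-D Wasserstein-1 distance between two empirical distributions:
# integral of |F1 - F2| over the merged support.
.w1 <- function(x, y) {
    xs <- sort(x); ys <- sort(y)
    grid <- sort(unique(c(xs, ys)))
    if (length(grid) == 1) return(0)
    Fx <- findInterval(grid, xs) / length(xs)
    Fy <- findInterval(grid, ys) / length(ys)
    k <- length(grid)
    sum(abs(Fx[-k] - Fy[-k]) * diff(grid))
}

#' Gene-wise Wasserstein distance between real and predicted cells
#'
#' Per-gene 1-D Wasserstein-1 distance between the empirical distributions
#' of real and predicted values, averaged over genes. Symmetric; zero iff
#' the per-gene empirical distributions coincide.
#'
#' @param realCells,predSamples matrices (cells x genes) with the same
#'   gene order.
#' @return scalar mean distance.
#' @export
geneWiseWasserstein <- function(realCells, predSamples) {
    if (ncol(realCells) != ncol(predSamples)) stop("gene sets differ")
    if (nrow(realCells) == 0 || nrow(predSamples) == 0)
        stop("empty sample")
    mean(vapply(seq_len(ncol(realCells)), function(g)
        .w1(realCells[, g], predSamples[, g]), numeric(1)))
}

.entropy <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
}

# Homogeneity: 1 - H(class | cluster) / H(class).
.homogeneity <- function(labels, membership) {
    tab <- table(labels, membership)
    N <- sum(tab)
    Hc <- .entropy(rowSums(tab) / N)
    if (Hc == 0) return(1)
    Hck <- 0
    for (k in seq_len(ncol(tab))) {
        nk <- sum(tab[, k])
        if (nk == 0) next
        Hck <- Hck + nk / N * .entropy(tab[, k] / nk)
    }
    1 - Hck / Hc
}

#' Clustering agreement of condition embeddings with known programs
#'
#' Builds a k-nearest-neighbour graph on the euclidean distances between
#' condition embeddings for every k in \code{kGrid}, Leiden-clusters it at
#' every resolution in \code{resolutionGrid}, and reports the grid optimum
#' of the normalized mutual information against the known labels, together
#' with the silhouette width and homogeneity at that optimum.
#'
#' @param embeddings matrix, one row per condition.
#' @param labels known program labels (>= 2 distinct values).
#' @param kGrid neighbour counts (default 3:10).
#' @param resolutionGrid Leiden resolutions (default
#'   c(0.3, 0.4, 0.5, 0.6, 0.7, 0.75, 0.8, 0.85, 0.9, 1)).
#' @param seed seed for the Leiden refinement.
#' @return list with \code{nmi}, \code{silhouette}, \code{homogeneity},
#'   \code{k}, \code{resolution}, \code{membership}.
#' @export
clusteringAgreement <- function(embeddings, labels, kGrid = 3:10,
                                resolutionGrid = c(0.3, 0.4, 0.5, 0.6, 0.7,
                                                   0.75, 0.8, 0.85, 0.9, 1),
                                seed = 1L) {
    n <- nrow(embeddings)
    labels <- as.integer(factor(labels))
    if (length(unique(labels)) < 2) stop("need at least 2 distinct labels")
    if (n <= min(kGrid)) stop("fewer conditions than the smallest k")
    dd <- as.matrix(stats::dist(embeddings))
    best <- list(nmi = -Inf)
    withSeed(seed, {
        for (k in kGrid[kGrid < n]) {
            adj <- matrix(0, n, n)
            for (i in seq_len(n)) {
                nb <- order(dd[i, ])[2:(k + 1)]
                adj[i, nb] <- 1
            }
            adj <- pmax(adj, t(adj))
            g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
            for (res in resolutionGrid) {
                cl <- igraph::cluster_leiden(
                    g, objective_function = "modularity",
                    resolution = res, n_iterations = 5)
                memb <- igraph::membership(cl)
                nmi <- igraph::compare(memb, labels, method = "nmi")
                if (nmi > best$nmi)
                    best <- list(nmi = nmi, k = k, resolution = res,
                                 membership = as.integer(memb))
            }
        }
    })
    memb <- best$membership
    sil <- if (length(unique(memb)) < 2) NA_real_ else
        mean(cluster::silhouette(memb, dmatrix = dd)[, "sil_width"])
    list(nmi = best$nmi, silhouette = sil,
         homogeneity = .homogeneity(labels, memb),
         k = best$k, resolution = best$resolution, membership = memb)
}

#' Score counterfactual predictions for one condition
#'
#' Computes the benchmark panel for a single (typically held-out)
#' condition: R2 between predicted and observed per-gene means and
#' variances, over all genes and over the top-\code{nDegs} DEG subset
#' (condition versus control, rank-sum ranked), plus the mean gene-wise
#' Wasserstein distance between observed cells and per-cell predictions.
#'
#' @param ds a split \linkS4class{PerturbationExperiment}.
#' @param model a trained \linkS4class{CPAModel}.
#' @param condition target condition id.
#' @param control control condition id (used for DEG ranking and as the
#'   source cells whose basal states are recombined with the target doses).
#' @param nDegs DEG subset size (default 50).
#' @return one-row data.frame mirroring the per-condition score fields.
#' @export
scoreCondition <- function(ds, model, condition, control, nDegs = 50L) {
    cond <- conditionIds(ds)
    iT <- which(cond == condition)
    iC <- which(cond == control)
    if (length(iT) == 0) stop(sprintf("condition '%s' absent", condition))
    if (length(iC) == 0) stop(sprintf("control '%s' absent", control))
    X <- cellMatrix(ds)
    covNames <- names(covariateSchemas(ds))
    pc <- parseConditionId(condition, perturbationNames(ds), covNames)
    ctrlCells <- X[iC, , drop = FALSE]
    covDf <- covariateAssignments(ds)[iC, , drop = FALSE]
    pred <- predictCondition(model, ctrlCells, unique(covDf), pc$dose)
    obs <- X[iT, , drop = FALSE]
    obsMean <- colMeans(obs)
    obsVar <- apply(obs, 2, var)
    degs <- selectTopDegs(ds, condition, control, nDegs)
    predVarAcross <- apply(pred$cells@mean, 2, var) + pred$variance
    data.frame(
        condition = condition,
        r2MeanAll = r2Score(obsMean, pred$mean),
        r2VarAll = r2Score(obsVar, predVarAcross),
        r2MeanDegs = r2Score(obsMean[degs], pred$mean[degs]),
        r2VarDegs = r2Score(obsVar[degs], predVarAcross[degs]),
        nCellsReal = length(iT),
        wassersteinMean = geneWiseWasserstein(obs, pred$cells@mean),
        stringsAsFactors = FALSE)
}
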