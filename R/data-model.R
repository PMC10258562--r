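#' Canonical condition identifier
#'
#' Builds the condition key \code{"perts@doses|cov1|...|covK"} from a dose
#' row and a covariate row. Perturbation names inside a combination are
#' sorted lexicographically (so \code{"A+B"} and \code{"B+A"} denote the
#' same condition) and doses are aligned to the sorted order. Cells with no
#' applied perturbation (all doses zero) get the key \code{"ctrl"}. The key
#' is a pure function of its inputs and round-trips through
#' \code{\link{parseConditionId}}.
#'
#' @param doses numeric vector of length M, or an N x M matrix.
#' @param covariates data.frame/list of covariate assignments (N rows), or a
#'   single named character vector.
#' @param perturbations the M perturbation names.
#' @return character vector of condition ids.
#' @examples
#' conditionId(c(A = 1, B = 1), list(cell_line = "lineX"), c("A", "B"))
#' @export
conditionId <- function(doses, covariates, perturbations) {
    if (!is.matrix(doses))
        doses <- matrix(doses, nrow = 1, dimnames = list(NULL, perturbations))
    if (is.atomic(covariates) && !is.null(names(covariates)))
        covariates <- as.data.frame(as.list(covariates),
                                    stringsAsFactors = FALSE)
    covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
    stopifnot(ncol(doses) == length(perturbations))
    if (any(doses < 0)) stop("doses must be >= 0")
    vapply(seq_len(nrow(doses)), function(i) {
        d <- doses[i, ]
        applied <- which(d > 0)
        if (length(applied) == 0L) {
            key <- "ctrl"
        } else {
            ord <- applied[order(perturbations[applied])]
            key <- paste0(paste(perturbations[ord], collapse = "+"), "@",
                          paste(.formatDose(d[ord]), collapse = "+"))
        }
        if (ncol(covariates) > 0)
            key <- paste(c(key, as.character(unlist(covariates[i, ,
                drop = TRUE]))), collapse = "|")
        key
    }, character(1))
}

#' Parse a condition identifier back into doses and covariates
#'
#' Inverse of \code{\link{conditionId}}.
#'
#' @param id a single condition id.
#' @param perturbations the M perturbation names.
#' @param covariateNames names of the covariates, in schema order.
#' @return list with \code{dose} (named length-M vector) and
#'   \code{covariates} (named character vector).
#' @export
parseConditionId <- function(id, perturbations, covariateNames = character()) {
    parts <- strsplit(id, "|", fixed = TRUE)[[1]]
    if (length(parts) != 1 + length(covariateNames))
        stop(sprintf("condition id '%s' does not match %d covariate(s)", id,
                     length(covariateNames)))
    covs <- setNames(as.list(parts[-1]), covariateNames)
    dose <- setNames(numeric(length(perturbations)), perturbations)
    pk <- parts[1]
    if (pk != "ctrl") {
        halves <- strsplit(pk, "@", fixed = TRUE)[[1]]
        if (length(halves) != 2) stop(sprintf("malformed condition id '%s'", id))
        ps <- strsplit(halves[1], "+", fixed = TRUE)[[1]]
        ds <- as.numeric(strsplit(halves[2], "+", fixed = TRUE)[[1]])
        if (length(ps) != length(ds))
            stop(sprintf("condition id '%s': %d perturbations but %d doses",
                         id, length(ps), length(ds)))
        unknown <- setdiff(ps, perturbations)
        if (length(unknown))
            stop(sprintf("unknown perturbation(s) in id: %s",
                         paste(unknown, collapse = ", ")))
        dose[ps] <- ds
    }
    list(dose = dose, covariates = unlist(covs))
}

#' Library-size normalization, log transform and HVG selection
#'
#' Cells are scaled to the median total count, then \code{log(x + 1)}
#' transformed. Genes are ranked by normalized dispersion (variance/mean of
#' the normalized counts, z-scored within 20 equal-frequency mean bins) and
#' the top \code{nHvg} retained, ties broken by gene index. Because the
#' per-cell transform is monotone with fixed point 0, zeros are preserved
#' exactly.
#'
#' @param counts non-negative count matrix, cells x genes, or a
#'   \linkS4class{PerturbationExperiment} carrying a \code{"counts"} assay.
#' @param nHvg number of highly variable genes to keep (\code{<=} G).
#' @return for a matrix input: the transformed cells x genes matrix, subset
#'   to the selected genes, with attribute \code{"hvg"} (integer indices
#'   into the original gene order, in rank order sorted increasingly). For a
#'   PerturbationExperiment: the same object with a \code{"logcounts"} assay
#'   restricted to the selected genes.
#' @export
preprocessExpression <- function(counts, nHvg) {
    if (is(counts, "PerturbationExperiment")) {
        if (!"counts" %in% assayNames(counts))
            stop("PerturbationExperiment input requires a 'counts' assay")
        raw <- t(assay(counts, "counts"))
        mat <- preprocessExpression(raw, nHvg)
        keep <- attr(mat, "hvg")
        out <- counts[keep, ]
        assay(out, "logcounts") <- t(mat)
        return(out)
    }
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("raw counts must be >= 0")
    G <- ncol(counts)
    if (nHvg > G) stop(sprintf("nHvg (%d) exceeds gene count (%d)", nHvg, G))
    totals <- rowSums(counts)
    zero <- which(totals == 0)
    if (length(zero))
        stop(sprintf("all-zero cell(s) at index: %s",
                     paste(utils::head(zero, 5), collapse = ", ")))
    target <- median(totals)
    norm <- counts * (target / totals)
    mu <- colMeans(norm)
    v <- apply(norm, 2, var)
    disp <- ifelse(mu > 0, v / mu, 0)
    nb <- max(1L, min(20L, G %/% 20L))   # ~20+ genes per mean bin
    bins <- if (nb == 1L) rep(1L, G) else
        cut(rank(mu, ties.method = "first"), breaks = nb, labels = FALSE)
    zdisp <- disp
    for (b in unique(bins)) {
        idx <- which(bins == b)
        s <- sd(disp[idx])
        m <- mean(disp[idx])
        zdisp[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - m) / s
    }
    ord <- order(-zdisp, seq_len(G))
    keep <- sort(ord[seq_len(nHvg)])
    out <- log1p(norm[, keep, drop = FALSE])
    attr(out, "hvg") <- keep
    out
}

#' Assign train/test/ood split labels
#'
#' Cells belonging to the plan's held-out (ood) conditions are labelled
#' \code{"ood"} and never enter train or test. Remaining cells are
#' partitioned per condition: a fraction \code{testFraction} (rounded) is
#' drawn as \code{"test"} with the plan's seed, the rest is \code{"train"}.
#' The assignment is a deterministic function of the dataset and the plan.
#'
#' @param ds a \linkS4class{PerturbationExperiment}.
#' @param plan a \linkS4class{SplitPlan}; every ood condition must occur in
#'   \code{ds}.
#' @return \code{ds} with split labels filled in.
#' @export
makeSplit <- function(ds, plan) {
    cond <- conditionIds(ds)
    missing <- setdiff(plan@oodConditions, cond)
    if (length(missing))
        stop(sprintf("ood condition(s) not present in dataset: %s",
                     paste(missing, collapse = ", ")))
    split <- rep("train", length(cond))
    split[cond %in% plan@oodConditions] <- "ood"
    withSeed(plan@seed, {
        for (cc in sort(unique(cond[split != "ood"]))) {
            idx <- which(cond == cc & split != "ood")
            nTest <- round(length(idx) * plan@testFraction)
            if (nTest > 0)
                split[sample(idx, nTest)] <- "test"
        }
    })
    splitLabels(ds) <- split
    ds
}
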