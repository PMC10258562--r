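#' Read and write annotated perturbation datasets
#'
#' Two on-disk dialects are supported. \code{"mtx+tsv"} stores a
#' MatrixMarket matrix (cells as rows, 1-based coordinates per the MTX
#' standard), \code{obs.tsv} / \code{var.tsv} annotation tables (UTF-8, with
#' header), and a YAML sidecar \code{config.yaml} naming the perturbation,
#' dose and covariate columns, the combination delimiter (\code{"+"}) and
#' the perturbation vocabulary. \code{"h5-annotated"} stores the same
#' content in a single HDF5 file (requires the \pkg{rhdf5} package).
#'
#' Combined perturbations are serialized as delimited strings, e.g.
#' perturbation \code{"A+B"} with dose \code{"1+1"}; these are parsed back
#' into the full M-length dose vector on read. Control cells carry
#' perturbation \code{"ctrl"} and dose \code{"0"}.
#'
#' @param ds a \linkS4class{PerturbationExperiment}.
#' @param path directory (mtx+tsv) or \code{.h5} file path (h5-annotated).
#' @param dialect one of \code{"mtx+tsv"}, \code{"h5-annotated"}; inferred
#'   from \code{path} when \code{NULL}.
#' @return \code{readPerturbDataset} returns a validated
#'   \linkS4class{PerturbationExperiment}; \code{writePerturbDataset}
#'   returns \code{path} invisibly.
#' @name dataset-io
NULL

.inferDialect <- function(path) {
    if (grepl("\\.h5$", path)) "h5-annotated" else "mtx+tsv"
}

.obsTable <- function(ds, delim = "+") {
    d <- doses(ds)
    perts <- perturbationNames(ds)
    pertStr <- character(nrow(d))
    doseStr <- character(nrow(d))
    for (i in seq_len(nrow(d))) {
        applied <- which(d[i, ] > 0)
        if (length(applied) == 0L) {
            pertStr[i] <- "ctrl"; doseStr[i] <- "0"
        } else {
            ord <- applied[order(perts[applied])]
            pertStr[i] <- paste(perts[ord], collapse = delim)
            doseStr[i] <- paste(.formatDose(d[i, ord]), collapse = delim)
        }
    }
    obs <- data.frame(cell = colnames(ds), perturbation = pertStr,
                      dose = doseStr, stringsAsFactors = FALSE)
    for (cv in names(covariateSchemas(ds)))
        obs[[cv]] <- as.character(colData(ds)[[cv]])
    obs$split <- ifelse(is.na(splitLabels(ds)), "", splitLabels(ds))
    obs
}

.obsToAnnotations <- function(obs, cfg) {
    need <- c(cfg$perturbation_column, cfg$dose_column, cfg$covariate_columns)
    miss <- setdiff(need, colnames(obs))
    if (length(miss))
        stop(sprintf("annotation table is missing column(s): %s",
                     paste(miss, collapse = ", ")))
    perts <- cfg$perturbations
    delim <- cfg$delimiter
    n <- nrow(obs)
    d <- matrix(0, n, length(perts), dimnames = list(NULL, perts))
    pertStr <- obs[[cfg$perturbation_column]]
    doseStr <- obs[[cfg$dose_column]]
    for (i in seq_len(n)) {
        if (pertStr[i] == "ctrl" || pertStr[i] == "") next
        ps <- strsplit(pertStr[i], delim, fixed = TRUE)[[1]]
        dsV <- as.numeric(strsplit(as.character(doseStr[i]), delim,
                                   fixed = TRUE)[[1]])
        if (length(ps) != length(dsV))
            stop(sprintf("row %d: %d perturbation(s) but %d dose value(s)",
                         i, length(ps), length(dsV)))
        unknown <- setdiff(ps, perts)
        if (length(unknown))
            stop(sprintf("row %d: unknown perturbation(s): %s", i,
                         paste(unknown, collapse = ", ")))
        if (any(is.na(dsV) | dsV < 0))
            stop(sprintf("row %d: doses must be numeric and >= 0", i))
        d[i, ps] <- dsV
    }
    covs <- obs[, cfg$covariate_columns, drop = FALSE]
    list(doses = d, covariates = covs)
}

.ioConfig <- function(ds) {
    list(perturbation_column = "perturbation",
         dose_column = "dose",
         covariate_columns = as.list(names(covariateSchemas(ds))),
         delimiter = "+",
         perturbations = as.list(perturbationNames(ds)),
         covariate_levels = lapply(covariateSchemas(ds), as.list))
}

.normalizeConfig <- function(cfg) {
    cfg$perturbations <- unlist(cfg$perturbations)
    cfg$covariate_columns <- unlist(cfg$covariate_columns)
    if (is.null(cfg$covariate_columns)) cfg$covariate_columns <- character()
    cfg$covariate_levels <- lapply(cfg$covariate_levels, unlist)
    cfg$delimiter <- cfg$delimiter %||% "+"
    cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname dataset-io
#' @export
writePerturbDataset <- function(ds, path, dialect = NULL) {
    dialect <- dialect %||% .inferDialect(path)
    obs <- .obsTable(ds)
    cfg <- .ioConfig(ds)
    X <- cellMatrix(ds)
    if (dialect == "mtx+tsv") {
        dir.create(path, showWarnings = FALSE, recursive = TRUE)
        Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(X,
            sparse = TRUE), "generalMatrix"), "CsparseMatrix"),
            file.path(path, "matrix.mtx"))
        utils::write.table(obs, file.path(path, "obs.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
        utils::write.table(data.frame(gene = colnames(X)),
                           file.path(path, "var.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
        yaml::write_yaml(cfg, file.path(path, "config.yaml"))
    } else if (dialect == "h5-annotated") {
        if (!requireNamespace("rhdf5", quietly = TRUE))
            stop("the h5-annotated dialect requires the rhdf5 package")
        if (file.exists(path)) unlink(path)
        rhdf5::h5createFile(path)
        rhdf5::h5write(X, path, "X")
        rhdf5::h5createGroup(path, "obs")
        for (cc in colnames(obs))
            rhdf5::h5write(obs[[cc]], path, paste0("obs/", cc))
        rhdf5::h5write(colnames(X), path, "var_names")
        rhdf5::h5write(yaml::as.yaml(cfg), path, "config_yaml")
        rhdf5::h5closeAll()
    } else stop(sprintf("unknown dialect '%s'", dialect))
    invisible(path)
}

#' @rdname dataset-io
#' @export
readPerturbDataset <- function(path, dialect = NULL) {
    dialect <- dialect %||% .inferDialect(path)
    if (dialect == "mtx+tsv") {
        for (f in c("matrix.mtx", "obs.tsv", "var.tsv", "config.yaml"))
            if (!file.exists(file.path(path, f)))
                stop(sprintf("missing file '%s' under %s", f, path))
        cfg <- .normalizeConfig(yaml::read_yaml(file.path(path, "config.yaml")))
        X <- as.matrix(Matrix::readMM(file.path(path, "matrix.mtx")))
        obs <- utils::read.table(file.path(path, "obs.tsv"), sep = "\t",
                                 header = TRUE, stringsAsFactors = FALSE,
                                 colClasses = "character")
        genes <- utils::read.table(file.path(path, "var.tsv"), sep = "\t",
                                   header = TRUE, stringsAsFactors = FALSE)$gene
    } else if (dialect == "h5-annotated") {
        if (!requireNamespace("rhdf5", quietly = TRUE))
            stop("the h5-annotated dialect requires the rhdf5 package")
        cfg <- .normalizeConfig(yaml::yaml.load(rhdf5::h5read(path, "config_yaml")))
        X <- rhdf5::h5read(path, "X")
        obsCols <- rhdf5::h5ls(path)
        obsCols <- obsCols$name[obsCols$group == "/obs"]
        obs <- as.data.frame(lapply(setNames(obsCols, obsCols), function(cc)
            as.character(rhdf5::h5read(path, paste0("obs/", cc)))),
            stringsAsFactors = FALSE)
        genes <- as.character(rhdf5::h5read(path, "var_names"))
        rhdf5::h5closeAll()
    } else stop(sprintf("unknown dialect '%s'", dialect))
    if (nrow(X) != nrow(obs))
        stop(sprintf("matrix has %d rows but obs table %d", nrow(X), nrow(obs)))
    if (ncol(X) != length(genes))
        stop(sprintf("matrix has %d columns but %d gene names", ncol(X),
                     length(genes)))
    ann <- .obsToAnnotations(obs, cfg)
    schemas <- cfg$covariate_levels
    colnames(X) <- genes
    if ("cell" %in% colnames(obs)) rownames(X) <- obs$cell
    out <- PerturbationExperiment(X, ann$doses, ann$covariates,
                                  perturbations = cfg$perturbations,
                                  covariateSchemas = schemas)
    if ("split" %in% colnames(obs)) {
        sp <- obs$split
        sp[sp == ""] <- NA_character_
        splitLabels(out) <- sp
    }
    out
}
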