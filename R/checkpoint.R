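#' Save / load a model checkpoint
#'
#' A checkpoint is a directory holding the full parameter set
#' (\code{weights.rds}) and a JSON manifest with the configuration and the
#' perturbation/covariate vocabularies, so compatibility of a checkpoint
#' with a dataset can be checked without loading the weights.
#'
#' @param model a \linkS4class{CPAModel}.
#' @param path checkpoint directory.
#' @return \code{saveCpaModel} returns \code{path} invisibly;
#'   \code{loadCpaModel} returns the model.
#' @export
saveCpaModel <- function(model, path) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(
        package = "cpae",
        version = as.character(utils::packageVersion("cpae")),
        genes = model@genes,
        perturbations = model@perturbations,
        covariateSchemas = model@covariateSchemas,
        latentDim = model@latentDim,
        advPert = model@advPert,
        trained = model@trained,
        config = model@config)
    jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    saveRDS(model@params, file.path(path, "weights.rds"))
    utils::write.csv(model@history, file.path(path, "history.csv"),
                     row.names = FALSE)
    invisible(path)
}

#' @rdname saveCpaModel
#' @export
loadCpaModel <- function(path) {
    mf <- jsonlite::read_json(file.path(path, "manifest.json"),
                              simplifyVector = TRUE)
    params <- readRDS(file.path(path, "weights.rds"))
    cfg <- mf$config
    cfg$embeddingDim <- as.integer(cfg$embeddingDim)
    hist <- file.path(path, "history.csv")
    history <- if (file.exists(hist) && length(readLines(hist)) > 1)
        utils::read.csv(hist) else data.frame()
    new("CPAModel", genes = mf$genes, perturbations = mf$perturbations,
        covariateSchemas = as.list(mf$covariateSchemas),
        latentDim = as.integer(mf$latentDim), params = params,
        advPert = mf$advPert, config = cfg, history = history,
        trained = isTRUE(mf$trained))
}
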