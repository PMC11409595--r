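## Plain-text model serialization: beta.tsv, alpha.tsv, theta.tsv,
## meta.json.

#' Save a TopicModel as plain text
#'
#' Writes `beta.tsv` (K x G, gene ids as columns), `alpha.tsv`,
#' `theta.tsv` (cells x topics) and `meta.json` (K, lambda, seed,
#' tolerances, convergence log) into a directory.
#'
#' @param model a [TopicModel].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
saveTopicModel <- function(model, dir) {
    stopifnot(methods::is(model, "TopicModel"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.table(topicGeneFreq(model), file.path(dir, "beta.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    write.table(data.frame(alpha = dirichletAlpha(model)),
                file.path(dir, "alpha.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(topicProfiles(model), file.path(dir, "theta.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    meta <- list(K = nTopics(model), lambda = penaltyLambda(model),
                 seed = model@seed, converged = isConverged(model),
                 nIter = model@nIter,
                 objectiveTrace = objectiveTrace(model),
                 meta = model@meta)
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
               file.path(dir, "meta.json"))
    invisible(dir)
}

#' Load a TopicModel saved by [saveTopicModel()]
#'
#' @param dir directory holding `beta.tsv`, `alpha.tsv`, `theta.tsv`,
#'   `meta.json`.
#' @return a [TopicModel] (the variational gamma is restored from theta
#'   up to its normalization, so refit if you need gamma itself).
#' @export
loadTopicModel <- function(dir) {
    beta <- as.matrix(read.delim(file.path(dir, "beta.tsv"), row.names = 1L,
                                 check.names = FALSE))
    theta <- as.matrix(read.delim(file.path(dir, "theta.tsv"), row.names = 1L,
                                  check.names = FALSE))
    alpha <- read.delim(file.path(dir, "alpha.tsv"))$alpha
    meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
    new("TopicModel", K = as.integer(meta$K), alpha = as.numeric(alpha),
        lambda = as.numeric(meta$lambda),
        beta = beta / rowSums(beta),
        theta = theta / rowSums(theta),
        gamma = theta,
        objectiveTrace = as.numeric(meta$objectiveTrace),
        converged = isTRUE(meta$converged),
        nIter = as.integer(meta$nIter),
        seed = as.integer(meta$seed),
        meta = as.list(meta$meta))
}

#' Write hierarchical predictions as TSV
#'
#' @param predictions data.frame from [predictHierarchical()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writePredictions <- function(predictions, file) {
    write.table(predictions, file, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(file)
}
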