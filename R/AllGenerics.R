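#' @rdname TopicModel-accessors
#' @export
setGeneric("topicGeneFreq", function(object) standardGeneric("topicGeneFreq"))

#' @rdname TopicModel-accessors
#' @export
setGeneric("topicProfiles", function(object) standardGeneric("topicProfiles"))

#' @rdname TopicModel-accessors
#' @export
setGeneric("nTopics", function(object) standardGeneric("nTopics"))

#' @rdname TopicModel-accessors
#' @export
setGeneric("dirichletAlpha", function(object) standardGeneric("dirichletAlpha"))

#' @rdname TopicModel-accessors
#' @export
setGeneric("penaltyLambda", function(object) standardGeneric("penaltyLambda"))

#' @rdname TopicModel-accessors
#' @export
setGeneric("objectiveTrace", function(object) standardGeneric("objectiveTrace"))

#' @rdname TopicModel-accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' Accessors for TopicModel and SimulationTruth
#'
#' `topicGeneFreq` returns the K x G topic-gene frequency matrix
#' \eqn{\beta}; `topicProfiles` the N x K per-cell topic frequency matrix
#' \eqn{\Theta}; `nTopics` the topic count K; `dirichletAlpha` the
#' Dirichlet prior; `penaltyLambda` the tuning parameter \eqn{\lambda};
#' `objectiveTrace` the penalized objective per EM iteration;
#' `isConverged` the convergence flag.
#'
#' @param object a [TopicModel] or [SimulationTruth].
#' @return the slot value described above.
#' @name TopicModel-accessors
#' @examples
#' sce <- presetScenario("small", seed = 1)
#' truth <- simTruth(sce)
#' nrow(topicGeneFreq(truth))
NULL

#' @rdname TopicModel-accessors
#' @export
setMethod("topicGeneFreq", "TopicModel", function(object) object@beta)

#' @rdname TopicModel-accessors
#' @export
setMethod("topicGeneFreq", "SimulationTruth", function(object) object@betaTrue)

#' @rdname TopicModel-accessors
#' @export
setMethod("topicProfiles", "TopicModel", function(object) object@theta)

#' @rdname TopicModel-accessors
#' @export
setMethod("nTopics", "TopicModel", function(object) object@K)

#' @rdname TopicModel-accessors
#' @export
setMethod("nTopics", "SimulationTruth", function(object) nrow(object@betaTrue))

#' @rdname TopicModel-accessors
#' @export
setMethod("dirichletAlpha", "TopicModel", function(object) object@alpha)

#' @rdname TopicModel-accessors
#' @export
setMethod("penaltyLambda", "TopicModel", function(object) object@lambda)

#' @rdname TopicModel-accessors
#' @export
setMethod("objectiveTrace", "TopicModel", function(object) object@objectiveTrace)

#' @rdname TopicModel-accessors
#' @export
setMethod("isConverged", "TopicModel", function(object) object@converged)

#' @describeIn TopicModel-accessors marker gene indices per topic
#'   (SimulationTruth).
#' @export
setGeneric("markerGenes", function(object) standardGeneric("markerGenes"))

#' @rdname TopicModel-accessors
#' @export
setMethod("markerGenes", "SimulationTruth", function(object) object@markerGenes)

#' @describeIn TopicModel-accessors stop-word gene indices
#'   (SimulationTruth).
#' @export
setGeneric("stopwordGenes", function(object) standardGeneric("stopwordGenes"))

#' @rdname TopicModel-accessors
#' @export
setMethod("stopwordGenes", "SimulationTruth", function(object) object@stopwordGenes)

setMethod("show", "TopicModel", function(object) {
    cat("TopicModel (penalized LDA fit)\n")
    cat("  topics:", object@K, " genes:", ncol(object@beta),
        " cells:", nrow(object@theta), "\n")
    cat("  lambda:", format(object@lambda), " alpha[1]:",
        format(object@alpha[1L]), "\n")
    cat("  EM iterations:", object@nIter,
        if (object@converged) "(converged)" else "(NOT converged)", "\n")
    if (length(object@objectiveTrace))
        cat("  final penalized objective:",
            format(tail(object@objectiveTrace, 1L), digits = 8), "\n")
})

setMethod("show", "SimulationTruth", function(object) {
    cat("SimulationTruth\n")
    cat("  topics:", nrow(object@betaTrue), " genes:", ncol(object@betaTrue), "\n")
    cat("  cell types:", paste(names(object@archetypes), collapse = ", "), "\n")
    cat("  stop-word genes:", length(object@stopwordGenes),
        " age shift:", object@ageEffect$shift, "\n")
})

setMethod("show", "CellTypeAgeClassifier", function(object) {
    cat("CellTypeAgeClassifier\n")
    cat("  feature transform:", object@featureTransform, "\n")
    cat("  cell types:", paste(object@classLevels, collapse = ", "), "\n")
    fallback <- setdiff(object@classLevels, names(object@ageModels))
    cat("  age models:", length(object@ageModels),
        if (length(fallback)) paste0("(majority fallback: ",
            paste(fallback, collapse = ", "), ")") else "", "\n")
})

#' @importFrom utils tail
NULL
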