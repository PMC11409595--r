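#' TopicModel: a fitted (penalized) LDA model
#'
#' Holds the topic-gene frequency matrix \eqn{\beta} (K x G, rows are
#' simplices), the per-cell topic profiles \eqn{\Theta} (N x K, rows are
#' simplices), the variational Dirichlet parameters \eqn{\gamma}, the
#' penalized-objective trace and convergence bookkeeping.
#'
#' @slot K number of topics.
#' @slot alpha Dirichlet prior parameter, length-K positive vector.
#' @slot lambda penalty tuning parameter \eqn{\lambda}.
#' @slot beta K x G matrix; row k is the gene frequency simplex of topic k.
#'   Columns are named by gene identifier.
#' @slot theta N x K matrix of per-cell topic frequencies (gamma, row
#'   normalized); rows named by cell identifier.
#' @slot gamma N x K matrix of variational Dirichlet parameters.
#' @slot objectiveTrace penalized objective value after each EM iteration.
#' @slot converged logical; did the relative objective change fall below
#'   the tolerance within the iteration budget.
#' @slot nIter number of EM iterations performed.
#' @slot seed integer seed the fit was started from.
#' @slot meta list of tolerances and other fit metadata.
#'
#' @aliases TopicModel
#' @exportClass TopicModel
setClass("TopicModel",
    representation(
        K = "integer",
        alpha = "numeric",
        lambda = "numeric",
        beta = "matrix",
        theta = "matrix",
        gamma = "matrix",
        objectiveTrace = "numeric",
        converged = "logical",
        nIter = "integer",
        seed = "integer",
        meta = "list"
    )
)

.rowSimplexOK <- function(m, tol = 1e-10) {
    nrow(m) == 0L || (all(m >= -tol) && all(abs(rowSums(m) - 1) <= tol * ncol(m) + tol))
}

setValidity("TopicModel", function(object) {
    msg <- character()
    if (object@K < 1L) msg <- c(msg, "K must be >= 1")
    if (length(object@alpha) != object@K || any(object@alpha <= 0))
        msg <- c(msg, "alpha must be a positive vector of length K")
    if (nrow(object@beta) != object@K)
        msg <- c(msg, "beta must have K rows")
    if (!.rowSimplexOK(object@beta))
        msg <- c(msg, "beta rows must be simplices (sum to 1 within 1e-10)")
    if (ncol(object@theta) != object@K)
        msg <- c(msg, "theta must have K columns")
    if (!.rowSimplexOK(object@theta))
        msg <- c(msg, "theta rows must be simplices (sum to 1 within 1e-10)")
    if (length(msg)) msg else TRUE
})

#' SimulationTruth: ground truth behind a simulated corpus
#'
#' Records everything the simulator planted: the true topic-gene matrix,
#' the per-(type, age) topic-mixture archetypes, marker and stop-word
#' gene positions and the age-effect specification, so recovery can be
#' scored downstream.
#'
#' @slot betaTrue K x G row-stochastic matrix used to generate counts.
#' @slot archetypes list keyed by cell type; each element a list with
#'   `young` and `old` K-simplex means.
#' @slot precision Dirichlet precision of the per-cell topic draw.
#' @slot markerGenes list keyed by topic of marker gene indices.
#' @slot stopwordGenes integer indices of planted stop-word genes.
#' @slot ageEffect list with `reducedTopic`, `boostedTopic` (named by
#'   type) and `shift`.
#'
#' @aliases SimulationTruth
#' @exportClass SimulationTruth
setClass("SimulationTruth",
    representation(
        betaTrue = "matrix",
        archetypes = "list",
        precision = "numeric",
        markerGenes = "list",
        stopwordGenes = "integer",
        ageEffect = "list"
    )
)

setValidity("SimulationTruth", function(object) {
    msg <- character()
    b <- object@betaTrue
    if (any(abs(rowSums(b) - 1) > 1e-12 * ncol(b)))
        msg <- c(msg, "betaTrue rows must sum to 1 within 1e-12")
    if (any(b < 0)) msg <- c(msg, "betaTrue must be nonnegative")
    sw <- object@stopwordGenes
    if (length(sw) && nrow(b) > 1L) {
        cols <- b[, sw, drop = FALSE]
        if (any(abs(sweep(cols, 2L, cols[1L, ], "-")) > 0))
            msg <- c(msg, "stop-word columns of betaTrue must be identical across topics")
    }
    for (a in object@archetypes) {
        for (v in a) {
            if (abs(sum(v) - 1) > 1e-12 * length(v) || any(v < 0))
                msg <- c(msg, "archetypes must be simplices")
        }
    }
    if (length(msg)) unique(msg) else TRUE
})

#' CellTypeAgeClassifier: hierarchical type-then-age classifier
#'
#' Bundles one multiclass SVM over cell types with one binary age SVM per
#' cell type, all trained on square-root transformed topic profiles.
#' Types for which only one age group was seen in training carry a
#' majority-age fallback instead of a model.
#'
#' @slot featureTransform name of the feature map applied to topic
#'   profiles before the SVMs (currently `"sqrt"`).
#' @slot cellTypeModel fitted multiclass SVM.
#' @slot ageModels list keyed by cell type of binary age SVMs; types
#'   without a model fall back to `majorityAge`.
#' @slot majorityAge named character vector, training majority age per type.
#' @slot classLevels cell type levels seen in training.
#' @slot ageLevels age levels (young/old) seen in training.
#' @slot meta list: seeds, hyperparameters, per-type training counts,
#'   training accuracy.
#'
#' @aliases CellTypeAgeClassifier
#' @exportClass CellTypeAgeClassifier
setClass("CellTypeAgeClassifier",
    representation(
        featureTransform = "character",
        cellTypeModel = "ANY",
        ageModels = "list",
        majorityAge = "character",
        classLevels = "character",
        ageLevels = "character",
        meta = "list"
    )
)

setValidity("CellTypeAgeClassifier", function(object) {
    msg <- character()
    extra <- setdiff(names(object@ageModels), object@classLevels)
    if (length(extra))
        msg <- c(msg, paste("age models for unseen types:", paste(extra, collapse = ", ")))
    if (!all(object@classLevels %in% names(object@majorityAge)))
        msg <- c(msg, "every training type needs a majority age")
    if (length(msg)) msg else TRUE
})
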