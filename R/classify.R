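## Hierarchical classification: sqrt-transformed topic profiles into one
## multiclass cell-type SVM, then one binary age SVM per cell type.

#' Square-root transform of topic profiles
#'
#' Maps each K-simplex row of \eqn{\Theta} onto the nonnegative unit
#' sphere by the elementwise square root.  The transform upweights less
#' abundant topics more gently than a logit would, and every output row
#' has Euclidean norm exactly 1 (since \eqn{\sum_k (\sqrt{\theta_k})^2
#' = 1}).
#'
#' @param theta N x K matrix with simplex rows.
#' @return N x K matrix of square roots.
#' @examples
#' sqrtFeatures(rbind(c(0.25, 0.75)))
#' @export
sqrtFeatures <- function(theta) {
    theta <- as.matrix(theta)
    if (any(theta < 0)) stop("topic profiles must be nonnegative")
    if (any(abs(rowSums(theta) - 1) > 1e-6))
        stop("topic profile rows must sum to 1")
    sqrt(theta)
}

## median-heuristic RBF width: 1 / median squared pairwise distance,
## computed on a deterministic subsample for large inputs
.medianGamma <- function(x, cap = 1000L) {
    n <- nrow(x)
    if (n > cap) x <- x[round(seq(1L, n, length.out = cap)), , drop = FALSE]
    d2 <- as.numeric(dist(x))^2
    m <- median(d2[d2 > 0])
    if (!is.finite(m) || m <= 0) 1 else 1 / m
}

.svmDefaults <- function(hyper, x) {
    h <- list(kernel = "radial", cost = 1, gamma = NULL, classWeights = NULL)
    h[names(hyper)] <- hyper
    if (is.null(h$gamma)) h$gamma <- .medianGamma(x)
    h
}

#' Train the multiclass cell-type SVM
#'
#' Radial-basis SVM (cost 1, kernel width from the median heuristic
#' unless overridden) on square-root topic features.
#'
#' @param features N x K numeric matrix (use [sqrtFeatures()]).
#' @param majorTypes length-N cell type labels; at least two classes.
#' @param hyper list overriding `kernel`, `cost`, `gamma`,
#'   `classWeights`.
#' @param seed integer seed (SVM training is deterministic, but the seed
#'   is set and recorded for protocol uniformity).
#' @return a fitted `e1071::svm` with the training accuracy in
#'   `attr(, "trainAccuracy")`.
#' @export
trainCellTypeSVM <- function(features, majorTypes, hyper = list(), seed = 1L) {
    features <- as.matrix(features)
    if (any(!is.finite(features))) stop("features must be finite")
    y <- factor(majorTypes)
    if (nlevels(y) < 2L)
        stop("single-class input; use a constant predictor instead of an SVM")
    h <- .svmDefaults(hyper, features)
    set.seed(seed)
    fit <- e1071::svm(features, y, kernel = h$kernel, cost = h$cost,
                      gamma = h$gamma, class.weights = h$classWeights,
                      scale = FALSE)
    attr(fit, "trainAccuracy") <- mean(predict(fit, features) == y)
    fit
}

#' Train one binary age SVM per cell type
#'
#' Cell types with both ages in training get a binary SVM; types where
#' one age is missing (e.g. a type detected almost exclusively in old
#' animals) are skipped with a warning and fall back to majority-age
#' prediction.
#'
#' @inheritParams trainCellTypeSVM
#' @param ages length-N age labels (`young`/`old`).
#' @return list with `models` (per-type SVMs), `majorityAge` (named
#'   character, every type) and `skipped` (types without a model).
#' @export
trainAgeSVMs <- function(features, majorTypes, ages, hyper = list(), seed = 1L) {
    features <- as.matrix(features)
    ty <- as.character(majorTypes)
    ages <- factor(ages)
    models <- list()
    majority <- character()
    skipped <- character()
    for (t in unique(ty)) {
        idx <- ty == t
        yt <- droplevels(ages[idx])
        tab <- table(yt)
        majority[t] <- names(tab)[which.max(tab)]
        if (nlevels(yt) < 2L) {
            skipped <- c(skipped, t)
            next
        }
        h <- .svmDefaults(hyper, features[idx, , drop = FALSE])
        set.seed(seed)
        models[[t]] <- e1071::svm(features[idx, , drop = FALSE], yt,
                                  kernel = h$kernel, cost = h$cost,
                                  gamma = h$gamma,
                                  class.weights = h$classWeights,
                                  scale = FALSE)
    }
    if (length(skipped))
        warning("only one age present for type(s) ",
                paste(skipped, collapse = ", "),
                "; falling back to majority-age prediction")
    list(models = models, majorityAge = majority, skipped = skipped)
}

#' Train the full hierarchical type-then-age classifier
#'
#' Square-root transforms the topic profiles, fits the multiclass
#' cell-type SVM and the per-type age SVMs, and bundles them.
#'
#' @param theta N x K topic profiles (simplex rows).
#' @param majorTypes,ages length-N labels.
#' @param hyper,seed passed to the SVM trainers.
#' @return a [CellTypeAgeClassifier].
#' @examples
#' sce <- presetScenario("small", seed = 1)
#' fit <- fitPLDA(sce[, 1:100], K = 6, seed = 1, maxIter = 10)
#' cls <- trainClassifier(topicProfiles(fit), sce$major_type[1:100],
#'                        sce$age[1:100], seed = 1)
#' @export
trainClassifier <- function(theta, majorTypes, ages, hyper = list(),
                            seed = 1L) {
    feats <- sqrtFeatures(theta)
    typeModel <- trainCellTypeSVM(feats, majorTypes, hyper, seed)
    ageFit <- trainAgeSVMs(feats, majorTypes, ages, hyper, seed)
    new("CellTypeAgeClassifier",
        featureTransform = "sqrt",
        cellTypeModel = typeModel,
        ageModels = ageFit$models,
        majorityAge = ageFit$majorityAge,
        classLevels = levels(factor(majorTypes)),
        ageLevels = levels(factor(ages)),
        meta = list(seed = as.integer(seed), hyper = hyper,
                    typeCounts = table(majorTypes, ages),
                    trainAccuracy = attr(typeModel, "trainAccuracy"),
                    ageSkipped = ageFit$skipped))
}

#' Hierarchical prediction of cell type, then age
#'
#' Predicts each cell's type from the multiclass SVM, then its age from
#' the age model of the *predicted* type (never the true type — truth is
#' not an argument).  Cells predicted as a type without an age model get
#' that type's training majority age.
#'
#' @param theta N x K topic profiles (simplex rows).
#' @param bundle a [CellTypeAgeClassifier].
#' @return data.frame with `cell_id`, `predicted_type`, `predicted_age`.
#' @export
predictHierarchical <- function(theta, bundle) {
    stopifnot(methods::is(bundle, "CellTypeAgeClassifier"))
    feats <- sqrtFeatures(theta)
    predType <- as.character(predict(bundle@cellTypeModel, feats))
    predAge <- character(length(predType))
    for (t in unique(predType)) {
        idx <- predType == t
        if (!t %in% bundle@classLevels)
            stop("predicted type ", t, " unknown to the bundle")
        m <- bundle@ageModels[[t]]
        predAge[idx] <- if (is.null(m)) bundle@majorityAge[[t]]
            else as.character(predict(m, feats[idx, , drop = FALSE]))
    }
    data.frame(cell_id = if (is.null(rownames(feats)))
                   seq_along(predType) else rownames(feats),
               predicted_type = predType, predicted_age = predAge,
               row.names = NULL)
}

#' Age prediction given the correct cell type
#'
#' Oracle-type mode: applies each cell's *true* type's age model, for
#' reporting "given the correct cell type" accuracies alongside the
#' end-to-end hierarchical mode.
#'
#' @param theta N x K topic profiles.
#' @param bundle a [CellTypeAgeClassifier].
#' @param trueTypes length-N true type labels.
#' @return character vector of predicted ages.
#' @export
predictAgeGivenType <- function(theta, bundle, trueTypes) {
    stopifnot(methods::is(bundle, "CellTypeAgeClassifier"))
    feats <- sqrtFeatures(theta)
    trueTypes <- as.character(trueTypes)
    out <- character(length(trueTypes))
    for (t in unique(trueTypes)) {
        idx <- trueTypes == t
        m <- bundle@ageModels[[t]]
        out[idx] <- if (is.null(m)) {
            if (t %in% names(bundle@majorityAge)) bundle@majorityAge[[t]]
            else NA_character_
        } else as.character(predict(m, feats[idx, , drop = FALSE]))
    }
    out
}

#' Marker-gene expression baseline classifier
#'
#' The comparison baseline: an SVM on `log1p`-scaled counts of a
#' supplied marker-gene list, under the same protocol (kernel, cost,
#' median-heuristic width) as the topic-feature SVMs.
#'
#' @param x SingleCellExperiment or genes x cells count matrix
#'   (training cells).
#' @param markerGenes character vector of marker gene identifiers (or a
#'   list of per-type vectors, which is flattened).
#' @param labels length-N training labels (cell type or age).
#' @param hyper,seed as in [trainCellTypeSVM()].
#' @return list of class `markerBaseline` with the fitted SVM and the
#'   gene list; predict with [predictMarkerBaseline()].
#' @export
markerGeneBaseline <- function(x, markerGenes, labels, hyper = list(),
                               seed = 1L) {
    m <- .countsOf(x)
    genes <- unique(unlist(markerGenes))
    if (length(genes) == 0L) stop("empty marker list")
    genes <- intersect(genes, rownames(m))
    if (length(genes) == 0L) stop("no marker genes present in the matrix")
    feats <- t(as.matrix(log1p(m[genes, , drop = FALSE])))
    y <- factor(labels)
    if (nlevels(y) < 2L) stop("single-class input")
    h <- .svmDefaults(hyper, feats)
    set.seed(seed)
    fit <- e1071::svm(feats, y, kernel = h$kernel, cost = h$cost,
                      gamma = h$gamma, class.weights = h$classWeights,
                      scale = FALSE)
    structure(list(model = fit, genes = genes), class = "markerBaseline")
}

#' Predict from a marker-gene baseline
#'
#' @param object a [markerGeneBaseline()] fit.
#' @param x SingleCellExperiment or genes x cells count matrix.
#' @return character vector of predicted labels.
#' @export
predictMarkerBaseline <- function(object, x) {
    m <- .countsOf(x)
    feats <- t(as.matrix(log1p(m[object$genes, , drop = FALSE])))
    as.character(predict(object$model, feats))
}
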