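## Reporting artifacts: confusion matrices, recall by age, hierarchical
## 2x2-block confusion, learning curves.

#' Confusion matrix with accuracy and per-class recall
#'
#' @param pred,truth equal-length label vectors over a shared label set.
#' @return list with `labels` (classes present in the truth or
#'   predictions), `matrix` (true x predicted integer counts),
#'   `overall_accuracy` and `per_class_recall` (named; classes with no
#'   test cells are absent rather than zero-divided).
#' @examples
#' confusionCounts(c("a", "a", "b"), c("a", "b", "b"))
#' @export
confusionCounts <- function(pred, truth) {
    if (length(pred) != length(truth)) stop("length mismatch")
    labels <- sort(unique(c(as.character(truth), as.character(pred))))
    m <- table(factor(truth, labels), factor(pred, labels))
    m <- matrix(as.integer(m), nrow(m), dimnames = list(labels, labels))
    present <- rownames(m)[rowSums(m) > 0]
    recall <- setNames(diag(m)[present] / rowSums(m)[present], present)
    list(labels = labels, matrix = m,
         overall_accuracy = sum(diag(m)) / length(truth),
         per_class_recall = recall)
}

#' Per-type recall within age strata
#'
#' Recall of the type prediction computed separately among young and old
#' test cells.  Strata with fewer than `minCells` cells are reported as
#' `NA` (a single detected cell says nothing about recall).
#'
#' @param predType,truthType,age equal-length vectors.
#' @param minCells minimum stratum size to report a recall.
#' @return numeric matrix, types x ages.
#' @export
recallByAge <- function(predType, truthType, age, minCells = 2L) {
    stopifnot(length(predType) == length(truthType),
              length(age) == length(truthType))
    types <- sort(unique(as.character(truthType)))
    ages <- unique(as.character(age))
    ages <- c(intersect(c("young", "old"), ages), setdiff(ages, c("young", "old")))
    out <- matrix(NA_real_, length(types), length(ages),
                  dimnames = list(types, ages))
    for (t in types) for (a in ages) {
        idx <- truthType == t & age == a
        if (sum(idx) >= minCells)
            out[t, a] <- mean(predType[idx] == t)
    }
    out
}

#' Hierarchical confusion: 2x2 age blocks per (true type, predicted type)
#'
#' A 4-way count array whose (trueType, predType) blocks each hold a
#' trueAge x predAge 2x2 table and sum exactly to the corresponding cell
#' of the type-level confusion matrix.
#'
#' @param predType,predAge,truthType,truthAge equal-length vectors.
#' @return list with `blocks` (4-d array: true type, predicted type,
#'   true age, predicted age) and `typeMatrix` (the marginal type
#'   confusion, identical to `confusionCounts(predType, truthType)$matrix`).
#' @export
hierarchicalConfusion <- function(predType, predAge, truthType, truthAge) {
    n <- length(truthType)
    stopifnot(length(predType) == n, length(predAge) == n,
              length(truthAge) == n)
    types <- sort(unique(c(as.character(truthType), as.character(predType))))
    ages <- sort(unique(c(as.character(truthAge), as.character(predAge))))
    blocks <- table(factor(truthType, types), factor(predType, types),
                    factor(truthAge, ages), factor(predAge, ages))
    blocks <- array(as.integer(blocks), dim = dim(blocks),
                    dimnames = list(types, types, ages, ages))
    typeMatrix <- apply(blocks, c(1L, 2L), sum)
    dimnames(typeMatrix) <- list(types, types)
    stopifnot(identical(sum(blocks), n))
    list(blocks = blocks, typeMatrix = typeMatrix)
}

## stratified subsample of training ids by (type, age), at least 1 per
## nonempty stratum
.subsampleStratified <- function(ann, size) {
    strata <- split(ann$cell_id, paste(ann$major_type, ann$age))
    total <- nrow(ann)
    ids <- unlist(lapply(strata, function(s) {
        k <- max(1L, round(size * length(s) / total))
        sample(s, min(k, length(s)))
    }))
    unname(ids)
}

#' Learning curve: age-prediction accuracy vs training-set size
#'
#' For each method, training size and replicate: subsample the training
#' cells (stratified by type and age), fit the topic model on the
#' subsample (`pLDA` at the supplied `lambda`, `LDA` at `lambda = 0`),
#' fold in the test cells, train per-type age SVMs on the subsample and
#' record the held-out age accuracy given the true type.  The `markers`
#' method trains per-type SVMs on log1p marker-gene counts under the
#' same subsamples.  Replicate seeds are derived deterministically from
#' `seed`.
#'
#' @param sce a SingleCellExperiment with `major_type` and `age`
#'   colData (e.g. from [presetScenario()]).
#' @param split a [stratifiedSplit()] result.
#' @param methods subset of `c("pLDA", "LDA", "markers")`.
#' @param trainSizes training-set sizes (cells) to evaluate.
#' @param nReplicates replicates per size.
#' @param K,lambda topic-model settings (`lambda` applies to `pLDA`).
#' @param markerGenes marker gene ids for the `markers` method.
#' @param seed master seed.
#' @param maxIter EM iteration cap per fit.
#' @return data.frame with columns `method`, `train_size`, `replicate`,
#'   `seed`, `accuracy`.
#' @export
learningCurve <- function(sce, split, methods = c("pLDA", "LDA", "markers"),
                          trainSizes, nReplicates = 1L, K, lambda = 0,
                          markerGenes = NULL, seed = 1L, maxIter = 50L) {
    methods <- match.arg(methods, several.ok = TRUE)
    ann <- .annOf(sce)
    annTrain <- ann[ann$cell_id %in% split$train, ]
    if (any(trainSizes > nrow(annTrain)))
        stop("train size exceeds available training cells")
    testIds <- split$test
    counts <- .countsOf(sce)

    rows <- list()
    for (size in trainSizes) {
        for (rep in seq_len(nReplicates)) {
            repSeed <- as.integer((seed * 1000L + size + rep * 7L) %% .Machine$integer.max)
            set.seed(repSeed)
            ids <- .subsampleStratified(annTrain, size)
            aTr <- annTrain[match(ids, annTrain$cell_id), ]
            ## guard: age SVMs need both ages somewhere
            if (length(unique(aTr$age)) < 2L)
                stop("train size too small to keep both ages")
            mTr <- counts[, ids, drop = FALSE]
            mTr <- filterGenesMinCount(mTr, 1L)
            mTe <- counts[rownames(mTr), testIds, drop = FALSE]
            aTe <- ann[match(testIds, ann$cell_id), ]

            for (method in methods) {
                acc <- if (method %in% c("pLDA", "LDA")) {
                    lam <- if (method == "pLDA") lambda else 0
                    fit <- fitPLDA(mTr, K = K, lambda = lam, seed = repSeed,
                                   maxIter = maxIter)
                    feats <- sqrtFeatures(topicProfiles(fit))
                    ageFit <- trainAgeSVMs(feats, aTr$major_type, aTr$age,
                                           seed = repSeed)
                    thTe <- inferProfiles(mTe, fit)
                    bundle <- new("CellTypeAgeClassifier",
                                  featureTransform = "sqrt",
                                  cellTypeModel = NULL,
                                  ageModels = ageFit$models,
                                  majorityAge = ageFit$majorityAge,
                                  classLevels = unique(aTr$major_type),
                                  ageLevels = unique(aTr$age),
                                  meta = list())
                    predAge <- predictAgeGivenType(thTe, bundle, aTe$major_type)
                    mean(predAge == aTe$age, na.rm = TRUE)
                } else {
                    if (is.null(markerGenes)) stop("markers method needs markerGenes")
                    preds <- rep(NA_character_, nrow(aTe))
                    for (t in unique(aTr$major_type)) {
                        trIdx <- aTr$major_type == t
                        teIdx <- aTe$major_type == t
                        if (!any(teIdx)) next
                        if (length(unique(aTr$age[trIdx])) < 2L) {
                            preds[teIdx] <- names(which.max(table(aTr$age[trIdx])))
                            next
                        }
                        bl <- markerGeneBaseline(mTr[, trIdx, drop = FALSE],
                                                 markerGenes,
                                                 aTr$age[trIdx], seed = repSeed)
                        preds[teIdx] <- predictMarkerBaseline(
                            bl, mTe[, teIdx, drop = FALSE])
                    }
                    mean(preds == aTe$age, na.rm = TRUE)
                }
                rows[[length(rows) + 1L]] <-
                    data.frame(method = method, train_size = size,
                               replicate = rep, seed = repSeed,
                               accuracy = acc)
            }
        }
    }
    do.call(rbind, rows)
}
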