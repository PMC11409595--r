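test_that("sqrt features map the simplex onto the unit sphere", {
    expect_equal(sqrtFeatures(rbind(c(0.25, 0.75))),
                 rbind(c(0.5, sqrt(0.75))))
    expect_equal(sqrtFeatures(rbind(c(1, 0))), rbind(c(1, 0)))

    set.seed(2)
    th <- matrix(rgamma(50 * 4, 1), 50); th <- th / rowSums(th)
    f <- sqrtFeatures(th)
    expect_true(all(abs(sqrt(rowSums(f^2)) - 1) < 1e-10))

    expect_error(sqrtFeatures(rbind(c(-0.1, 1.1))), "nonnegative")
    expect_error(sqrtFeatures(rbind(c(0.2, 0.2))), "sum to 1")
})

## two well-separated simplex clusters for classifier tests
.clusters <- function(n, seed, sep = 12) {
    set.seed(seed)
    a <- pldaCells:::.rdirichlet(n, c(sep, 1, 1))
    b <- pldaCells:::.rdirichlet(n, c(1, sep, 1))
    list(theta = rbind(a, b),
         labels = rep(c("A", "B"), each = n))
}

test_that("cell-type SVM separates separable clusters and is honest at chance", {
    cl <- .clusters(60, seed = 3)
    feats <- sqrtFeatures(cl$theta)
    idx <- seq(1, 120, by = 2)      # interleaved split
    fit <- trainCellTypeSVM(feats[idx, ], cl$labels[idx], seed = 1)
    acc <- mean(predict(fit, feats[-idx, ]) == cl$labels[-idx])
    expect_equal(acc, 1.0)

    ## permuted labels give near-chance accuracy (3 SE band)
    set.seed(4)
    perm <- sample(cl$labels[idx])
    fitP <- trainCellTypeSVM(feats[idx, ], perm, seed = 1)
    accP <- mean(predict(fitP, feats[-idx, ]) == cl$labels[-idx])
    se <- sqrt(0.25 / 60)
    expect_lt(abs(accP - 0.5), 3 * se)

    ## duplicating every training point leaves decisions unchanged
    fitD <- trainCellTypeSVM(feats[c(idx, idx), ], cl$labels[c(idx, idx)],
                             hyper = list(gamma = 1), seed = 1)
    fit1 <- trainCellTypeSVM(feats[idx, ], cl$labels[idx],
                             hyper = list(gamma = 1), seed = 1)
    expect_equal(as.character(predict(fitD, feats[-idx, ])),
                 as.character(predict(fit1, feats[-idx, ])))

    expect_error(trainCellTypeSVM(feats, rep("A", 120)), "single-class")
})

test_that("age SVMs detect a planted shift and stay at chance without one", {
    K <- 5
    young <- c(0.6, 0.1, 0.1, 0.1, 0.1)
    shift <- 0.3
    old <- young
    old[1] <- young[1] * (1 - shift)
    old[2] <- young[2] + young[1] * shift
    set.seed(11)
    n <- 500
    th <- rbind(pldaCells:::.rdirichlet(n, 50 * young),
                pldaCells:::.rdirichlet(n, 50 * old))
    ages <- rep(c("young", "old"), each = n)
    types <- rep("T", 2 * n)
    idx <- seq(1, 2 * n, by = 2)

    fit <- trainAgeSVMs(sqrtFeatures(th[idx, ]), types[idx], ages[idx], seed = 1)
    pred <- as.character(predict(fit$models[["T"]], sqrtFeatures(th[-idx, ])))
    expect_gte(mean(pred == ages[-idx]), 0.75)

    ## no shift: held-out accuracy within 3 SE of coin flipping
    th0 <- rbind(pldaCells:::.rdirichlet(n, 50 * young),
                 pldaCells:::.rdirichlet(n, 50 * young))
    fit0 <- trainAgeSVMs(sqrtFeatures(th0[idx, ]), types[idx], ages[idx], seed = 1)
    pred0 <- as.character(predict(fit0$models[["T"]], sqrtFeatures(th0[-idx, ])))
    expect_lt(abs(mean(pred0 == ages[-idx]) - 0.5), 3 * sqrt(0.25 / n))

    ## a type observed at one age only is skipped with a majority fallback
    expect_warning(
        f1 <- trainAgeSVMs(sqrtFeatures(th[1:20, ]), rep("MK", 20),
                           rep("old", 20), seed = 1),
        "majority")
    expect_equal(f1$majorityAge[["MK"]], "old")
    expect_null(f1$models[["MK"]])
})

test_that("hierarchical prediction uses the predicted type's age model", {
    cl <- .clusters(80, seed = 5)
    ## ages differ along topic 3 within each cluster
    set.seed(6)
    bump <- rep(rep(c(0, 0.25), each = 40), 2)
    th <- cl$theta * (1 - bump) + outer(bump, c(0, 0, 1))
    ages <- rep(rep(c("young", "old"), each = 40), 2)
    bundle <- trainClassifier(th, cl$labels, ages, seed = 1)
    expect_s4_class(bundle, "CellTypeAgeClassifier")

    pred <- predictHierarchical(th, bundle)
    expect_named(pred, c("cell_id", "predicted_type", "predicted_age"))

    ## the age call must equal what the predicted type's own model says
    feats <- sqrtFeatures(th)
    for (t in unique(pred$predicted_type)) {
        i <- pred$predicted_type == t
        manual <- as.character(predict(bundle@ageModels[[t]],
                                       feats[i, , drop = FALSE]))
        expect_equal(pred$predicted_age[i], manual)
    }

    ## oracle-type mode agrees with per-type manual application
    given <- predictAgeGivenType(th, bundle, cl$labels)
    for (t in c("A", "B")) {
        i <- cl$labels == t
        manual <- as.character(predict(bundle@ageModels[[t]],
                                       feats[i, , drop = FALSE]))
        expect_equal(given[i], manual)
    }
})

test_that("single-type bundles degrade to that type and its majority age", {
    th <- pldaCells:::.rdirichlet(30, c(5, 1, 1))
    bundle <- new("CellTypeAgeClassifier", featureTransform = "sqrt",
                  cellTypeModel = NULL, ageModels = list(),
                  majorityAge = c(T1 = "old"), classLevels = "T1",
                  ageLevels = c("old", "young"), meta = list())
    ## with no multiclass model we exercise the age fallback directly
    pred <- predictAgeGivenType(th, bundle, rep("T1", 30))
    expect_equal(unique(pred), "old")
})

test_that("marker baseline follows the shared protocol and checks inputs", {
    sce0 <- presetScenario("small", seed = 2)
    idx <- seq(1, ncol(sce0), by = 7)          # deterministic mixed-type subset
    sce <- sce0[, idx]
    m <- SummarizedExperiment::assay(sce, "counts")
    truth <- simTruth(sce)
    markers <- colnames(topicGeneFreq(truth))[unlist(markerGenes(truth)[1:2])]

    ntr <- 150L
    bl <- markerGeneBaseline(m[, 1:ntr], markers, sce$major_type[1:ntr], seed = 1)
    pred <- predictMarkerBaseline(bl, m[, (ntr + 1):ncol(m)])
    expect_length(pred, ncol(m) - ntr)

    expect_error(markerGeneBaseline(m, character(), sce$major_type), "empty")
    expect_error(markerGeneBaseline(m, c("nope1", "nope2"), sce$major_type),
                 "no marker genes")
})
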