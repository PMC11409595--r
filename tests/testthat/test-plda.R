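test_that("penalty term matches an independent scalar loop", {
    b <- rbind(c(0.8, 0.2), c(0.2, 0.8))
    expect_equal(penaltyTerm(b), 0.36)
    expect_equal(penaltyTerm(b), ref_penalty(b))

    ## homogeneous rows and K = 1 give zero
    expect_equal(penaltyTerm(rbind(c(0.3, 0.7), c(0.3, 0.7))), 0)
    expect_equal(penaltyTerm(matrix(c(0.5, 0.5), 1)), 0)

    ## random matrices agree with the loop oracle
    set.seed(1)
    for (i in 1:5) {
        m <- matrix(rgamma(4 * 7, 1), 4)
        m <- m / rowSums(m)
        expect_equal(penaltyTerm(m), ref_penalty(m))
    }
})

test_that("penalized objective is elbo minus lambda times the penalty", {
    b <- rbind(c(0.8, 0.2), c(0.2, 0.8))
    expect_equal(penalizedObjective(-100, b, 0), -100)
    expect_equal(penalizedObjective(-100, b, 1), -100.36)
    expect_equal(penalizedObjective(-100, rbind(c(0.5, 0.5), c(0.5, 0.5)), 50),
                 -100)
    expect_error(penalizedObjective(NaN, b, 1), "non-finite")
    expect_error(penalizedObjective(-1, b, -2), "allowSignedLambda")
    expect_equal(penalizedObjective(-100, b, -1, allowSignedLambda = TRUE),
                 -99.64)
})

test_that("single-cell E-step hits the independent fixed-point oracle", {
    ## K = 2, one expressed gene
    beta <- rbind(c(0.7, 0.3), c(0.2, 0.8))
    alpha <- c(0.4, 0.6)
    counts <- c(0, 7)
    es <- eStepCell(counts, beta, alpha, tol = 1e-10, maxInner = 5000)
    ref <- ref_estep_cell(counts, beta, alpha, tol = 1e-10)
    expect_equal(es$gamma, ref$gamma, tolerance = 1e-8)

    ## denser cell
    counts2 <- c(4, 9)
    es2 <- eStepCell(counts2, beta, alpha, tol = 1e-12, maxInner = 10000)
    ref2 <- ref_estep_cell(counts2, beta, alpha, tol = 1e-12)
    expect_equal(es2$gamma, ref2$gamma, tolerance = 1e-8)

    ## K = 1 closed form: gamma = alpha + total, phi degenerate
    es1 <- eStepCell(c(3, 4), matrix(c(0.6, 0.4), 1), alpha = 2)
    expect_equal(es1$gamma, 2 + 7)
    expect_equal(es1$theta, 1)

    ## all-zero cell: posterior equals the prior, theta uniform
    es0 <- eStepCell(c(0, 0), beta, c(0.5, 0.5))
    expect_equal(es0$gamma, c(0.5, 0.5))
    expect_equal(es0$theta, c(0.5, 0.5))
})

test_that("penalized M-step matches the dense grid-search oracle", {
    counts <- rbind(c(8, 2), c(5, 5))
    for (lam in c(0, 0.5, 1)) {
        got <- mStepPenalized(counts, lam)
        oracle <- ref_mstep_grid(counts, lam)
        expect_lt(max(abs(got - oracle)), 2e-3)
        expect_equal(rowSums(got), c(1, 1))
    }

    ## unpenalized closed form
    expect_equal(mStepPenalized(counts, 0), counts / rowSums(counts))

    ## symmetric expected counts give identical rows for any lambda
    sym <- rbind(c(3, 7), c(3, 7))
    for (lam in c(0, 10, 1e4))
        expect_equal(mStepPenalized(sym, lam)[1, ], mStepPenalized(sym, lam)[2, ])

    expect_error(mStepPenalized(rbind(c(1, 1), c(0, 0)), 1), "degenerate")
})

test_that("lambda = 0 fit reproduces an independent reference LDA", {
    Y <- rand_counts(G = 30, N = 12, seed = 21)
    K <- 2
    alpha <- rep(0.5, K)
    binit <- pldaCells:::.initBeta(K, nrow(Y), seed = 3)
    fit <- fitPLDA(Y, K = K, lambda = 0, alpha = alpha, betaInit = binit,
                   tol = 1e-9, maxIter = 400, innerTol = 1e-10,
                   finalInnerTol = 1e-10, maxInner = 5000)
    ref <- ref_lda_fit(Y, K, alpha, binit)
    expect_lt(max(abs(topicGeneFreq(fit) - ref$beta)), 1e-3)
    thRef <- ref$gamma / rowSums(ref$gamma)
    expect_lt(max(abs(unname(topicProfiles(fit)) - thRef)), 1e-3)
})

test_that("fit invariants: simplices, monotone objective, determinism", {
    Y <- rand_counts(G = 40, N = 25, seed = 31)
    f1 <- fitPLDA(Y, K = 3, lambda = 50, seed = 5, maxIter = 40)
    f2 <- fitPLDA(Y, K = 3, lambda = 50, seed = 5, maxIter = 40)
    expect_identical(topicGeneFreq(f1), topicGeneFreq(f2))
    expect_identical(topicProfiles(f1), topicProfiles(f2))

    expect_true(all(abs(rowSums(topicGeneFreq(f1)) - 1) < 1e-10))
    expect_true(all(abs(rowSums(topicProfiles(f1)) - 1) < 1e-10))
    expect_true(all(diff(objectiveTrace(f1)) >= -1e-8))

    ## K = 1 degenerate fit: beta is the pooled gene frequencies
    fk1 <- fitPLDA(Y, K = 1, seed = 1, maxIter = 10)
    expect_equal(drop(topicGeneFreq(fk1)), rowSums(Y) / sum(Y),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(unname(drop(topicProfiles(fk1))), rep(1, ncol(Y)))

    expect_error(fitPLDA(rbind(Y, zero = 0), K = 2, seed = 1), "zero-count")
    expect_error(fitPLDA(Y, K = 2, lambda = -1, seed = 1), "allowSignedLambda")
})

test_that("fold-in reproduces training profiles and respects vocabulary", {
    Y <- rand_counts(G = 40, N = 20, seed = 41)
    fit <- fitPLDA(Y, K = 3, lambda = 10, seed = 2, maxIter = 80)
    th <- inferProfiles(Y, fit)
    expect_equal(unname(th), unname(topicProfiles(fit)), tolerance = 1e-6,
                 ignore_attr = TRUE)

    ## missing genes are dropped with a warning; disjoint genes error
    Ysub <- Y[1:30, ]
    Yren <- Y; rownames(Yren)[31:40] <- paste0("novel", 1:10)
    expect_warning(inferProfiles(Yren, fit), "absent")
    rownames(Yren) <- paste0("x", 1:40)
    expect_error(inferProfiles(Yren, fit), "no overlap")

    ## K = 1 model: every profile is the point mass
    fk1 <- fitPLDA(Y, K = 1, seed = 1, maxIter = 5)
    expect_equal(unname(drop(inferProfiles(Y, fk1))), rep(1, ncol(Y)),
                 ignore_attr = TRUE)
})

test_that("a cell made of one topic's markers folds in onto that topic", {
    ## separable beta: topic 2's markers are (almost) exclusive to it
    tp <- makeTopics(K = 3, G = 60, markersPerTopic = 8, nStopwords = 0,
                     markerStrength = 200, seed = 7)
    model <- new("TopicModel", K = 3L, alpha = rep(1 / 3, 3),
                 lambda = 0, beta = tp$beta,
                 theta = matrix(1 / 3, 1, 3), gamma = matrix(1, 1, 3),
                 objectiveTrace = numeric(), converged = TRUE, nIter = 0L,
                 seed = 1L, meta = list(innerTol = 1e-8, maxInner = 1000))
    y <- numeric(60)
    y[tp$markerGenes[[2]]] <- 25
    m <- matrix(y, dimnames = list(colnames(tp$beta), "cellX"))
    th <- inferProfiles(m, model)
    expect_gte(th[1, 2], 0.9)
})

test_that("topic alignment recovers permutations and matches brute force", {
    set.seed(9)
    b <- matrix(rgamma(4 * 6, 1), 4); b <- b / rowSums(b)

    expect_equal(as.integer(alignTopics(b, b)), 1:4)
    expect_equal(as.integer(alignTopics(b[c(2, 1, 3, 4), ], b)), c(2, 1, 3, 4))

    for (i in 1:5) {
        bh <- matrix(rgamma(4 * 6, 1), 4); bh <- bh / rowSums(bh)
        expect_equal(as.integer(alignTopics(bh, b)), ref_align(bh, b))
    }

    ## Hungarian fallback agrees with exhaustive search on K <= 7
    for (i in 1:10) {
        C <- matrix(rnorm(49), 7)
        perms <- pldaCells:::.allPerms(7)
        scores <- vapply(perms, function(p) sum(C[cbind(1:7, p)]), numeric(1))
        expect_equal(sum(C[cbind(1:7, pldaCells:::.hungarianMax(C))]),
                     max(scores))
    }
})
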