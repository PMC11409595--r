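test_that("cosine distance to uniform behaves like a heterogeneity score", {
    expect_equal(cosineDistanceToUniform(c(2, 2, 2)), 0)
    expect_equal(cosineDistanceToUniform(c(1, 0, 0, 0)), 1 - 1 / sqrt(4))

    ## direct evaluation of the cosine formula on a generic vector
    v <- c(0.1, 0.7, 0.2)
    expect_equal(cosineDistanceToUniform(v),
                 1 - sum(v) / (sqrt(sum(v^2)) * sqrt(3)))

    ## invariance to positive scaling
    expect_lt(abs(cosineDistanceToUniform(7 * v) - cosineDistanceToUniform(v)),
              1e-12)

    expect_error(cosineDistanceToUniform(c(0, 0)), "zero")
    expect_error(cosineDistanceToUniform(c(-1, 2)), "nonnegative")
})

test_that("heterogeneity filter keeps exclusive markers and drops stop words", {
    ## strongly exclusive markers are needed to clear 0.6: the distance of
    ## any K-vector is bounded by 1 - 1/sqrt(K)
    tp <- makeTopics(K = 8, G = 160, markersPerTopic = 6, nStopwords = 15,
                     markerStrength = 100, seed = 13)
    keep <- filterHeterogeneousGenes(tp$beta, cutoff = 0.6)
    gid <- colnames(tp$beta)
    expect_true(all(gid[unlist(tp$markerGenes)] %in% keep))
    expect_false(any(gid[tp$stopwordGenes] %in% keep))

    ## universe + removed set partition the vocabulary
    d <- cosineDistanceToUniform(tp$beta)
    expect_setequal(c(keep, gid[d < 0.6]), gid)

    ## all-constant matrix: nothing passes
    expect_error(filterHeterogeneousGenes(rbind(c(0.5, 0.5), c(0.5, 0.5))),
                 "cutoff")
    ## vacuous threshold keeps everything
    expect_length(filterHeterogeneousGenes(tp$beta, cutoff = 0), ncol(tp$beta))
})

test_that("genes go to their argmax topic, ties to the lowest index", {
    b <- cbind(g1 = c(0.1, 0.7, 0.2), g2 = c(0.2, 0.2, 0.6),
               g3 = c(0.5, 0.5, 0.0))
    expect_message(a <- assignGenesToTopics(b), "tie")
    expect_equal(unname(a), c(2L, 3L, 1L))
    expect_equal(names(a), c("g1", "g2", "g3"))
    expect_error(assignGenesToTopics(b, genes = "missing"), "vocabulary")

    ## planted markers land on their own topic in a well-separated matrix
    tp <- makeTopics(K = 5, G = 100, markersPerTopic = 8, nStopwords = 10,
                     markerStrength = 10, seed = 17)
    a2 <- assignGenesToTopics(tp$beta)
    hit <- mapply(function(mk, k) mean(a2[mk] == k),
                  tp$markerGenes, seq_along(tp$markerGenes))
    expect_gte(mean(hit), 0.95)
})

test_that("hypergeometric p-values are exact against enumeration", {
    ## the documented 252-subset case
    expect_equal(hypergeomEnrichTest(4, 5, 4, 10), ref_hyper_enum(4, 5, 4, 10),
                 tolerance = 1e-12)
    expect_equal(hypergeomEnrichTest(4, 5, 4, 10), 5 / 210, tolerance = 1e-12)

    ## certain-overlap and zero-hit boundaries
    expect_equal(hypergeomEnrichTest(5, 5, 12, 12), 1)
    expect_equal(hypergeomEnrichTest(0, 6, 3, 12), 1)

    ## sweep of small universes to machine accuracy
    set.seed(19)
    for (i in 1:20) {
        U <- sample(4:12, 1)
        S <- sample(1:U, 1)
        T_ <- sample(1:U, 1)
        h <- sample(0:min(S, T_), 1)
        expect_equal(hypergeomEnrichTest(h, T_, S, U),
                     ref_hyper_enum(h, T_, S, U), tolerance = 1e-12)
    }

    expect_error(hypergeomEnrichTest(6, 5, 4, 10), "inconsistent")
})

test_that("conditional enrichment without a DAG is the plain test", {
    genes <- sprintf("g%02d", 1:20)
    assign <- setNames(rep(1:2, each = 10), genes)
    sets <- list(SA = genes[1:8], SB = genes[c(1, 11:15)])
    tab <- conditionalEnrichment(assign, genes, sets, dag = NULL, pCutoff = 0.05)
    for (r in seq_len(nrow(tab))) {
        expect_equal(tab$p_value[r],
                     hypergeomEnrichTest(tab$hits[r], tab$topic_gene_count[r],
                                         tab$set_size[r], tab$universe_size[r]))
    }
    ## invariants of the table
    expect_true(all(tab$hits <= pmin(tab$set_size, tab$topic_gene_count)))
    expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
})

test_that("a significant child is eliminated from its ancestors", {
    genes <- sprintf("g%02d", 1:12)
    assign <- setNames(c(rep(1L, 6), rep(2L, 6)), genes)
    child <- genes[1:5]                      # strongly topic-1
    sets <- list(child = child, parent = c(child, genes[12]))
    dag <- data.frame(child = "child", parent = "parent")

    tab <- conditionalEnrichment(assign, genes, sets, dag = dag, pCutoff = 0.05)
    childP <- tab$p_value[tab$set_id == "child" & tab$topic == 1]
    expect_lt(childP, 0.05)
    ## parent then tested on its single non-child gene
    expect_equal(unique(tab$set_size[tab$set_id == "parent"]), 1L)

    ## cyclic DAG rejected
    dagBad <- data.frame(child = c("child", "parent"),
                         parent = c("parent", "child"))
    expect_error(conditionalEnrichment(assign, genes, sets, dag = dagBad),
                 "cyclic")

    ## sets with no universe genes are skipped with a warning
    expect_warning(
        conditionalEnrichment(assign, genes,
                              list(ok = child, off = c("zz1", "zz2")),
                              pCutoff = 0.05),
        "skipped")
})

test_that("a gene set equal to a topic's markers is enriched there only", {
    tp <- makeTopics(K = 8, G = 160, markersPerTopic = 8, nStopwords = 10,
                     markerStrength = 100, seed = 23)
    keep <- filterHeterogeneousGenes(tp$beta, cutoff = 0.6)
    assign <- assignGenesToTopics(tp$beta, keep)
    gid <- colnames(tp$beta)
    sets <- list(topic2markers = gid[tp$markerGenes[[2]]])
    tab <- conditionalEnrichment(assign, keep, sets, pCutoff = 0.001)
    expect_lt(tab$p_value[tab$topic == 2], 0.001)
    expect_true(all(tab$p_value[tab$topic != 2] >= 0.001))
})

test_that("GMT files round-trip through the reader", {
    f <- tempfile(fileext = ".gmt")
    writeLines(c("set1\tdesc\tg1\tg2\tg3", "set2\tdesc\tg2\tg4"), f)
    gs <- readGMT(f)
    expect_equal(gs$set1, c("g1", "g2", "g3"))
    expect_equal(gs$set2, c("g2", "g4"))
})
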