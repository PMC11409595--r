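## Synthetic-data module: Dirichlet-multinomial corpora with planted
## cell types, ages, marker genes and stop-word genes.

.rdirichlet <- function(n, alpha) {
    k <- length(alpha)
    x <- matrix(rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
    x / rowSums(x)
}

#' Specify a planted age effect
#'
#' In old cells a fraction `shift` of the mass the young archetype puts
#' on `reducedTopic` is moved to `boostedTopic`, emulating the loss of a
#' cell type's marker-topic activity with age and the rise of an
#' alternative program.
#'
#' @param reducedTopic integer vector (one per cell type, recycled):
#'   topic whose frequency drops in old cells.
#' @param boostedTopic integer vector: topic that gains the moved mass.
#' @param shift fraction in `[0, 1)` of the reduced topic's archetype
#'   mass moved in old cells.
#' @return a list of class spec fields used by [makeArchetypes()].
#' @examples
#' ageEffectSpec(reducedTopic = 1:2, boostedTopic = c(3L, 4L), shift = 0.3)
#' @export
ageEffectSpec <- function(reducedTopic, boostedTopic, shift) {
    if (any(reducedTopic == boostedTopic))
        stop("reducedTopic and boostedTopic must differ")
    if (shift < 0 || shift >= 1)
        stop("shift must lie in [0, 1)")
    list(reducedTopic = as.integer(reducedTopic),
         boostedTopic = as.integer(boostedTopic),
         shift = as.numeric(shift))
}

#' Generate a topic-gene frequency matrix with planted structure
#'
#' Builds a K x G row-stochastic matrix in which each topic has
#' `markersPerTopic` marker genes elevated `markerStrength`-fold over the
#' background in that topic only, and `nStopwords` stop-word genes whose
#' frequency is exactly constant across topics.  A fixed share of each
#' row's mass (`stopMass`) is reserved for the stop-word block so rows
#' stay exactly stochastic while stop-word columns stay exactly equal.
#'
#' @param K number of topics.
#' @param G number of genes.
#' @param markersPerTopic marker genes planted per topic.
#' @param nStopwords stop-word genes planted.
#' @param concentration Gamma shape of the background frequency draws.
#' @param markerStrength multiplicative elevation of a marker gene in its
#'   own topic relative to the background mean.
#' @param stopMass total frequency mass reserved for the stop-word block;
#'   defaults to `nStopwords / G` (stop words at background frequency).
#' @param seed integer seed; runs are bit-reproducible.
#' @return a [SimulationTruth]-shaped list with elements `beta`
#'   (rownames `topicNN`, colnames `geneNNNN`), `markerGenes` (list per
#'   topic) and `stopwordGenes` (integer indices).
#' @examples
#' tp <- makeTopics(K = 3, G = 60, markersPerTopic = 5, nStopwords = 6, seed = 1)
#' rowSums(tp$beta)
#' @export
makeTopics <- function(K, G, markersPerTopic = 10L, nStopwords = 0L,
                       concentration = 1, markerStrength = 10,
                       stopMass = nStopwords / G, seed = 1L) {
    K <- as.integer(K); G <- as.integer(G)
    if (K < 1L) stop("K must be >= 1")
    if (markersPerTopic * K + nStopwords > G)
        stop("markersPerTopic * K + nStopwords exceeds the gene count")
    set.seed(seed)

    geneIds <- sprintf("gene%04d", seq_len(G))
    stopIdx <- if (nStopwords > 0L) seq_len(nStopwords) + markersPerTopic * K else integer()
    markerIdx <- lapply(seq_len(K), function(k)
        seq_len(markersPerTopic) + (k - 1L) * markersPerTopic)

    beta <- matrix(0, K, G, dimnames = list(sprintf("topic%02d", seq_len(K)), geneIds))

    ## shared stop-word block: one draw, scaled to a fixed mass
    if (nStopwords > 0L) {
        s <- rgamma(nStopwords, shape = concentration) + 1e-6
        s <- s / sum(s) * stopMass
        beta[, stopIdx] <- matrix(s, K, nStopwords, byrow = TRUE)
    } else stopMass <- 0

    ## per-topic weights over the non-stop-word genes
    freeIdx <- setdiff(seq_len(G), stopIdx)
    for (k in seq_len(K)) {
        w <- rgamma(length(freeIdx), shape = concentration) + 1e-6
        own <- match(markerIdx[[k]], freeIdx)
        w[own] <- markerStrength * mean(w)
        beta[k, freeIdx] <- w / sum(w) * (1 - stopMass)
    }

    list(beta = beta,
         markerGenes = markerIdx,
         stopwordGenes = as.integer(stopIdx))
}

#' Generate per-(cell type, age) topic-mixture archetypes
#'
#' Each cell type gets a young archetype dominated by its own marker
#' topic (topic `t` for type `t`), with the remaining mass spread over
#' the other topics by a seeded Dirichlet draw.  The old archetype is the
#' young one with `shift` of the reduced topic's mass moved to the
#' boosted topic (a deterministic mean shift, so planted effects are
#' recoverable at moderate cell numbers).
#'
#' @param nTypes number of cell types; `nTypes <= K` so each type has its
#'   own dominant topic.
#' @param K number of topics.
#' @param ageEffect an [ageEffectSpec()].
#' @param dominance archetype mass on the type's own topic.
#' @param typeNames optional character names; defaults to `typeA`, ...
#' @param seed integer seed.
#' @return named list per type with `young` and `old` K-simplices.
#' @examples
#' ae <- ageEffectSpec(1L, 2L, 0.25)
#' makeArchetypes(nTypes = 1, K = 3, ageEffect = ae, seed = 1)
#' @export
makeArchetypes <- function(nTypes, K, ageEffect, dominance = 0.8,
                           typeNames = NULL, seed = 1L) {
    if (nTypes > K) stop("nTypes must not exceed K (one dominant topic per type)")
    if (ageEffect$shift < 0 || ageEffect$shift >= 1) stop("shift must lie in [0, 1)")
    set.seed(seed)
    if (is.null(typeNames)) typeNames <- paste0("type", LETTERS[seq_len(nTypes)])
    reduced <- rep_len(ageEffect$reducedTopic, nTypes)
    boosted <- rep_len(ageEffect$boostedTopic, nTypes)

    out <- vector("list", nTypes)
    names(out) <- typeNames
    for (t in seq_len(nTypes)) {
        young <- numeric(K)
        young[t] <- dominance
        rest <- setdiff(seq_len(K), t)
        young[rest] <- drop(.rdirichlet(1L, rep(2, length(rest)))) * (1 - dominance)
        old <- young
        moved <- ageEffect$shift * young[reduced[t]]
        old[reduced[t]] <- old[reduced[t]] - moved
        old[boosted[t]] <- old[boosted[t]] + moved
        out[[t]] <- list(young = young, old = old)
    }
    attr(out, "ageEffect") <- list(reducedTopic = setNames(reduced, typeNames),
                                   boostedTopic = setNames(boosted, typeNames),
                                   shift = ageEffect$shift)
    out
}

#' Simulate an LDA-structured scRNA-seq corpus
#'
#' For every cell: draw a topic profile `theta ~ Dirichlet(precision *
#' archetype)`, a library size `L ~ round(LogNormal)`, then counts
#' `~ Multinomial(L, t(theta) %*% beta)`.  Counts are multinomial given
#' the library size (not independent Poissons) so column totals are
#' exact, matching the word-count analogy of the topic model.
#'
#' @param truth a [SimulationTruth] or the list returned by
#'   [makeTopics()] plus archetypes: pass `beta`/`markerGenes`/
#'   `stopwordGenes` via `topics` and archetypes via `archetypes`.
#' @param topics list from [makeTopics()].
#' @param archetypes list from [makeArchetypes()].
#' @param cellsPerGroup data.frame with columns `type`, `age`
#'   (`young`/`old`) and `n` (cells to draw).
#' @param precision Dirichlet precision (archetype mean times this is the
#'   Dirichlet parameter); 50 gives the moderate within-type spread seen
#'   in droplet data.
#' @param libMeanlog,libSdlog log-normal library-size parameters.
#' @param seed integer seed.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   integer `counts` assay (genes x cells), colData columns `cell_id`,
#'   `subtype`, `major_type`, `age`, and metadata entries `truth` (a
#'   [SimulationTruth]) and `thetaTrue` (N x K true topic profiles).
#' @examples
#' tp <- makeTopics(K = 3, G = 40, markersPerTopic = 4, nStopwords = 4, seed = 1)
#' ar <- makeArchetypes(3, 3, ageEffectSpec(1:3, c(2L, 3L, 1L), 0.2), seed = 1)
#' groups <- expand.grid(type = names(ar), age = c("young", "old"), n = 5)
#' sce <- simulateCells(tp, ar, groups, seed = 1)
#' dim(sce)
#' @export
simulateCells <- function(topics, archetypes, cellsPerGroup,
                          precision = 50, libMeanlog = log(500),
                          libSdlog = 0.3, seed = 1L) {
    if (nrow(cellsPerGroup) == 0L) stop("cellsPerGroup is empty")
    if (!all(c("type", "age", "n") %in% names(cellsPerGroup)))
        stop("cellsPerGroup needs columns type, age, n")
    if (!is.finite(libMeanlog) || !is.finite(libSdlog) || libSdlog < 0)
        stop("library size parameters must be finite (sdlog >= 0)")
    if (any(cellsPerGroup$n < 0)) stop("group cell counts must be >= 0")

    beta <- topics$beta
    K <- nrow(beta); G <- ncol(beta)
    set.seed(seed)

    total <- sum(cellsPerGroup$n)
    counts <- matrix(0L, G, total)
    thetaTrue <- matrix(0, total, K)
    type <- character(total); age <- character(total)

    i <- 0L
    for (r in seq_len(nrow(cellsPerGroup))) {
        ty <- as.character(cellsPerGroup$type[r])
        ag <- as.character(cellsPerGroup$age[r])
        n <- cellsPerGroup$n[r]
        if (n == 0L) next
        arch <- archetypes[[ty]][[ag]]
        if (is.null(arch)) stop("no archetype for (", ty, ", ", ag, ")")
        th <- .rdirichlet(n, precision * arch)
        L <- pmax(1L, as.integer(round(rlnorm(n, libMeanlog, libSdlog))))
        for (j in seq_len(n)) {
            p <- drop(crossprod(beta, th[j, ]))
            counts[, i + j] <- drop(rmultinom(1L, L[j], p))
        }
        idx <- i + seq_len(n)
        thetaTrue[idx, ] <- th
        type[idx] <- ty; age[idx] <- ag
        i <- i + n
    }

    cellIds <- sprintf("cell%05d", seq_len(total))
    dimnames(counts) <- list(colnames(beta), cellIds)
    rownames(thetaTrue) <- cellIds
    colnames(thetaTrue) <- rownames(beta)

    ae <- attr(archetypes, "ageEffect")
    if (is.null(ae)) ae <- list(reducedTopic = integer(), boostedTopic = integer(), shift = 0)
    truth <- new("SimulationTruth",
                 betaTrue = beta,
                 archetypes = lapply(archetypes, identity),
                 precision = precision,
                 markerGenes = topics$markerGenes,
                 stopwordGenes = topics$stopwordGenes,
                 ageEffect = ae)

    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")),
        colData = S4Vectors::DataFrame(cell_id = cellIds, subtype = type,
                                       major_type = type, age = age,
                                       row.names = cellIds),
        metadata = list(truth = truth, thetaTrue = thetaTrue,
                        simParams = list(precision = precision,
                                         libMeanlog = libMeanlog,
                                         libSdlog = libSdlog, seed = seed)))
}

#' Extract the planted ground truth from a simulated corpus
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] produced by
#'   [simulateCells()] or [presetScenario()].
#' @return the [SimulationTruth] stored in the object's metadata.
#' @examples
#' sce <- presetScenario("small", seed = 1)
#' simTruth(sce)
#' @export
simTruth <- function(sce) {
    tr <- S4Vectors::metadata(sce)$truth
    if (is.null(tr)) stop("no SimulationTruth in metadata(sce)")
    tr
}

#' Preset simulation scenarios
#'
#' Ready-made corpora mirroring the shape of droplet-based aging blood
#' data: several major cell types each dominated by its own topic, one
#' rare type (too few young cells to clear the rare-type rule after a
#' half split), planted stop-word genes, heterogeneous library sizes and
#' a nonzero old-age topic shift.  All generator parameters are recorded
#' in `metadata(sce)$presetParams`.
#'
#' The `small` preset has 5 types (one rare), K = 8 topics, 240 genes and
#' about 1,500 cells; `medium` has 6 types, K = 10, 400 genes and about
#' 3,000 cells.  By default the age effect reduces each type's own marker
#' topic and boosts one of the non-marker topics.  With
#' `ageEffect = "background"` the shift instead moves mass between two
#' background topics whose marker-gene frequencies are identical, so
#' marker-gene expression carries no age signal while topic composition
#' does.
#'
#' @param scale `"small"` or `"medium"`.
#' @param ageShift fraction of topic mass moved in old cells (default
#'   0.3; 0 disables the age effect).
#' @param ageEffect `"marker"` (reduce the type's marker topic) or
#'   `"background"` (shift between two background topics only).
#' @param seed integer seed.
#' @return a [SingleCellExperiment::SingleCellExperiment] as from
#'   [simulateCells()].
#' @examples
#' sce <- presetScenario("small", seed = 7)
#' table(sce$major_type, sce$age)
#' @export
presetScenario <- function(scale = c("small", "medium"), ageShift = 0.3,
                           ageEffect = c("marker", "background"), seed = 1L) {
    scale <- match.arg(scale)
    ageEffect <- match.arg(ageEffect)
    p <- if (scale == "small") {
        list(nTypes = 5L, K = 8L, G = 240L, markersPerTopic = 10L,
             nStopwords = 20L, nAbundant = 160L, nRareYoung = 24L,
             nRareOld = 160L, libMeanlog = log(600), libSdlog = 0.3)
    } else {
        list(nTypes = 6L, K = 10L, G = 400L, markersPerTopic = 12L,
             nStopwords = 30L, nAbundant = 250L, nRareYoung = 24L,
             nRareOld = 250L, libMeanlog = log(800), libSdlog = 0.3)
    }
    typeNames <- c("T", "B", "NK", "Mono", "RBC", "DC")[seq_len(p$nTypes)]

    if (ageEffect == "marker") {
        ## each type's own topic is reduced; a background topic is boosted
        reduced <- seq_len(p$nTypes)
        boosted <- p$nTypes + 1L + (seq_len(p$nTypes) - 1L) %% (p$K - p$nTypes)
    } else {
        ## shift between the last two background topics for every type
        reduced <- rep(p$K - 1L, p$nTypes)
        boosted <- rep(p$K, p$nTypes)
    }
    ae <- ageEffectSpec(reduced, boosted, ageShift)

    topics <- makeTopics(p$K, p$G, p$markersPerTopic, p$nStopwords,
                         markerStrength = 10, seed = seed)
    if (ageEffect == "background") {
        ## make the two shifted background topics identical on all marker
        ## genes so marker expression is age-invariant
        mk <- unlist(topics$markerGenes)
        b <- topics$beta
        shared <- (b[p$K - 1L, mk] + b[p$K, mk]) / 2
        for (k in c(p$K - 1L, p$K)) {
            b[k, mk] <- shared
            free <- setdiff(seq_len(p$G), c(mk, topics$stopwordGenes))
            b[k, free] <- b[k, free] / sum(b[k, free]) *
                (1 - sum(b[k, mk]) - sum(b[k, topics$stopwordGenes]))
        }
        topics$beta <- b
    }
    arch <- makeArchetypes(p$nTypes, p$K, ae, dominance = 0.8,
                           typeNames = typeNames, seed = seed + 1L)
    if (ageEffect == "background") {
        ## give the shifted background topics real archetype mass so the
        ## planted age signal is detectable in topic space
        aeAttr <- attr(arch, "ageEffect")
        for (t in seq_along(arch)) {
            young <- numeric(p$K)
            young[t] <- 0.6
            young[p$K - 1L] <- 0.3
            young[p$K] <- 0.02
            rest <- setdiff(seq_len(p$K), c(t, p$K - 1L, p$K))
            young[rest] <- (1 - sum(young)) / length(rest)
            old <- young
            moved <- ageShift * young[p$K - 1L]
            old[p$K - 1L] <- old[p$K - 1L] - moved
            old[p$K] <- old[p$K] + moved
            arch[[t]] <- list(young = young, old = old)
        }
        attr(arch, "ageEffect") <- aeAttr
    }

    groups <- data.frame(
        type = rep(typeNames, each = 2L),
        age = rep(c("young", "old"), p$nTypes),
        n = c(rep(c(p$nAbundant, p$nAbundant), p$nTypes - 1L),
              p$nRareYoung, p$nRareOld))

    sce <- simulateCells(topics, arch, groups,
                         libMeanlog = p$libMeanlog, libSdlog = p$libSdlog,
                         seed = seed + 2L)
    S4Vectors::metadata(sce)$presetParams <-
        c(p, list(scale = scale, ageShift = ageShift, ageEffect = ageEffect,
                  seed = seed, rareType = typeNames[p$nTypes]))
    sce
}
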