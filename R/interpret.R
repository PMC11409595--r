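## Topic interpretation: heterogeneous-gene filter, gene-to-topic
## assignment, (conditional) hypergeometric gene-set enrichment.

#' Cosine distance of per-gene topic frequencies to the uniform vector
#'
#' For a gene's length-K frequency vector v, returns `1 - cos(v, 1)` =
#' `1 - sum(v) / (||v|| * sqrt(K))`.  Zero exactly for constant vectors
#' (stop-word-like genes), invariant to positive scaling, and bounded by
#' `[0, 1]` for nonnegative v.
#'
#' @param v nonnegative, nonzero length-K vector, or a K x G matrix
#'   (one distance per column).
#' @return scalar (or length-G vector) in `[0, 1]`.
#' @examples
#' cosineDistanceToUniform(c(1, 1, 1, 1))          # 0
#' cosineDistanceToUniform(c(1, 0, 0, 0))          # 1 - 1/2
#' @export
cosineDistanceToUniform <- function(v) {
    if (is.matrix(v)) return(apply(v, 2L, cosineDistanceToUniform))
    if (any(v < 0)) stop("frequencies must be nonnegative")
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("zero vector has no direction")
    1 - sum(v) / (nv * sqrt(length(v)))
}

#' Keep genes with heterogeneous topic frequencies
#'
#' Genes whose frequency column lies close to the uniform direction
#' (cosine distance below `cutoff`, default 0.6) behave like stop words
#' and are removed; the survivors are the informative genes and form the
#' enrichment universe.
#'
#' @param beta K x G topic-gene matrix (from [topicGeneFreq()]).
#' @param cutoff removal threshold on the cosine distance.
#' @return character vector of retained gene identifiers (column names
#'   of beta), with the distances as attribute `distance`.
#' @export
filterHeterogeneousGenes <- function(beta, cutoff = 0.6) {
    beta <- as.matrix(beta)
    d <- cosineDistanceToUniform(beta)
    keep <- d >= cutoff
    if (!any(keep))
        stop("no gene passes the heterogeneity cutoff; lower the cutoff")
    ids <- colnames(beta)
    if (is.null(ids)) ids <- as.character(seq_len(ncol(beta)))
    structure(ids[keep], distance = d[keep])
}

#' Assign genes to their dominant topic
#'
#' Each gene goes to the topic where its frequency is largest; exact
#' ties go to the lowest topic index (reported via a message).
#'
#' @param beta K x G topic-gene matrix.
#' @param genes gene identifiers to assign (subset of the vocabulary);
#'   default all columns.
#' @return named integer vector, gene -> topic index.
#' @examples
#' b <- cbind(g1 = c(0.1, 0.7, 0.2), g2 = c(0.5, 0.5, 0))
#' assignGenesToTopics(b / rowSums(b) * rowSums(b))
#' @export
assignGenesToTopics <- function(beta, genes = NULL) {
    beta <- as.matrix(beta)
    ids <- colnames(beta)
    if (is.null(ids)) ids <- as.character(seq_len(ncol(beta)))
    if (is.null(genes)) genes <- ids
    bad <- setdiff(genes, ids)
    if (length(bad)) stop("genes not in the vocabulary: ",
                          paste(head(bad, 5L), collapse = ", "))
    sub <- beta[, match(genes, ids), drop = FALSE]
    ties <- vapply(seq_len(ncol(sub)),
                   function(j) sum(sub[, j] == max(sub[, j])) > 1L, logical(1))
    if (any(ties))
        message(sum(ties), " tie(s) broken toward the lowest topic index")
    setNames(apply(sub, 2L, which.max), genes)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' P(X >= hits) where X is the overlap of a random
#' `topicGeneCount`-subset of the universe with a gene set of size
#' `setSize`.
#'
#' @param hits observed overlap.
#' @param topicGeneCount genes assigned to the topic (draws).
#' @param setSize gene-set size within the universe.
#' @param universeSize universe size.
#' @return exact p-value in `[0, 1]`.
#' @examples
#' hypergeomEnrichTest(4, 5, 4, 10)
#' @export
hypergeomEnrichTest <- function(hits, topicGeneCount, setSize, universeSize) {
    if (hits > min(setSize, topicGeneCount) ||
        max(setSize, topicGeneCount) > universeSize || hits < 0)
        stop("inconsistent counts")
    phyper(hits - 1, setSize, universeSize - setSize, topicGeneCount,
           lower.tail = FALSE)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (one set per line: id, description, genes...).
#' @return named list of character vectors.
#' @export
readGMT <- function(path) fgsea::gmtPathways(path)

#' Per-topic (conditional) hypergeometric gene-set enrichment
#'
#' Tests each gene set for over-representation among each topic's genes,
#' within the heterogeneous-gene universe.  If an ontology DAG is
#' supplied (edge list child -> parent), sets are tested children-first
#' and the genes of a significant child are removed from all of its
#' ancestors' sets before those are tested (elimination-style
#' conditioning); with no DAG the table is exactly the unconditional
#' test.
#'
#' @param assignments named integer vector from
#'   [assignGenesToTopics()], restricted to the universe.
#' @param universe character vector of universe genes.
#' @param geneSets named list of gene-id vectors, or a GMT file path.
#' @param dag optional two-column matrix/data.frame of edges (child,
#'   parent); must be acyclic.
#' @param pCutoff significance threshold used both for reporting and for
#'   the conditioning step (default 0.001, no multiplicity correction).
#' @param adjust also add a Benjamini-Hochberg column `p_adjusted`.
#' @return data.frame with columns `set_id`, `topic`, `hits`,
#'   `set_size`, `topic_gene_count`, `universe_size`, `p_value`,
#'   `significant`.
#' @export
conditionalEnrichment <- function(assignments, universe, geneSets,
                                  dag = NULL, pCutoff = 0.001,
                                  adjust = FALSE) {
    if (is.character(geneSets) && length(geneSets) == 1L)
        geneSets <- readGMT(geneSets)
    universe <- unique(as.character(universe))
    assignments <- assignments[names(assignments) %in% universe]
    topics <- sort(unique(assignments))

    sets <- lapply(geneSets, function(g) intersect(g, universe))
    empty <- lengths(sets) == 0L
    if (any(empty)) {
        warning("gene set(s) with no universe genes skipped: ",
                paste(names(sets)[empty], collapse = ", "))
        sets <- sets[!empty]
    }
    if (length(sets) == 0L) stop("no usable gene sets")

    ## testing order: children before any of their ancestors
    testOrder <- names(sets)
    ancestors <- NULL
    if (!is.null(dag) && nrow(as.data.frame(dag)) > 0L) {
        e <- as.data.frame(dag)[, 1:2]
        names(e) <- c("child", "parent")
        nodes <- unique(c(e$child, e$parent, names(sets)))
        kids <- split(as.character(e$child), as.character(e$parent))
        ## Kahn topological sort over child -> parent edges
        indeg <- setNames(integer(length(nodes)), nodes)
        for (p in e$parent) indeg[p] <- indeg[p] + 1L
        queue <- nodes[indeg == 0L]
        topo <- character()
        while (length(queue)) {
            x <- queue[1L]; queue <- queue[-1L]
            topo <- c(topo, x)
            for (p in unique(as.character(e$parent[e$child == x]))) {
                indeg[p] <- indeg[p] - sum(e$child == x & e$parent == p)
                if (indeg[p] == 0L) queue <- c(queue, p)
            }
        }
        if (length(topo) < length(nodes)) stop("ontology DAG is cyclic")
        testOrder <- c(intersect(topo, names(sets)),
                   setdiff(names(sets), topo))
        ## transitive ancestor closure
        parentOf <- split(as.character(e$parent), as.character(e$child))
        ancestors <- lapply(setNames(nodes, nodes), function(x) {
            out <- character(); frontier <- x
            while (length(frontier)) {
                ps <- unique(unlist(parentOf[frontier]))
                ps <- setdiff(ps, out)
                out <- c(out, ps); frontier <- ps
            }
            out
        })
    }

    U <- length(universe)
    rows <- vector("list", length(testOrder) * length(topics))
    r <- 0L
    current <- sets
    for (sid in testOrder) {
        sg <- current[[sid]]
        sigAny <- FALSE
        for (k in topics) {
            tg <- names(assignments)[assignments == k]
            h <- length(intersect(sg, tg))
            p <- if (length(sg) == 0L) 1
                 else hypergeomEnrichTest(h, length(tg), length(sg), U)
            r <- r + 1L
            rows[[r]] <- data.frame(set_id = sid, topic = k, hits = h,
                                    set_size = length(sg),
                                    topic_gene_count = length(tg),
                                    universe_size = U, p_value = p)
            if (p < pCutoff) sigAny <- TRUE
        }
        if (sigAny && !is.null(ancestors) && length(sg)) {
            for (anc in intersect(ancestors[[sid]], names(current)))
                current[[anc]] <- setdiff(current[[anc]], sg)
        }
    }
    out <- do.call(rbind, rows[seq_len(r)])
    out$significant <- out$p_value < pCutoff
    if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
    out[order(out$p_value), , drop = FALSE]
}
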