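## Penalized LDA core: penalty, variational E-step, EM driver, fold-in.

#' Across-topic heterogeneity penalty of a topic-gene matrix
#'
#' \eqn{P(\beta) = \sum_k \sum_g (\beta_{kg} - \bar\beta_g)^2} where
#' \eqn{\bar\beta_g} is the across-topic mean frequency of gene g.  Zero
#' exactly when every gene has identical frequency in all topics (the
#' stop-word configuration); always zero for a single topic.
#'
#' @param beta K x G matrix with row simplices.
#' @return a nonnegative scalar.
#' @examples
#' penaltyTerm(rbind(c(0.8, 0.2), c(0.2, 0.8)))  # 0.36
#' @export
penaltyTerm <- function(beta) {
    beta <- as.matrix(beta)
    sum(sweep(beta, 2L, colMeans(beta), "-")^2)
}

#' Penalized objective value
#'
#' Combines a variational lower bound on the LDA log likelihood with the
#' heterogeneity penalty: `elbo - lambda * penaltyTerm(beta)`.  Positive
#' `lambda` shrinks topic-gene frequencies toward across-topic
#' homogeneity; `lambda = 0` recovers plain LDA.  Negative `lambda`
#' (rewarding heterogeneity) is permitted only behind
#' `allowSignedLambda`.
#'
#' @param elbo the lower-bound value l(alpha, beta).
#' @param beta K x G topic-gene matrix.
#' @param lambda tuning parameter.
#' @param allowSignedLambda allow `lambda < 0`.
#' @return the penalized objective, a scalar.
#' @examples
#' penalizedObjective(-100, rbind(c(0.8, 0.2), c(0.2, 0.8)), 1)  # -100.36
#' @export
penalizedObjective <- function(elbo, beta, lambda, allowSignedLambda = FALSE) {
    if (!is.finite(elbo) || !is.finite(lambda)) stop("non-finite inputs")
    if (lambda < 0 && !allowSignedLambda)
        stop("negative lambda rewards heterogeneity; set allowSignedLambda = TRUE if intended")
    elbo - lambda * penaltyTerm(beta)
}

#' Variational E-step for a single cell
#'
#' Iterates the mean-field updates
#' \eqn{\phi_{gk} \propto \beta_{kg} \exp(\psi(\gamma_k))},
#' \eqn{\gamma = \alpha + \sum_g n_g \phi_g} to a fixed point.  Genes
#' with zero count contribute no \eqn{\phi} terms; a cell with no counts
#' returns the prior (`gamma = alpha`).
#'
#' @param counts length-G count vector aligned to `beta` columns.
#' @param beta K x G topic-gene matrix.
#' @param alpha length-K positive Dirichlet parameter.
#' @param tol fixed-point tolerance on `max |gamma change|`.
#' @param maxInner inner iteration cap.
#' @return list with `gamma` (length K), `phi` (K x G, zero columns for
#'   unexpressed genes), `theta` (normalized gamma), `elbo` and
#'   `innerIters`.
#' @examples
#' b <- rbind(c(0.9, 0.1), c(0.1, 0.9))
#' eStepCell(c(5, 0), b, c(0.5, 0.5))$theta
#' @export
eStepCell <- function(counts, beta, alpha, tol = 1e-8, maxInner = 200L) {
    beta <- as.matrix(beta)
    stopifnot(length(alpha) == nrow(beta), all(alpha > 0))
    res <- cpp_estep_cell(as.numeric(counts), beta, as.numeric(alpha),
                          tol, as.integer(maxInner))
    res$gamma <- as.numeric(res$gamma)
    res$theta <- res$gamma / sum(res$gamma)
    res
}

.initBeta <- function(K, G, seed, smooth = 1e-8) {
    set.seed(seed)
    b <- matrix(rgamma(K * G, shape = 1), K, G) + smooth
    b / rowSums(b)
}

.sparseCounts <- function(x) {
    m <- .countsOf(x)
    methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

#' Fit penalized latent Dirichlet allocation by variational EM
#'
#' Alternates a variational E-step over all cells with a penalized
#' M-step that maximizes \eqn{\sum_{k,g} c_{kg} \log \beta_{kg} -
#' \lambda P(\beta)} over the row simplices, until the relative change
#' of the penalized objective falls below `tol`.  `lambda = 0` is
#' standard variational LDA.  The Dirichlet prior is fixed at the
#' symmetric `1/K` unless `alpha` is supplied; `alpha` is not estimated.
#'
#' @param x SingleCellExperiment (with a `counts` assay) or genes x
#'   cells count matrix; genes must have passed a zero-count filter.
#' @param K number of topics (assumed known and fixed).
#' @param lambda penalty tuning parameter, `>= 0` (see
#'   [penalizedObjective()] for the signed escape hatch).
#' @param alpha optional length-K Dirichlet parameter; default symmetric
#'   `1/K`.
#' @param seed integer seed for the Dirichlet initialization of beta;
#'   fits are bit-reproducible given it.
#' @param tol relative objective-change convergence tolerance.
#' @param maxIter EM iteration cap; non-convergence returns the fit with
#'   `isConverged(fit) = FALSE` and a warning.
#' @param innerTol,maxInner E-step fixed-point controls for the EM
#'   sweeps (warm-started from the previous sweep, so truncated inner
#'   loops still increase the bound).
#' @param finalInnerTol tolerance of the final cold-started E-step pass
#'   that produces the reported profiles; [inferProfiles()] uses the
#'   same setting, so fold-in on the training matrix reproduces
#'   `topicProfiles(fit)` exactly.
#' @param betaInit optional K x G starting value for beta (rows
#'   normalized internally); overrides the seeded initialization.
#' @param allowSignedLambda permit negative lambda.
#' @return a [TopicModel].
#' @examples
#' sce <- presetScenario("small", seed = 1)[, 1:40]
#' fit <- fitPLDA(sce, K = 3, lambda = 0, seed = 1, maxIter = 20)
#' fit
#' @export
fitPLDA <- function(x, K, lambda = 0, alpha = NULL, seed = 1L,
                    tol = 1e-4, maxIter = 200L, innerTol = 1e-3,
                    finalInnerTol = 1e-6, maxInner = 200L, betaInit = NULL,
                    allowSignedLambda = FALSE) {
    K <- as.integer(K)
    if (K < 1L) stop("K must be >= 1")
    if (lambda < 0 && !allowSignedLambda)
        stop("negative lambda rewards heterogeneity; set allowSignedLambda = TRUE if intended")
    Y <- .sparseCounts(x)
    G <- nrow(Y); N <- ncol(Y)
    if (any(Matrix::rowSums(Y) == 0))
        stop("zero-count genes present; run filterGenesMinCount() first")
    if (is.null(alpha)) alpha <- rep(1 / K, K)
    stopifnot(length(alpha) == K, all(alpha > 0))

    beta <- if (is.null(betaInit)) .initBeta(K, G, seed) else {
        b <- as.matrix(betaInit)
        stopifnot(nrow(b) == K, ncol(b) == G)
        (b + 1e-12) / rowSums(b + 1e-12)
    }

    trace <- numeric(0)
    converged <- FALSE
    gammaWarm <- NULL
    for (iter in seq_len(maxIter)) {
        es <- cpp_estep_corpus(Y, beta, alpha, innerTol,
                               as.integer(maxInner), gammaWarm)
        gammaWarm <- es$gamma
        obj <- es$elbo - lambda * penaltyTerm(beta)
        trace <- c(trace, obj)
        if (iter > 1L) {
            prev <- trace[iter - 1L]
            if (abs(obj - prev) <= tol * abs(prev)) { converged <- TRUE; break }
        }
        beta <- mStepPenalized(es$expected, lambda)
    }
    if (!converged)
        warning("EM did not converge in ", maxIter, " iterations")

    ## final cold-started E-step pass at the tight tolerance: the
    ## reported theta is then exactly what fold-in on the training
    ## matrix would return
    es <- cpp_estep_corpus(Y, beta, alpha, finalInnerTol,
                           as.integer(maxInner))
    gamma <- es$gamma
    theta <- gamma / rowSums(gamma)
    rownames(theta) <- rownames(gamma) <- colnames(Y)
    colnames(theta) <- colnames(gamma) <- sprintf("topic%02d", seq_len(K))
    colnames(beta) <- rownames(Y)
    rownames(beta) <- colnames(theta)

    new("TopicModel", K = K, alpha = as.numeric(alpha),
        lambda = as.numeric(lambda), beta = beta, theta = theta,
        gamma = gamma, objectiveTrace = trace, converged = converged,
        nIter = length(trace), seed = as.integer(seed),
        meta = list(tol = tol, innerTol = finalInnerTol,
                    sweepInnerTol = innerTol, maxInner = maxInner,
                    nGenes = G, nCells = N))
}

#' Fold-in: infer topic profiles for new cells with beta fixed
#'
#' Runs the variational E-step only, holding the trained topic-gene
#' frequencies fixed — the transfer-learning step that projects new
#' cells onto previously learned topics.  Genes absent from the model
#' vocabulary are dropped with a warning; genes of the vocabulary absent
#' from the new data simply contribute no counts.
#'
#' @param x SingleCellExperiment or genes x cells count matrix.
#' @param model a fitted [TopicModel].
#' @param innerTol,maxInner E-step controls (defaults from the fit).
#' @return N x K matrix of topic profiles (rows are simplices, named by
#'   cell), with the variational `gamma` as attribute.
#' @examples
#' sce <- presetScenario("small", seed = 1)[, 1:60]
#' fit <- fitPLDA(sce[, 1:40], K = 3, seed = 1, maxIter = 15)
#' th <- inferProfiles(sce[, 41:60], fit)
#' rowSums(th)
#' @export
inferProfiles <- function(x, model, innerTol = NULL, maxInner = NULL) {
    stopifnot(methods::is(model, "TopicModel"))
    Y <- .sparseCounts(x)
    vocab <- colnames(model@beta)
    common <- intersect(rownames(Y), vocab)
    if (length(common) == 0L)
        stop("no overlap between data genes and model vocabulary")
    if (length(common) < nrow(Y))
        warning(nrow(Y) - length(common),
                " gene(s) absent from the model vocabulary dropped")
    ## align to the model vocabulary; missing vocabulary genes get zeros
    Ya <- Matrix::Matrix(0, length(vocab), ncol(Y), sparse = TRUE,
                         dimnames = list(vocab, colnames(Y)))
    Ya[common, ] <- Y[common, ]
    Ya <- methods::as(Ya, "CsparseMatrix")

    if (is.null(innerTol)) innerTol <- model@meta$innerTol
    if (is.null(maxInner)) maxInner <- model@meta$maxInner
    es <- cpp_estep_corpus(Ya, model@beta, model@alpha, innerTol,
                           as.integer(maxInner))
    theta <- es$gamma / rowSums(es$gamma)
    dimnames(theta) <- list(colnames(Y), rownames(model@beta))
    attr(theta, "gamma") <- es$gamma
    theta
}

#' Match estimated topics to reference topics
#'
#' Topic labels are exchangeable, so recovery is scored after finding
#' the permutation that maximizes the summed per-topic Pearson
#' correlation between matched rows of the two matrices.  Exhaustive
#' search over permutations up to K = 8; larger K uses a Hungarian
#' assignment on the correlation matrix (exact for this linear
#' objective).
#'
#' @param betaHat,betaRef K x G matrices with matching dimensions.
#' @return integer permutation `p`: row `p[k]` of `betaHat` matches row
#'   `k` of `betaRef`; the matched per-topic correlations are attached
#'   as attribute `cor`.
#' @examples
#' b <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.3, 0.6))
#' alignTopics(b[2:1, ], b)  # c(2, 1)
#' @export
alignTopics <- function(betaHat, betaRef) {
    betaHat <- as.matrix(betaHat); betaRef <- as.matrix(betaRef)
    if (!all(dim(betaHat) == dim(betaRef)))
        stop("betaHat and betaRef must share dimensions")
    K <- nrow(betaRef)
    if (K == 1L) {
        p <- 1L
    } else {
        C <- cor(t(betaRef), t(betaHat))   # C[i, j] = cor(ref i, hat j)
        C[!is.finite(C)] <- 0
        if (K <= 8L) {
            perms <- .allPerms(K)
            scores <- vapply(perms, function(p) sum(C[cbind(seq_len(K), p)]),
                             numeric(1))
            p <- perms[[which.max(scores)]]
        } else {
            p <- .hungarianMax(C)
        }
    }
    cors <- if (K == 1L) suppressWarnings(cor(betaRef[1L, ], betaHat[1L, ]))
            else cor(t(betaRef), t(betaHat))[cbind(seq_len(K), p)]
    structure(as.integer(p), cor = cors)
}

.allPerms <- function(n) {
    if (n == 1L) return(list(1L))
    do.call(c, lapply(seq_len(n), function(i)
        lapply(.allPerms(n - 1L), function(p) c(i, setdiff(seq_len(n), i)[p]))))
}
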