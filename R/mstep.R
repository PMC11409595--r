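## Penalized M-step: maximize sum_kg c_kg log beta_kg - lambda * P(beta)
## over the product of row simplices.  The objective is concave (sum of
## logs minus a convex quadratic), so projected gradient ascent with
## backtracking converges to the constrained maximum; lambda = 0 has the
## usual closed form and is used as the warm start.

#' Euclidean projection of a vector onto the probability simplex
#'
#' Sorting-based algorithm; O(K log K).
#' @param v numeric vector.
#' @return the closest (L2) point on the simplex.
#' @keywords internal
.projectSimplex <- function(v) {
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u + (1 - css) / seq_along(u) > 0))
    tau <- (css[rho] - 1) / rho
    pmax(v - tau, 0)
}

.mstepObjective <- function(beta, counts, lambda) {
    pos <- counts > 0
    if (any(beta[pos] <= 0)) return(-Inf)
    sum(counts[pos] * log(beta[pos])) - lambda * penaltyTerm(beta)
}

#' Penalized M-step update of the topic-gene matrix
#'
#' Given expected topic-gene counts \eqn{c_{kg} = \sum_i n_{ig}
#' \phi_{igk}} from the E-step, returns the row-stochastic matrix
#' maximizing \eqn{\sum_{k,g} c_{kg}\log\beta_{kg} - \lambda P(\beta)}.
#' For `lambda = 0` this is the closed-form row normalization; otherwise
#' projected gradient ascent with backtracking line search, warm-started
#' from the closed form, run to a `convTol` relative objective change.
#'
#' @param expectedCounts K x G nonnegative matrix; every row must have a
#'   positive total (a zero row is a degenerate topic).
#' @param lambda penalty tuning parameter.
#' @param convTol relative objective-change tolerance.
#' @param maxIter iteration cap.
#' @return K x G matrix with row simplices.
#' @examples
#' mStepPenalized(rbind(c(8, 2), c(5, 5)), lambda = 0)
#' @export
mStepPenalized <- function(expectedCounts, lambda = 0, convTol = 1e-8,
                           maxIter = 1000L) {
    c0 <- as.matrix(expectedCounts)
    if (any(c0 < 0)) stop("expected counts must be nonnegative")
    rs <- rowSums(c0)
    if (any(rs <= 0)) stop("degenerate topic: zero total expected count")

    beta <- c0 / rs
    if (lambda == 0 || nrow(c0) == 1L) return(beta)

    obj <- .mstepObjective(beta, c0, lambda)
    step <- 1 / (2 * lambda + max(rs))
    for (it in seq_len(maxIter)) {
        ## grad of P wrt beta_kg is 2 (beta_kg - colmean_g)
        grad <- matrix(0, nrow(beta), ncol(beta))
        pos <- c0 > 0
        grad[pos] <- c0[pos] / pmax(beta[pos], 1e-300)
        grad <- grad - 2 * lambda * sweep(beta, 2L, colMeans(beta), "-")

        t <- step
        repeat {
            cand <- t(apply(beta + t * grad, 1L, .projectSimplex))
            newObj <- .mstepObjective(cand, c0, lambda)
            d <- cand - beta
            if (newObj >= obj + sum(grad * d) - sum(d * d) / (2 * t) - 1e-12)
                break
            t <- t / 2
            if (t < 1e-18) { cand <- beta; newObj <- obj; break }
        }
        improved <- newObj - obj
        beta <- cand
        obj <- newObj
        if (improved >= 0 && improved <= convTol * abs(obj)) break
        step <- min(t * 2, 1)   # adaptive: try growing the step back
    }
    beta
}

## Hungarian algorithm (shortest augmenting paths) for a square
## assignment maximizing sum C[i, p[i]]; exact fallback for topic
## alignment when exhaustive permutation search is too large.
.hungarianMax <- function(C) {
    a <- -C                      # minimize cost
    n <- nrow(a)
    INF <- .Machine$double.xmax / 4
    u <- numeric(n + 1L); v <- numeric(n + 1L)
    p <- integer(n + 1L); way <- integer(n + 1L)   # columns 0..n -> index+1
    for (i in seq_len(n)) {
        p[1L] <- i
        j0 <- 0L
        minv <- rep(INF, n + 1L)
        used <- rep(FALSE, n + 1L)
        repeat {
            used[j0 + 1L] <- TRUE
            i0 <- p[j0 + 1L]; delta <- INF; j1 <- 0L
            for (j in seq_len(n)) {
                if (!used[j + 1L]) {
                    cur <- a[i0, j] - u[i0 + 1L] - v[j + 1L]
                    if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
                    if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
                }
            }
            for (j in 0:n) {
                if (used[j + 1L]) {
                    u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
                    v[j + 1L] <- v[j + 1L] - delta
                } else minv[j + 1L] <- minv[j + 1L] - delta
            }
            j0 <- j1
            if (p[j0 + 1L] == 0L) break
        }
        repeat {
            j1 <- way[j0 + 1L]
            p[j0 + 1L] <- p[j1 + 1L]
            j0 <- j1
            if (j0 == 0L) break
        }
    }
    perm <- integer(n)
    for (j in seq_len(n)) if (p[j + 1L] > 0L) perm[p[j + 1L]] <- j
    perm
}
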