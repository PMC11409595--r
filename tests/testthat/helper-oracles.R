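## Independent straight-loop oracles.  These deliberately avoid the
## package's vectorized / compiled code paths: plain R loops, closed
## forms and exhaustive enumeration only.

## scalar double-loop penalty
ref_penalty <- function(beta) {
    K <- nrow(beta); G <- ncol(beta)
    s <- 0
    for (g in seq_len(G)) {
        m <- 0
        for (k in seq_len(K)) m <- m + beta[k, g]
        m <- m / K
        for (k in seq_len(K)) s <- s + (beta[k, g] - m)^2
    }
    s
}

## naive per-cell variational fixed point
ref_estep_cell <- function(counts, beta, alpha, tol = 1e-10, max_iter = 5000) {
    K <- nrow(beta)
    idx <- which(counts > 0)
    n <- counts[idx]
    if (length(idx) == 0) return(list(gamma = alpha, phi = NULL))
    gamma <- alpha + sum(n) / K
    phi <- matrix(0, K, length(idx))
    for (it in seq_len(max_iter)) {
        for (j in seq_along(idx)) {
            w <- numeric(K)
            for (k in seq_len(K)) w[k] <- beta[k, idx[j]] * exp(digamma(gamma[k]))
            phi[, j] <- w / sum(w)
        }
        gnew <- alpha
        for (j in seq_along(idx)) gnew <- gnew + n[j] * phi[, j]
        conv <- max(abs(gnew - gamma)) < tol
        gamma <- gnew
        if (conv) break
    }
    list(gamma = gamma, phi = phi, idx = idx)
}

## naive variational LDA (lambda = 0): E-steps to a tight per-cell
## fixed point, closed-form M-step, iterate until beta stabilizes
ref_lda_fit <- function(Y, K, alpha, beta_init, max_iter = 300,
                        beta_tol = 1e-10) {
    Y <- as.matrix(Y)
    beta <- beta_init / rowSums(beta_init)
    N <- ncol(Y); G <- nrow(Y)
    for (it in seq_len(max_iter)) {
        expected <- matrix(0, K, G)
        for (i in seq_len(N)) {
            es <- ref_estep_cell(Y[, i], beta, alpha)
            for (j in seq_along(es$idx))
                expected[, es$idx[j]] <- expected[, es$idx[j]] +
                    Y[es$idx[j], i] * es$phi[, j]
        }
        beta_new <- expected / rowSums(expected)
        delta <- max(abs(beta_new - beta))
        beta <- beta_new
        if (delta < beta_tol) break
    }
    gamma <- matrix(0, N, K)
    for (i in seq_len(N)) gamma[i, ] <- ref_estep_cell(Y[, i], beta, alpha)$gamma
    list(beta = beta, gamma = gamma, iters = it)
}

## dense grid search over two 2-simplices (rows parameterized by their
## first entry) for the penalized M-step, K = 2, G = 2
ref_mstep_grid <- function(counts, lambda, step = 1e-3) {
    p <- seq(0, 1, by = step)
    obj <- function(b11, b21) {
        beta <- rbind(c(b11, 1 - b11), c(b21, 1 - b21))
        s <- 0
        for (k in 1:2) for (g in 1:2)
            if (counts[k, g] > 0) s <- s + counts[k, g] * log(beta[k, g])
        s - lambda * ref_penalty(beta)
    }
    vals <- outer(p, p, Vectorize(obj))
    best <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    rbind(c(p[best[1]], 1 - p[best[1]]), c(p[best[2]], 1 - p[best[2]]))
}

## exhaustive-enumeration hypergeometric upper tail: all subsets of the
## universe of size `draws`, fraction with >= hits overlap with the set
ref_hyper_enum <- function(hits, draws, set_size, universe_size) {
    stopifnot(universe_size <= 12)
    subsets <- combn(universe_size, draws)
    set <- seq_len(set_size)        # exchangeable: wlog first set_size genes
    good <- 0
    for (j in seq_len(ncol(subsets)))
        if (sum(subsets[, j] %in% set) >= hits) good <- good + 1
    good / ncol(subsets)
}

## direct-count confusion oracle
ref_confusion <- function(pred, truth) {
    labels <- sort(unique(c(pred, truth)))
    m <- matrix(0L, length(labels), length(labels),
                dimnames = list(labels, labels))
    for (i in seq_along(pred))
        m[truth[i], pred[i]] <- m[truth[i], pred[i]] + 1L
    m
}

## brute-force topic alignment over all permutations
ref_align <- function(betaHat, betaRef) {
    K <- nrow(betaRef)
    perms <- pldaCells:::.allPerms(K)
    C <- matrix(0, K, K)
    for (i in seq_len(K)) for (j in seq_len(K))
        C[i, j] <- cor(betaRef[i, ], betaHat[j, ])
    best <- NULL; bestval <- -Inf
    for (p in perms) {
        v <- 0
        for (i in seq_len(K)) v <- v + C[i, p[i]]
        if (v > bestval) { bestval <- v; best <- p }
    }
    best
}

## small dense random count matrix (genes x cells) with no zero genes
rand_counts <- function(G, N, seed, lam = 3) {
    set.seed(seed)
    repeat {
        m <- matrix(rpois(G * N, lam), G, N,
                    dimnames = list(sprintf("g%03d", 1:G), sprintf("c%03d", 1:N)))
        if (all(rowSums(m) > 0)) return(m)
    }
}
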