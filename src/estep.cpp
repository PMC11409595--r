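#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Variational E-step for one cell: iterate
//   phi_gk  propto  beta_kg * exp(digamma(gamma_k))
//   gamma_k = alpha_k + sum_g n_g phi_gk
// to a fixed point. Counts enter only through the expressed genes
// (zero-count genes contribute no phi terms).
//
// Returns the number of inner iterations used; fills gamma and phi.
static int estep_one(const arma::vec& n,        // counts, expressed genes (ne)
                     const arma::mat& logB,     // K x ne, log beta columns
                     const arma::vec& alpha,    // K
                     double tol, int max_inner,
                     bool warm,                 // use incoming gamma as start
                     arma::vec& gamma,          // K, in/out
                     arma::mat& phi)            // K x ne, out
{
    const arma::uword K  = alpha.n_elem;
    const arma::uword ne = n.n_elem;

    if (ne == 0) {            // no data: posterior equals the prior
        gamma = alpha;
        return 0;
    }

    double total = arma::accu(n);
    if (!warm) {
        gamma.fill(0.0);
        for (arma::uword k = 0; k < K; ++k) gamma(k) = alpha(k) + total / K;
    }

    arma::vec dg(K), lp(K), gamma_new(K);
    int it = 0;
    for (it = 0; it < max_inner; ++it) {
        for (arma::uword k = 0; k < K; ++k) dg(k) = R::digamma(gamma(k));
        for (arma::uword g = 0; g < ne; ++g) {
            lp = logB.col(g) + dg;
            double m = lp.max();
            if (!std::isfinite(m)) {
                // every topic gives this gene zero frequency
                Rcpp::stop("cell expresses a gene with zero frequency in every topic");
            }
            lp = arma::exp(lp - m);
            phi.col(g) = lp / arma::accu(lp);
        }
        gamma_new = alpha + phi * n;
        double delta = arma::abs(gamma_new - gamma).max();
        gamma = gamma_new;
        if (delta < tol) { ++it; break; }
    }
    return it;
}

// Per-cell contribution to the variational lower bound (ELBO), with
// alpha fixed.  Standard mean-field bound for LDA.
static double elbo_one(const arma::vec& n, const arma::mat& logB,
                       const arma::vec& alpha,
                       const arma::vec& gamma, const arma::mat& phi)
{
    const arma::uword K  = alpha.n_elem;
    const arma::uword ne = n.n_elem;

    double a0 = arma::accu(alpha), g0 = arma::accu(gamma);
    double psi_g0 = R::digamma(g0);

    double bound = std::lgamma(a0);
    for (arma::uword k = 0; k < K; ++k) {
        double psi_gk = R::digamma(gamma(k)) - psi_g0;
        bound -= std::lgamma(alpha(k));
        bound += (alpha(k) - 1.0) * psi_gk;              // E log p(theta)
        bound += std::lgamma(gamma(k));                  // entropy of q(theta)
        bound -= (gamma(k) - 1.0) * psi_gk;
    }
    bound -= std::lgamma(g0);

    for (arma::uword g = 0; g < ne; ++g) {
        for (arma::uword k = 0; k < K; ++k) {
            double p = phi(k, g);
            if (p > 0.0) {
                double psi_gk = R::digamma(gamma(k)) - psi_g0;
                bound += n(g) * p * (psi_gk + logB(k, g) - std::log(p));
            }
        }
    }
    return bound;
}

// One E-step sweep over a corpus.  Y is genes x cells (sparse), beta is
// K x genes with simplex rows.  Returns per-cell gamma, the expected
// topic-gene counts sum_i n_ig phi_igk (the M-step sufficient
// statistics), the summed ELBO and per-cell inner iteration counts.
// An optional gamma_init (N x K) warm-starts every cell's fixed point,
// e.g. from the previous EM sweep; each inner update is coordinate
// ascent on the bound, so warm-started sweeps keep the ELBO monotone
// even when truncated.
// [[Rcpp::export]]
List cpp_estep_corpus(const arma::sp_mat& Y, const arma::mat& beta,
                      const arma::vec& alpha, double tol, int max_inner,
                      Rcpp::Nullable<Rcpp::NumericMatrix> gamma_init = R_NilValue)
{
    const arma::uword K = beta.n_rows;
    const arma::uword G = beta.n_cols;
    const arma::uword N = Y.n_cols;
    if (Y.n_rows != G) stop("gene dimension of counts does not match beta");

    bool warm = gamma_init.isNotNull();
    arma::mat ginit;
    if (warm) {
        ginit = Rcpp::as<arma::mat>(gamma_init.get());
        if (ginit.n_rows != N || ginit.n_cols != K)
            stop("gamma_init must be cells x topics");
    }

    arma::mat logB_full = arma::log(beta);   // -inf where beta == 0 is fine

    arma::mat gamma_out(N, K);
    arma::mat expected(K, G, arma::fill::zeros);
    arma::ivec inner(N);
    double elbo = 0.0;

    arma::vec gamma(K);
    for (arma::uword i = 0; i < N; ++i) {
        // gather expressed genes of cell i
        arma::sp_mat::const_col_iterator it  = Y.begin_col(i);
        arma::sp_mat::const_col_iterator end = Y.end_col(i);
        std::vector<arma::uword> idx;
        std::vector<double> cnt;
        for (; it != end; ++it) {
            if (*it > 0.0) { idx.push_back(it.row()); cnt.push_back(*it); }
        }
        const arma::uword ne = idx.size();
        arma::vec n(ne);
        arma::mat logB(K, ne);
        for (arma::uword j = 0; j < ne; ++j) {
            n(j) = cnt[j];
            logB.col(j) = logB_full.col(idx[j]);
        }

        arma::mat phi(K, ne);
        if (warm) gamma = ginit.row(i).t();
        inner(i) = estep_one(n, logB, alpha, tol, max_inner, warm, gamma, phi);
        gamma_out.row(i) = gamma.t();
        for (arma::uword j = 0; j < ne; ++j)
            expected.col(idx[j]) += n(j) * phi.col(j);
        elbo += elbo_one(n, logB, alpha, gamma, phi);
    }

    return List::create(_["gamma"] = gamma_out,
                        _["expected"] = expected,
                        _["elbo"] = elbo,
                        _["inner_iters"] = inner);
}

// Single-cell E-step, exposed for unit-level use (dense count vector).
// [[Rcpp::export]]
List cpp_estep_cell(const arma::vec& counts, const arma::mat& beta,
                    const arma::vec& alpha, double tol, int max_inner)
{
    const arma::uword K = beta.n_rows;
    const arma::uword G = beta.n_cols;
    if (counts.n_elem != G) stop("count vector length does not match beta");

    arma::uvec idx = arma::find(counts > 0.0);
    arma::vec n = counts.elem(idx);
    arma::mat logB(K, idx.n_elem);
    arma::mat beta_log = arma::log(beta);
    for (arma::uword j = 0; j < idx.n_elem; ++j)
        logB.col(j) = beta_log.col(idx(j));

    arma::vec gamma(K);
    arma::mat phi(K, idx.n_elem);
    int it = estep_one(n, logB, alpha, tol, max_inner, false, gamma, phi);
    double elbo = elbo_one(n, logB, alpha, gamma, phi);

    // scatter phi back to full gene indexing for the caller
    arma::mat phi_full(K, G, arma::fill::zeros);
    for (arma::uword j = 0; j < idx.n_elem; ++j)
        phi_full.col(idx(j)) = phi.col(j);

    return List::create(_["gamma"] = gamma, _["phi"] = phi_full,
                        _["elbo"] = elbo, _["inner_iters"] = it);
}
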