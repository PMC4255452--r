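# Reversible amino-acid substitution model: rate matrix construction,
# transition probabilities via symmetric eigendecomposition, discrete-gamma
# rate heterogeneity.

#' Construct a reversible amino-acid substitution model
#'
#' Builds a time-reversible continuous-time Markov model from a symmetric
#' exchangeability matrix and stationary frequencies. The default is the
#' WAG empirical model with uniform rates across sites; discrete-gamma
#' rate heterogeneity is available via `n_gamma_cats` and `alpha`.
#'
#' @param name model name; `"WAG"` loads the embedded WAG constants.
#' @param exchangeabilities optional symmetric 20x20 matrix of relative
#'   exchange rates (overrides `name`).
#' @param freqs optional stationary frequencies (length 20, positive,
#'   summing to 1); e.g. empirical frequencies from a reference alignment.
#' @param n_gamma_cats number of discrete gamma rate categories (default 1,
#'   i.e. rate homogeneity).
#' @param alpha gamma shape parameter, used when `n_gamma_cats > 1`.
#'
#' @return an object of class `pia_model` holding the normalized rate
#'   matrix, its eigendecomposition and the per-category rates.
#' @export
substitution_model <- function(name = "WAG", exchangeabilities = NULL,
                               freqs = NULL, n_gamma_cats = 1L,
                               alpha = 1.0) {
  if (is.null(exchangeabilities)) {
    if (!identical(name, "WAG")) {
      stop("unknown model name '", name, "'; supply exchangeabilities")
    }
    exchangeabilities <- wag_exchangeabilities()
  }
  if (is.null(freqs)) freqs <- wag_frequencies()
  freqs <- as.numeric(freqs)
  if (length(freqs) != 20L || any(freqs <= 0)) {
    stop("freqs must be 20 positive values")
  }
  if (abs(sum(freqs) - 1) > 1e-12) {
    stop("freqs must sum to 1 within 1e-12")
  }
  n_gamma_cats <- as.integer(n_gamma_cats)
  if (n_gamma_cats < 1L) stop("n_gamma_cats must be >= 1")
  if (n_gamma_cats > 1L && alpha <= 0) stop("alpha must be positive")

  model <- structure(
    list(name = name, exchangeabilities = exchangeabilities,
         freqs = stats::setNames(freqs, .aa_order),
         n_gamma_cats = n_gamma_cats, alpha = alpha),
    class = "pia_model")
  model$Q <- build_rate_matrix(model)
  model$eig <- .rate_matrix_eigen(model$Q, freqs)
  model$rates <- gamma_category_rates(alpha, n_gamma_cats)
  model
}

#' Build the normalized instantaneous rate matrix
#'
#' Q_ij = s_ij * pi_j for i != j, diagonal set so rows sum to zero, then
#' globally rescaled so the mean substitution rate -sum_i pi_i Q_ii is 1
#' (branch lengths are expected substitutions per site).
#'
#' @param model a `pia_model` or a list with `exchangeabilities` and `freqs`.
#' @return numeric 20x20 rate matrix.
#' @export
build_rate_matrix <- function(model) {
  S <- model$exchangeabilities
  pi <- as.numeric(model$freqs)
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-12))) {
    stop("exchangeability matrix must be symmetric")
  }
  if (any(S < 0)) stop("exchangeabilities must be non-negative")
  if (any(pi <= 0)) stop("all stationary frequencies must be positive")
  Q <- S * rep(pi, each = 20L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mean_rate <- -sum(pi * diag(Q))
  Q <- Q / mean_rate
  dimnames(Q) <- list(.aa_order, .aa_order)
  Q
}

# Symmetrizing similarity transform: B = D^(1/2) Q D^(-1/2) with
# D = diag(pi) is symmetric for reversible Q, so exp(Qt) can be computed
# from one real eigendecomposition.
.rate_matrix_eigen <- function(Q, pi) {
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2  # symmetrize away rounding noise
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       V = e$vectors / sq,          # D^(-1/2) U
       Vi = t(e$vectors) * rep(sq, each = 20L))  # U' D^(1/2)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed from the cached symmetric eigendecomposition of the rate
#' matrix. Rows sum to 1; tiny negative entries from rounding are clamped
#' to zero.
#'
#' @param model a `pia_model`.
#' @param t branch length (expected substitutions per site), `t >= 0`.
#' @return 20x20 row-stochastic matrix.
#' @export
transition_probs <- function(model, t) {
  if (!is.finite(t) || t < 0) stop("branch length t must be >= 0")
  e <- model$eig
  P <- e$V %*% (exp(e$values * t) * e$Vi)
  P[P < 0] <- 0
  dimnames(P) <- list(.aa_order, .aa_order)
  P
}

#' Discrete-gamma rate categories (mean-per-category)
#'
#' Splits a Gamma(alpha, alpha) distribution (mean 1) into `k` equal
#' probability bins and returns the mean rate of each bin, the standard
#' discretization for among-site rate variation.
#'
#' @param alpha gamma shape parameter (> 0).
#' @param k number of categories (>= 1). `k = 1` returns `1.0`.
#' @return numeric vector of `k` rates with mean 1.
#' @export
gamma_category_rates <- function(alpha, k) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k == 1L) return(1.0)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
  breaks <- stats::qgamma(seq(0, 1, length.out = k + 1L),
                          shape = alpha, rate = alpha)
  # mean of Gamma(a, a) over (b_i, b_{i+1}] is P(b; a+1, a) differences
  cum <- stats::pgamma(breaks, shape = alpha + 1, rate = alpha)
  rates <- diff(cum) * k
  rates / mean(rates)  # exact unit mean despite tail rounding
}
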