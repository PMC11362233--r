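#' @useDynLib ditree, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm rnorm runif rlnorm dgamma sd var quantile setNames
#'   aggregate cor rbinom
#' @importFrom rlang .data
NULL

# row-wise log-sum-exp with max subtraction
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# elementwise log(exp(a) + exp(b)), stable
log_add_exp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(-abs(a - b)))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# normalize a matrix of log-weights (rows = persons, cols = categories)
softmax_rows <- function(lw) {
  m <- apply(lw, 1L, max)
  w <- exp(lw - m)
  w / rowSums(w)
}

check_weights <- function(weights, K, label = "pseudo-item") {
  if (length(weights) != K + 1L) {
    stop(sprintf(
      "scoring weights for %s have length %d but the item has %d categories (K = %d)",
      label, length(weights), K + 1L, K
    ), call. = FALSE)
  }
  if (!all(is.finite(weights))) {
    stop(sprintf("scoring weights for %s must be finite", label), call. = FALSE)
  }
  invisible(weights)
}

#' Category probabilities of the generalized partial credit model
#'
#' Divide-by-total dominance model for an ordinal item with categories
#' `0, ..., K`. The linear predictor of category `y` is
#' `alpha * (s_y * theta - sum_{k<=y} beta_k)` with `beta_0 = 0`, and category
#' probabilities are the softmax over categories. All arithmetic is done in
#' log space with max subtraction, so extreme trait values do not overflow.
#'
#' @param theta Numeric vector of latent trait levels.
#' @param alpha Positive discrimination parameter.
#' @param beta Numeric vector of thresholds `beta_1, ..., beta_K` (the implicit
#'   `beta_0` is 0).
#' @param weights Scoring weights `s_0, ..., s_K`; defaults to `0:K`.
#' @param label Item label used in error messages.
#' @return For scalar `theta` a probability vector of length `K + 1`;
#'   otherwise a matrix with one row per element of `theta`.
#' @examples
#' gpcm_probs(0, alpha = 1, beta = 0)            # 0.5, 0.5
#' gpcm_probs(1, alpha = 1, beta = c(0, 0))      # proportional to 1, e, e^2
#' @export
gpcm_probs <- function(theta, alpha, beta, weights = NULL, label = "item") {
  K <- length(beta)
  if (is.null(weights)) weights <- 0:K
  check_weights(weights, K, label)
  stopifnot(alpha > 0, all(is.finite(beta)))
  cumb <- c(0, cumsum(beta))
  lw <- alpha * (outer(theta, weights) - rep(cumb, each = length(theta)))
  out <- softmax_rows(matrix(lw, nrow = length(theta)))
  if (length(theta) == 1L) drop(out) else out
}

#' Category probabilities of the generalized graded unfolding model
#'
#' Divide-by-total ideal-point model for an ordinal item with categories
#' `0, ..., K`. Each observable category aggregates two latent categories
#' ("from below" with scoring weight `s_y` and "from above" with weight
#' `M - s_y`, `M = 2K + 1`), giving category components
#' `exp(lambda * (s_y * (theta - delta) - sum xi)) +
#'  exp(lambda * ((M - s_y) * (theta - delta) - sum xi))`.
#' The resulting probabilities are symmetric about `theta = delta`.
#'
#' @param theta Numeric vector of latent trait levels (ideal points).
#' @param lambda Positive discrimination parameter.
#' @param delta Item location.
#' @param xi Numeric vector of thresholds `xi_1, ..., xi_K` (`xi_0 = 0`).
#' @inheritParams gpcm_probs
#' @return As [gpcm_probs()].
#' @examples
#' ggum_probs(0, lambda = 1, delta = 0, xi = -1)
#' @export
ggum_probs <- function(theta, lambda, delta, xi, weights = NULL, label = "item") {
  K <- length(xi)
  if (is.null(weights)) weights <- 0:K
  check_weights(weights, K, label)
  stopifnot(lambda > 0, all(is.finite(xi)), is.finite(delta))
  M <- 2 * K + 1
  cumxi <- c(0, cumsum(xi))
  d <- theta - delta
  a <- lambda * (outer(d, weights) - rep(cumxi, each = length(theta)))
  b <- lambda * (outer(d, M - weights) - rep(cumxi, each = length(theta)))
  lw <- log_add_exp(a, b)
  out <- softmax_rows(matrix(lw, nrow = length(theta)))
  if (length(theta) == 1L) drop(out) else out
}

#' Expected score of a category distribution
#'
#' The item response function value: `sum_y y * p(y)` for categories
#' `0, ..., K`.
#'
#' @param p Probability vector over categories `0..K`, or a matrix with one
#'   distribution per row.
#' @return Numeric expected score(s) in `[0, K]`.
#' @export
expected_score <- function(p) {
  if (is.matrix(p)) {
    K <- ncol(p) - 1L
    stopifnot(all(p >= 0), max(abs(rowSums(p) - 1)) < 1e-8)
    drop(p %*% (0:K))
  } else {
    K <- length(p) - 1L
    stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-8)
    sum((0:K) * p)
  }
}
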