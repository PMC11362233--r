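# Rank-normalized split-chain convergence diagnostics (Vehtari, Gelman,
# Simpson, Carpenter & Buerkner, 2021): split R-hat computed on rank-normalized
# draws (max of bulk and folded versions), bulk ESS on rank-normalized split
# chains, tail ESS as the minimum ESS of the 5% / 95% quantile indicators.

# split each chain in half; x: iterations x chains -> iterations/2 x 2*chains
split_chains <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  if (half < 2) return(x)
  cbind(x[seq_len(half), , drop = FALSE],
        x[seq.int(n - half + 1L, n), , drop = FALSE])
}

rank_normalize <- function(x) {
  d <- dim(x)
  r <- rank(as.vector(x), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, d[1], d[2])
}

rhat_basic <- function(sims) {
  S <- nrow(sims); M <- ncol(sims)
  means <- colMeans(sims)
  vars <- apply(sims, 2L, var)
  W <- mean(vars)
  B <- S * var(means)
  if (W == 0) return(1)
  sqrt(((S - 1) / S * W + B / S) / W)
}

# FFT autocovariance (biased, lag 0..n-1)
autocov <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  np <- 2L^ceiling(log2(2L * n))
  f <- stats::fft(c(x, rep(0, np - n)))
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (np * n)
}

ess_basic <- function(sims) {
  S <- nrow(sims); M <- ncol(sims)
  if (S < 4) return(NA_real_)
  ac <- vapply(seq_len(M), function(m) autocov(sims[, m]), numeric(S))
  chain_var <- ac[1, ] * S / (S - 1)
  W <- mean(chain_var)
  var_plus <- W * (S - 1) / S
  if (M > 1) var_plus <- var_plus + var(colMeans(sims))
  if (var_plus == 0) return(S * M)
  rho <- 1 - (W - rowMeans(ac)) / var_plus
  # Geyer initial monotone positive sequence on paired sums
  tau <- -1
  t <- 0
  prev_pair <- Inf
  while (t + 2 < S) {
    pair <- rho[t + 1] + rho[t + 2]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev_pair)
    prev_pair <- pair
    tau <- tau + 2 * pair
    t <- t + 2
  }
  tau <- max(tau, 1 / log10(S * M + 10))
  S * M / tau
}

#' Convergence diagnostics for a matrix of MCMC draws
#'
#' `rhat()` is the rank-normalized split potential-scale-reduction statistic
#' (the maximum of the bulk and folded versions); `ess_bulk()` the effective
#' sample size of rank-normalized split chains; `ess_tail()` the minimum ESS
#' of the 5% and 95% quantile indicator variables.
#'
#' @param x Matrix of post-warmup draws, iterations x chains.
#' @return A scalar.
#' @export
rhat <- function(x) {
  x <- split_chains(x)
  if (var(as.vector(x)) == 0) return(1)
  bulk <- rhat_basic(rank_normalize(x))
  folded <- rhat_basic(rank_normalize(abs(x - stats::median(x))))
  max(bulk, folded)
}

#' @rdname rhat
#' @export
ess_bulk <- function(x) {
  x <- split_chains(x)
  if (var(as.vector(x)) == 0) return(length(x))
  ess_basic(rank_normalize(x))
}

#' @rdname rhat
#' @export
ess_tail <- function(x) {
  x <- split_chains(x)
  if (var(as.vector(x)) == 0) return(length(x))
  q <- quantile(as.vector(x), c(0.05, 0.95), names = FALSE)
  min(ess_basic(rank_normalize(1 * (x <= q[1]))),
      ess_basic(rank_normalize(1 * (x <= q[2]))))
}

# draws: list of per-chain matrices (iterations x parameters, same colnames)
diagnose_draws <- function(chains) {
  pnames <- colnames(chains[[1L]])
  out <- tibble::tibble(
    parameter = pnames,
    rhat = NA_real_, ess_bulk = NA_real_, ess_tail = NA_real_
  )
  for (j in seq_along(pnames)) {
    x <- vapply(chains, function(m) m[, j], numeric(nrow(chains[[1L]])))
    out$rhat[j] <- rhat(x)
    out$ess_bulk[j] <- ess_bulk(x)
    out$ess_tail[j] <- ess_tail(x)
  }
  out
}
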