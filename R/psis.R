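# Pareto-smoothed importance sampling leave-one-out cross-validation
# (Vehtari, Gelman & Gabry, 2017), with the generalized Pareto tail fit of
# Zhang & Stephens (2009).

# Fit a generalized Pareto distribution to exceedances x (> 0) by the
# Zhang-Stephens profile posterior-mean estimator, with the weak prior on the
# shape used in PSIS (shrinks k toward 0.5 by 10 pseudo-observations).
# Returns the usual-convention shape k (positive = heavy tail) and scale.
gpd_fit <- function(x) {
  x <- sort.int(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  b <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  ks <- vapply(b, function(bj) mean(log1p(-bj * x)), 0)
  L <- n * (log(-b / ks) - ks - 1)
  L[!is.finite(L)] <- -Inf   # degenerate grid points (ks crossing zero)
  wl <- exp(L - max(L))
  w <- wl / sum(wl)
  b_post <- sum(b * w)
  k_raw <- mean(log1p(-b_post * x))
  # weak prior shrinking the shape toward 0.5 (10 pseudo-observations);
  # the scale comes from the unshrunk shape
  list(k = (k_raw * n + 5) / (n + 10), sigma = -k_raw / b_post)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

# Smooth one observation's log importance ratios. Returns the smoothed log
# weights (unnormalized, shifted so max = 0) and the Pareto k diagnostic.
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5 || var(lw) == 0) return(list(lw = lw, k = -Inf))
  ord <- order(lw)
  tail_ids <- ord[seq.int(S - M + 1L, S)]
  cutpoint <- lw[ord[S - M]]
  exceed <- exp(lw[tail_ids]) - exp(cutpoint)
  # ties at the cutpoint give zero exceedances; fit the GPD to positive ones
  if (sum(exceed > 0) < 5) return(list(lw = lw, k = -Inf))
  fit <- gpd_fit(exceed[exceed > 0])
  # replace tail weights by expected order statistics of the fitted GPD
  p <- (seq_len(M) - 0.5) / M
  smoothed <- log(exp(cutpoint) + qgpd(p, fit$k, fit$sigma))
  lw[tail_ids[order(lw[tail_ids])]] <- smoothed
  lw <- pmin(lw, 0)  # truncate at the maximum raw weight
  list(lw = lw, k = fit$k)
}

#' PSIS-LOO cross-validation from a pointwise log-likelihood matrix
#'
#' Computes the leave-one-out expected log predictive density by importance
#' sampling with Pareto-smoothed weights, and reports the LOO information
#' criterion on the deviance scale (`-2 * elpd_loo`; small values indicate
#' better out-of-sample fit).
#'
#' @param loglik Matrix of pointwise log-likelihood values, posterior draws in
#'   rows and observations in columns.
#' @return A list of class `ditree_loo`: `looic`, `se` (SE of `looic`),
#'   `elpd_loo`, `elpd_se`, `pointwise` (per-observation elpd), `pareto_k`
#'   (per-observation tail-shape diagnostics), `n_bad_k` (count of k > 0.7).
#' @export
psis_loo <- function(loglik) {
  stopifnot(is.matrix(loglik), nrow(loglik) >= 10)
  n <- ncol(loglik)
  pointwise <- numeric(n)
  ks <- numeric(n)
  for (j in seq_len(n)) {
    ll <- loglik[, j]
    sm <- psis_smooth(-ll)
    pointwise[j] <- log_sum_exp(sm$lw + ll) - log_sum_exp(sm$lw)
    ks[j] <- sm$k
  }
  elpd <- sum(pointwise)
  elpd_se <- sqrt(n * var(pointwise))
  structure(
    list(looic = -2 * elpd, se = 2 * elpd_se, elpd_loo = elpd,
         elpd_se = elpd_se, pointwise = pointwise, pareto_k = ks,
         n_bad_k = sum(ks > 0.7), n_obs = n),
    class = "ditree_loo"
  )
}

#' @export
print.ditree_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO: looic = %.1f (SE %.1f), elpd = %.1f over %d observations\n",
              x$looic, x$se, x$elpd_loo, x$n_obs))
  if (x$n_bad_k > 0) {
    cat(sprintf("Warning: %d observation(s) with Pareto k > 0.7\n", x$n_bad_k))
  }
  invisible(x)
}

#' Compare fitted models by PSIS-LOO
#'
#' @param ... Fitted models ([fit_irtree()] objects) or `ditree_loo` objects,
#'   optionally named. All must refer to the same observations.
#' @return Tibble with one row per model: `looic`, `se`, `elpd_loo`,
#'   `delta_looic` relative to the best (smallest-LOO) model, a `best` flag,
#'   and the count of high Pareto-k observations.
#' @export
loo_compare <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1L]]) && !inherits(fits[[1L]], c("ditree_fit", "ditree_loo"))) {
    fits <- fits[[1L]]
  }
  nms <- names(fits)
  if (is.null(nms)) nms <- rep("", length(fits))
  loos <- vector("list", length(fits))
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    if (inherits(f, "ditree_fit")) {
      if (nms[i] == "") nms[i] <- f$spec$model
      loos[[i]] <- loo(f)
    } else if (inherits(f, "ditree_loo")) {
      loos[[i]] <- f
    } else {
      stop("loo_compare() accepts ditree_fit or ditree_loo objects", call. = FALSE)
    }
    if (nms[i] == "") nms[i] <- paste0("model", i)
  }
  nobs <- vapply(loos, `[[`, 0, "n_obs")
  if (length(unique(nobs)) != 1L) {
    stop("models were fitted to different numbers of observations", call. = FALSE)
  }
  out <- tibble::tibble(
    model = nms,
    looic = vapply(loos, `[[`, 0, "looic"),
    se = vapply(loos, `[[`, 0, "se"),
    elpd_loo = vapply(loos, `[[`, 0, "elpd_loo"),
    n_bad_k = vapply(loos, `[[`, 0, "n_bad_k")
  )
  out$delta_looic <- out$looic - min(out$looic)
  out$best <- out$looic == min(out$looic)
  dplyr::arrange(out, .data$looic)
}
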