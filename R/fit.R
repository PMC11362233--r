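#' Priors for IRTree estimation
#'
#' Discriminations get a Gamma(shape, rate) prior (default Gamma(1.5, 1.5),
#' mean 1); category intercepts a normal prior (default N(0, 5)); ideal-point
#' locations a hierarchical normal prior whose mean has a N(0, 5) hyperprior
#' and whose sd has a half-normal(0, 5) hyperprior. Trait distributions are
#' fixed to N(0, 1) for identification. For joint response-time models the
#' RT fixed effects get N(0, `rt_coef_sd`) priors and the variance components
#' half-normal(0, `rt_sd_scale`).
#'
#' @param disc_shape,disc_rate Gamma shape and rate of discrimination priors.
#' @param tau_sd Normal sd of category-intercept priors.
#' @param delta_mean_sd,delta_sd_sd Hyperprior scales of the location prior.
#' @param rt_coef_sd,rt_sd_scale RT fixed-effect / variance-component scales.
#' @return A list of class `ditree_priors`.
#' @export
ditree_priors <- function(disc_shape = 1.5, disc_rate = 1.5, tau_sd = 5,
                          delta_mean_sd = 5, delta_sd_sd = 5,
                          rt_coef_sd = 5, rt_sd_scale = 5) {
  structure(list(disc_shape = disc_shape, disc_rate = disc_rate,
                 tau_sd = tau_sd, delta_mean_sd = delta_mean_sd,
                 delta_sd_sd = delta_sd_sd, rt_coef_sd = rt_coef_sd,
                 rt_sd_scale = rt_sd_scale),
            class = "ditree_priors")
}

#' Sampler configuration
#'
#' Four chains with 500 warmup and 1000 post-warmup stored draws by default.
#' If any parameter has split R-hat above `rhat_max` or bulk/tail effective
#' sample size below `min_ess`, sampling is extended in steps of `extend_step`
#' stored draws per chain up to `max_draws`; a fit that still fails is flagged
#' non-converged. Because the backend is a random-walk sampler, each stored
#' draw is separated by `sweeps_per_draw` full update sweeps (built-in
#' thinning; warmup counts sweeps on the same schedule).
#'
#' @param chains,warmup,draws,extend_step,max_draws,rhat_max,min_ess See above.
#' @param sweeps_per_draw Update sweeps between stored draws.
#' @param seed Integer seed.
#' @param loglik_draws Maximum pooled draws used for the pointwise
#'   log-likelihood matrix (for PSIS-LOO).
#' @param refit_attempts Maximum refits with a new seed when the fit fails to
#'   converge or its orientation contradicts the sign template (a chain can
#'   occasionally commit to a local maximum or the inverted solution).
#' @param quiet Suppress progress messages.
#' @return A list of class `ditree_control`.
#' @export
mcmc_control <- function(chains = 4, warmup = 500, draws = 1000,
                         extend_step = 500, max_draws = 3000,
                         rhat_max = 1.05, min_ess = 100,
                         sweeps_per_draw = 3, seed = 1,
                         loglik_draws = 1000, refit_attempts = 2,
                         quiet = TRUE) {
  stopifnot(rhat_max > 1, min_ess > 0, max_draws >= draws, extend_step > 0)
  structure(list(chains = chains, warmup = warmup, draws = draws,
                 extend_step = extend_step, max_draws = max_draws,
                 rhat_max = rhat_max, min_ess = min_ess,
                 sweeps_per_draw = sweeps_per_draw, seed = seed,
                 loglik_draws = loglik_draws, refit_attempts = refit_attempts,
                 quiet = quiet),
            class = "ditree_control")
}

# ---- parameter bookkeeping --------------------------------------------------

# Reference discrimination for each category intercept: the ideal-point
# process of the intercept's node if there is one, else the first process.
# Intercepts are sampled as tau / reference-discrimination (a threshold-scale
# coordinate), which straightens the scale ridges of saturating ideal-point
# items: the ratio is well identified even where the discrimination is not.
tau_ref_names <- function(spec) {
  out <- character(0)
  for (nd in spec$nodes) {
    ip <- vapply(nd$processes, function(p) p$kind == "ideal_point", TRUE)
    ref <- nd$processes[[if (any(ip)) which(ip)[1] else 1L]]$disc
    out[nd$tau] <- ref
  }
  out
}

# Free-parameter map. Full models free every (item, parameter) pair;
# constrained warm-start models share discriminations and intercepts across
# items while locations stay item-specific.
make_par_map <- function(spec, constrained = FALSE) {
  ptab <- spec$params
  refs <- tau_ref_names(spec)
  ptab$ref <- refs[ptab$name]
  I <- spec$I
  free_names <- character(0)
  free_type <- character(0)
  idx <- matrix(0L, I, nrow(ptab))
  colnames(idx) <- ptab$name
  for (p in seq_len(nrow(ptab))) {
    shared <- constrained && ptab$type[p] != "loc"
    if (shared) {
      free_names <- c(free_names, ptab$name[p])
      free_type <- c(free_type, ptab$type[p])
      idx[, p] <- length(free_names)
    } else {
      nm <- paste0(ptab$name[p], "[", seq_len(I), "]")
      idx[, p] <- length(free_names) + seq_len(I)
      free_names <- c(free_names, nm)
      free_type <- c(free_type, rep(ptab$type[p], I))
    }
  }
  # split the free parameters into per-item blocks (parameters appearing in a
  # single item's row) and one block shared across items
  counts <- tabulate(as.vector(idx), nbins = length(free_names))
  item_free <- lapply(seq_len(I), function(i)
    unique(idx[i, ][counts[idx[i, ]] == 1L]))
  shared_free <- which(counts > 1L)
  # reference-discrimination free index for every intercept free parameter
  tau_ref_free <- integer(length(free_names))
  for (p in seq_len(nrow(ptab))) {
    if (ptab$type[p] != "tau") next
    refcol <- match(ptab$ref[p], ptab$name)
    for (i in seq_len(I)) tau_ref_free[idx[i, p]] <- idx[i, refcol]
  }
  list(free_names = free_names, free_type = free_type, idx = idx,
       ptab = ptab, I = I, constrained = constrained,
       item_free = item_free, shared_free = shared_free,
       tau_ref_free = tau_ref_free,
       loc_free = which(free_type == "loc"),
       disc_free = which(free_type == "disc"))
}

# phi is on the sampling scale: log for discriminations, threshold-scale
# (tau / reference discrimination) for intercepts; ipar is natural
build_ipar <- function(phi, map) {
  m <- matrix(phi[map$idx], map$I, ncol(map$idx))
  disc_cols <- which(map$ptab$type == "disc")
  if (length(disc_cols)) m[, disc_cols] <- exp(m[, disc_cols])
  for (p in which(map$ptab$type == "tau")) {
    refcol <- match(map$ptab$ref[p], map$ptab$name)
    m[, p] <- m[, p] * m[, refcol]
  }
  colnames(m) <- map$ptab$name
  m
}

# single item row of the natural parameter matrix
build_ipar_row <- function(phi, map, i) {
  v <- phi[map$idx[i, ]]
  disc <- which(map$ptab$type == "disc")
  v[disc] <- exp(v[disc])
  for (p in which(map$ptab$type == "tau")) {
    v[p] <- v[p] * v[match(map$ptab$ref[p], map$ptab$name)]
  }
  matrix(v, 1, dimnames = list(NULL, map$ptab$name))
}

# stored draws hold final natural values; placement only
build_ipar_natural <- function(phi_nat, map) {
  m <- matrix(phi_nat[map$idx], map$I, ncol(map$idx))
  colnames(m) <- map$ptab$name
  m
}

phi_to_natural <- function(phi, map) {
  out <- phi
  disc <- map$free_type == "disc"
  out[disc] <- exp(out[disc])
  tau <- which(map$free_type == "tau")
  out[tau] <- out[tau] * out[map$tau_ref_free[tau]]
  names(out) <- map$free_names
  out
}

natural_to_phi <- function(phi_nat, map) {
  out <- phi_nat
  tau <- which(map$free_type == "tau")
  out[tau] <- out[tau] / phi_nat[map$tau_ref_free[tau]]
  disc <- map$free_type == "disc"
  out[disc] <- log(out[disc])
  out
}

# adaptive-Metropolis block state: proposal covariance learned from the
# chain's own history (Haario-style), with a scalar log step size tuned
# toward a 0.25 acceptance rate
new_amh <- function(d) {
  list(d = d, n = 0L, mean = rep(0, d), M2 = matrix(0, d, d),
       ls = 0, L = diag(0.05, d))
}

amh_learn <- function(a, x) {
  a$n <- a$n + 1L
  delta <- x - a$mean
  a$mean <- a$mean + delta / a$n
  a$M2 <- a$M2 + tcrossprod(delta, x - a$mean)
  a
}

amh_refresh <- function(a) {
  if (a$n < 20L) return(a)
  S <- a$M2 / (a$n - 1L) * (2.38^2 / a$d) + diag(1e-8, a$d)
  L <- tryCatch(t(chol(S)), error = function(e) NULL)
  if (!is.null(L)) a$L <- L
  a
}

# Univariate slice sampling (stepping out + shrinkage) along a direction in
# a block's parameter space. Directions drawn through the learned proposal
# covariance travel along flat posterior ridges that defeat random-walk
# steps; a slice move crosses such a ridge in one update.
slice_along <- function(lp, x0, dir, w = 1, max_step = 8L) {
  f0 <- lp(x0)
  if (!is.finite(f0)) return(x0)
  y <- f0 - stats::rexp(1)
  lo <- -w * runif(1)
  hi <- lo + w
  k <- max_step
  while (k > 0 && lp(x0 + lo * dir) > y) { lo <- lo - w; k <- k - 1 }
  k <- max_step
  while (k > 0 && lp(x0 + hi * dir) > y) { hi <- hi + w; k <- k - 1 }
  for (r in 1:20) {
    t <- runif(1, lo, hi)
    if (lp(x0 + t * dir) > y) return(x0 + t * dir)
    if (t < 0) lo <- t else hi <- t
  }
  x0
}

# Refine per-item initial values to the mode of their conditional posterior
# given the warm-start person parameters. The per-item posterior can have
# minor local modes; starting every chain at the dominant mode keeps chains
# from committing to different basins during warmup.
refine_item_inits <- function(phi, theta, X, comp, map, priors, hyper) {
  H <- comp$H
  for (i in seq_len(map$I)) {
    J <- map$item_free[[i]]
    if (!length(J)) next
    Xi <- X[, (i - 1L) * H + seq_len(H), drop = FALSE]
    obj <- function(par) {
      phi_i <- phi
      phi_i[J] <- par
      ipar_i <- build_ipar(phi_i, map)[i, , drop = FALSE]
      ll <- tree_loglik(theta, ipar_i, Xi, comp, reduce = "sum")
      -(ll + block_logprior(phi_i, J, map, priors, hyper))
    }
    opt <- tryCatch(
      stats::optim(phi[J], obj, method = "Nelder-Mead",
                   control = list(maxit = 400)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value)) phi[J] <- opt$par
  }
  phi
}

# log prior of one block of free parameters, on the sampling scale (the
# intercept coordinate carries the Jacobian of tau = u * ref_discrimination)
block_logprior <- function(phi, J, map, priors, hyper) {
  tp <- map$free_type[J]
  s <- 0
  d <- J[tp == "disc"]
  if (length(d)) {
    s <- s + sum(dgamma(exp(phi[d]), priors$disc_shape,
                        rate = priors$disc_rate, log = TRUE) + phi[d])
  }
  l <- J[tp == "loc"]
  if (length(l)) {
    s <- s + sum(dnorm(phi[l], hyper$mu, exp(hyper$log_sd), log = TRUE))
  }
  u <- J[tp == "tau"]
  if (length(u)) {
    dn <- exp(phi[map$tau_ref_free[u]])
    s <- s + sum(dnorm(phi[u] * dn, 0, priors$tau_sd, log = TRUE) + log(dn))
  }
  s
}

#' Align initial values with a scale orientation
#'
#' Ideal-point models leave the orientation of the latent continuum
#' unidentified: flipping the signs of all trait levels and item locations
#' jointly leaves the likelihood unchanged. A sign template (one `+1`/`-1`
#' per item, from the generating parameters or a reference analysis) picks one
#' of the two solutions. If the majority of location inits disagrees with the
#' template, the whole solution (locations and the ideal-point trait) is
#' flipped; every location init then carries the template's sign.
#'
#' @param inits List with `theta` (persons x traits matrix with named columns)
#'   and `delta` (numeric vector of location inits, one per item).
#' @param sign_template Vector of `+1`/`-1`, one per item (zero is an error).
#' @param flip_trait Name of the trait column to flip jointly with the
#'   locations.
#' @return The adjusted `inits` list.
#' @export
fix_orientation <- function(inits, sign_template, flip_trait = "theta") {
  if (any(sign_template == 0)) {
    stop("sign_template must contain only +1 / -1 (zero signs are ambiguous)",
         call. = FALSE)
  }
  sign_template <- sign(sign_template)
  d <- inits$delta
  if (is.null(d)) return(inits)
  stopifnot(length(d) == length(sign_template))
  nz <- d != 0
  if (any(nz) && mean(sign(d[nz]) == sign_template[nz]) < 0.5) {
    d <- -d
    if (!is.null(inits$theta) && flip_trait %in% colnames(inits$theta)) {
      inits$theta[, flip_trait] <- -inits$theta[, flip_trait]
    }
  }
  mag <- abs(d)
  mag[mag == 0] <- 1
  inits$delta <- mag * sign_template
  inits
}

# ---- response-time state (joint model) -------------------------------------

rt_gamma_names <- c("gamma_intercept", "gamma_middle", "gamma_extreme",
                    "gamma_mrs_middle", "gamma_ers_extreme", "gamma_distance")

prep_rt_data <- function(responses, rt, map) {
  des <- build_rt_design(responses)
  mask <- !is.na(rt) & !is.na(responses)
  logRT <- log(rt)
  logRT[!mask] <- NA_real_
  list(logRT = logRT, middle = des$middle, extreme = des$extreme, mask = mask,
       col_tau2 = match("tau2_1", map$ptab$name),
       col_alpha2 = match("alpha2", map$ptab$name))
}

# conditional mean of log RT given current latent state
rt_mean_matrix <- function(theta, ipar, rtd, gamma, u_p, u_i) {
  beta2 <- ipar[, rtd$col_tau2] / ipar[, rtd$col_alpha2]
  dist <- abs(outer(theta[, "theta"], beta2, `-`))
  gamma[1] +
    (gamma[2] + gamma[4] * theta[, "eta1"]) * rtd$middle +
    (gamma[3] + gamma[5] * theta[, "eta2"]) * rtd$extreme +
    gamma[6] * dist +
    matrix(u_p, nrow(dist), ncol(dist)) +
    matrix(u_i, nrow(dist), ncol(dist), byrow = TRUE)
}

rt_ll <- function(theta, ipar, rtd, rt_state, reduce) {
  mu <- rt_mean_matrix(theta, ipar, rtd, rt_state$gamma, rt_state$u_p,
                       rt_state$u_i)
  sd_e <- exp(rt_state$log_sds[3])
  ll <- dnorm(rtd$logRT, mu, sd_e, log = TRUE)
  ll[!rtd$mask] <- 0
  switch(reduce,
         person = rowSums(ll),
         item = colSums(ll),
         sum = sum(ll))
}

# ---- the sampler ------------------------------------------------------------

# One full update sweep over persons, item-parameter blocks, hyperparameters
# and (for joint models) the RT block. Operates on an environment `e` holding
# the chain state; returns nothing. Proposal scales and covariances adapt
# throughout sampling with a vanishing rate (diminishing adaptation), which
# lets the learned covariance grow to span long flat posterior ridges.
mwg_sweep <- function(e) {
  ctx <- e$ctx
  gam <- min(0.25, 2 / sqrt(e$sweep + 1))
  adapt <- TRUE

  # persons: joint random-walk proposal on all trait dimensions
  pri_old <- rowSums(dnorm(e$theta, 0, 1, log = TRUE))
  ll_old <- tree_loglik(e$theta, e$ipar, ctx$X, ctx$comp, reduce = "person")
  if (!is.null(ctx$rtd)) ll_old <- ll_old + rt_ll(e$theta, e$ipar, ctx$rtd, e$rt, "person")
  prop <- e$theta + matrix(rnorm(length(e$theta)), nrow(e$theta)) * e$s_person
  pri_new <- rowSums(dnorm(prop, 0, 1, log = TRUE))
  ll_new <- tree_loglik(prop, e$ipar, ctx$X, ctx$comp, reduce = "person")
  if (!is.null(ctx$rtd)) ll_new <- ll_new + rt_ll(prop, e$ipar, ctx$rtd, e$rt, "person")
  acc <- log(runif(nrow(prop))) < (ll_new + pri_new) - (ll_old + pri_old)
  e$theta[acc, ] <- prop[acc, ]
  if (adapt) e$s_person <- exp(log(e$s_person) + gam * (acc - 0.30))

  # item parameters: per-item adaptive-covariance blocks, proposed jointly
  # for all items and accepted item-wise (the likelihood factorizes over
  # items given the person parameters)
  map <- ctx$map
  if (any(lengths(map$item_free) > 0L)) {
    phi2 <- e$phi
    for (i in seq_len(map$I)) {
      J <- map$item_free[[i]]
      if (!length(J)) next
      a <- e$amh_items[[i]]
      phi2[J] <- e$phi[J] + exp(a$ls) * drop(a$L %*% rnorm(length(J)))
    }
    ipar2 <- build_ipar(phi2, map)
    ll_old <- tree_loglik(e$theta, e$ipar, ctx$X, ctx$comp, reduce = "item")
    ll_new <- tree_loglik(e$theta, ipar2, ctx$X, ctx$comp, reduce = "item")
    if (!is.null(ctx$rtd)) {
      ll_old <- ll_old + rt_ll(e$theta, e$ipar, ctx$rtd, e$rt, "item")
      ll_new <- ll_new + rt_ll(e$theta, ipar2, ctx$rtd, e$rt, "item")
    }
    for (i in seq_len(map$I)) {
      J <- map$item_free[[i]]
      if (!length(J)) next
      pri_old <- block_logprior(e$phi, J, map, ctx$priors, e$hyper)
      pri_new <- block_logprior(phi2, J, map, ctx$priors, e$hyper)
      acc <- log(runif(1)) < (ll_new[i] + pri_new) - (ll_old[i] + pri_old)
      if (acc) e$phi[J] <- phi2[J]
      if (adapt) {
        a <- e$amh_items[[i]]
        a$ls <- a$ls + gam * (acc - 0.25)
        a <- amh_learn(a, e$phi[J])
        if (e$sweep %% 25L == 24L) a <- amh_refresh(a)
        e$amh_items[[i]] <- a
      }
    }
    e$ipar <- build_ipar(e$phi, map)

    # slice moves along random learned-covariance directions
    H <- ctx$comp$H
    for (i in seq_len(map$I)) {
      J <- map$item_free[[i]]
      if (!length(J)) next
      a <- e$amh_items[[i]]
      dir <- drop(a$L %*% rnorm(length(J)))
      Xi <- ctx$X[, (i - 1L) * H + seq_len(H), drop = FALSE]
      lp <- function(bx) {
        phi_i <- e$phi
        phi_i[J] <- bx
        ipar_i <- build_ipar_row(phi_i, map, i)
        ll <- tree_loglik(e$theta, ipar_i, Xi, ctx$comp, reduce = "sum")
        if (!is.null(ctx$rtd)) {
          full <- e$ipar
          full[i, ] <- ipar_i
          ll <- ll + rt_ll(e$theta, full, ctx$rtd, e$rt, "item")[i]
        }
        ll + block_logprior(phi_i, J, map, ctx$priors, e$hyper)
      }
      e$phi[J] <- slice_along(lp, e$phi[J], dir)
      if (adapt) e$amh_items[[i]] <- amh_learn(e$amh_items[[i]], e$phi[J])
    }
    e$ipar <- build_ipar(e$phi, map)
  }

  # parameters shared across items (constrained warm-start models)
  if (length(map$shared_free)) {
    J <- map$shared_free
    a <- e$amh_shared
    phi2 <- e$phi
    phi2[J] <- e$phi[J] + exp(a$ls) * drop(a$L %*% rnorm(length(J)))
    ipar2 <- build_ipar(phi2, map)
    ll_old <- tree_loglik(e$theta, e$ipar, ctx$X, ctx$comp, reduce = "sum")
    ll_new <- tree_loglik(e$theta, ipar2, ctx$X, ctx$comp, reduce = "sum")
    if (!is.null(ctx$rtd)) {
      ll_old <- ll_old + rt_ll(e$theta, e$ipar, ctx$rtd, e$rt, "sum")
      ll_new <- ll_new + rt_ll(e$theta, ipar2, ctx$rtd, e$rt, "sum")
    }
    accS <- log(runif(1)) <
      (ll_new + block_logprior(phi2, J, map, ctx$priors, e$hyper)) -
      (ll_old + block_logprior(e$phi, J, map, ctx$priors, e$hyper))
    if (accS) {
      e$phi <- phi2
      e$ipar <- ipar2
    }
    if (adapt) {
      a$ls <- a$ls + gam * (accS - 0.25)
      a <- amh_learn(a, e$phi[J])
      if (e$sweep %% 25L == 24L) a <- amh_refresh(a)
      e$amh_shared <- a
    }
  }

  # hierarchical location prior hyperparameters
  if (!is.null(e$hyper)) {
    d <- e$phi[map$loc_free]
    sd_d <- exp(e$hyper$log_sd)
    v <- 1 / (1 / ctx$priors$delta_mean_sd^2 + length(d) / sd_d^2)
    e$hyper$mu <- rnorm(1, v * sum(d) / sd_d^2, sqrt(v))
    prop <- e$hyper$log_sd + rnorm(1) * e$s_hyper
    lp <- function(ls) {
      s <- exp(ls)
      sum(dnorm(d, e$hyper$mu, s, log = TRUE)) +
        dnorm(s, 0, ctx$priors$delta_sd_sd, log = TRUE) + ls
    }
    accH <- log(runif(1)) < lp(prop) - lp(e$hyper$log_sd)
    if (accH) e$hyper$log_sd <- prop
    if (adapt) e$s_hyper <- exp(log(e$s_hyper) + gam * (accH - 0.44))
  }

  # joint response-time block
  if (!is.null(ctx$rtd)) rt_sweep(e, ctx, gam, adapt)

  e$sweep <- e$sweep + 1
  invisible(NULL)
}

rt_sweep <- function(e, ctx, gam, adapt) {
  rtd <- ctx$rtd
  mask <- rtd$mask
  sd_e <- exp(e$rt$log_sds[3])
  beta2 <- e$ipar[, rtd$col_tau2] / e$ipar[, rtd$col_alpha2]
  N <- nrow(rtd$logRT); I <- ncol(rtd$logRT)
  dist <- abs(outer(e$theta[, "theta"], beta2, `-`))

  # fixed effects: conjugate normal update given latents and random effects
  y <- rtd$logRT - matrix(e$rt$u_p, N, I) - matrix(e$rt$u_i, N, I, byrow = TRUE)
  Zl <- cbind(1, as.vector(rtd$middle), as.vector(rtd$extreme),
              as.vector(rtd$middle * e$theta[, "eta1"]),
              as.vector(rtd$extreme * e$theta[, "eta2"]),
              as.vector(dist))[as.vector(mask), , drop = FALSE]
  yv <- as.vector(y)[as.vector(mask)]
  prec <- crossprod(Zl) / sd_e^2 + diag(6) / ctx$priors$rt_coef_sd^2
  ch <- chol(prec)
  m <- backsolve(ch, backsolve(ch, crossprod(Zl, yv) / sd_e^2, transpose = TRUE))
  e$rt$gamma <- drop(m + backsolve(ch, rnorm(6)))

  # random intercepts: conjugate given everything else
  mu_fix <- rt_mean_matrix(e$theta, e$ipar, rtd, e$rt$gamma, rep(0, N), rep(0, I))
  resid <- rtd$logRT - mu_fix
  resid[!mask] <- 0
  sd_p <- exp(e$rt$log_sds[1]); sd_i <- exp(e$rt$log_sds[2])
  n_v <- rowSums(mask)
  v_p <- 1 / (1 / sd_p^2 + n_v / sd_e^2)
  e$rt$u_p <- rnorm(N, v_p * rowSums(resid - matrix(e$rt$u_i, N, I, byrow = TRUE) * mask) / sd_e^2, sqrt(v_p))
  n_i <- colSums(mask)
  v_i <- 1 / (1 / sd_i^2 + n_i / sd_e^2)
  e$rt$u_i <- rnorm(I, v_i * colSums(resid - matrix(e$rt$u_p, N, I) * mask) / sd_e^2, sqrt(v_i))

  # variance components: random-walk MH on the log scale, half-normal priors
  res_all <- (resid - matrix(e$rt$u_p, N, I) -
                matrix(e$rt$u_i, N, I, byrow = TRUE))[mask]
  lp_sd <- function(k, ls) {
    s <- exp(ls)
    ll <- switch(k,
                 sum(dnorm(e$rt$u_p, 0, s, log = TRUE)),
                 sum(dnorm(e$rt$u_i, 0, s, log = TRUE)),
                 sum(dnorm(res_all, 0, s, log = TRUE)))
    ll + dnorm(s, 0, ctx$priors$rt_sd_scale, log = TRUE) + ls
  }
  for (k in 1:3) {
    prop <- e$rt$log_sds[k] + rnorm(1) * e$rt$s_sds[k]
    accS <- log(runif(1)) < lp_sd(k, prop) - lp_sd(k, e$rt$log_sds[k])
    if (accS) e$rt$log_sds[k] <- prop
    if (adapt) e$rt$s_sds[k] <- exp(log(e$rt$s_sds[k]) + gam * (accS - 0.44))
  }
}

# snapshot the current state as one stored draw (natural scale)
state_draw <- function(e, ctx) {
  th <- e$theta
  trait_cols <- unlist(lapply(colnames(th), function(tr)
    stats::setNames(th[, tr], paste0(tr, "[", seq_len(nrow(th)), "]"))))
  out <- c(trait_cols, phi_to_natural(e$phi, ctx$map))
  if (!is.null(e$hyper)) {
    out <- c(out, delta_mu = e$hyper$mu, delta_sd = exp(e$hyper$log_sd))
  }
  if (!is.null(e$rt)) {
    out <- c(out, stats::setNames(e$rt$gamma, rt_gamma_names),
             rt_sd_person = exp(e$rt$log_sds[1]),
             rt_sd_item = exp(e$rt$log_sds[2]),
             rt_sd_resid = exp(e$rt$log_sds[3]),
             stats::setNames(e$rt$u_p, paste0("u_person[", seq_along(e$rt$u_p), "]")),
             stats::setNames(e$rt$u_i, paste0("u_item[", seq_along(e$rt$u_i), "]")))
  }
  out
}

run_segment <- function(e, n_draws, warmup_sweeps = 0) {
  ctx <- e$ctx
  if (warmup_sweeps > 0) {
    for (s in seq_len(warmup_sweeps)) mwg_sweep(e)
  }
  if (n_draws == 0) return(NULL)
  first <- state_draw(e, ctx)
  draws <- matrix(NA_real_, n_draws, length(first))
  colnames(draws) <- names(first)
  for (d in seq_len(n_draws)) {
    for (s in seq_len(ctx$control$sweeps_per_draw)) mwg_sweep(e)
    draws[d, ] <- state_draw(e, ctx)
  }
  draws
}

new_chain_state <- function(ctx, inits, chain, seed) {
  set.seed(seed + 7901L * chain)
  N <- ctx$N
  Tr <- length(ctx$spec$traits)
  theta <- inits$theta
  if (is.null(theta)) theta <- matrix(0, N, Tr)
  theta <- theta + matrix(rnorm(N * Tr, 0, if (chain == 1) 0.05 else 0.15), N, Tr)
  colnames(theta) <- names(ctx$spec$traits)
  phi_nat <- inits$phi_natural
  if (is.null(phi_nat)) {
    phi_nat <- stats::setNames(rep(0, length(ctx$map$free_names)),
                               ctx$map$free_names)
    phi_nat[ctx$map$free_type == "disc"] <- 1
  }
  phi <- natural_to_phi(phi_nat, ctx$map)
  jit <- rnorm(length(phi), 0, if (chain == 1) 0.02 else 0.08)
  # keep location signs intact so all chains share the chosen orientation
  jit[ctx$map$free_type == "loc"] <- pmin(abs(jit[ctx$map$free_type == "loc"]),
                                          0.2) * sign(phi[ctx$map$free_type == "loc"])
  phi <- phi + jit
  e <- new.env(parent = emptyenv())
  e$ctx <- ctx
  e$theta <- theta
  e$phi <- phi
  e$ipar <- build_ipar(phi, ctx$map)
  e$s_person <- rep(0.5, N)
  e$amh_items <- lapply(ctx$map$item_free, function(J) new_amh(length(J)))
  e$amh_shared <- if (length(ctx$map$shared_free))
    new_amh(length(ctx$map$shared_free)) else NULL
  e$s_hyper <- 0.5
  e$hyper <- if (length(ctx$map$loc_free)) list(mu = 0, log_sd = 0) else NULL
  if (!is.null(ctx$rtd)) {
    mean_lrt <- mean(ctx$rtd$logRT[ctx$rtd$mask])
    e$rt <- list(gamma = c(mean_lrt, 0, 0, 0, 0, 0),
                 u_p = rep(0, N), u_i = rep(0, ncol(ctx$rtd$logRT)),
                 log_sds = log(c(0.3, 0.1, 0.5)), s_sds = rep(0.3, 3))
  }
  e$sweep <- 0
  e
}

# ---- top-level fitting ------------------------------------------------------

#' Fit an IRTree model with DI-MIRT pseudo-items by MCMC
#'
#' Bayesian estimation by adaptive Metropolis-within-Gibbs: joint random-walk
#' proposals for persons; per-item parameter blocks updated by adaptive
#' Metropolis with covariance learned from the chain history (diminishing
#' adaptation) plus slice moves along learned-covariance directions, which
#' traverse the flat likelihood ridges of weakly constrained ideal-point
#' items; conjugate updates for hierarchical hyperparameters and, in joint
#' models, for response-time fixed and random effects. Intercepts are sampled
#' on the threshold scale (tau divided by the node's reference
#' discrimination). By default a constrained warm-start model
#' (discriminations and intercepts shared across items) is fitted first with a
#' single short chain, and its EAP estimates initialize the full model.
#' Sampling is extended adaptively until all parameters satisfy the R-hat and
#' ESS thresholds in `control`, or `max_draws` is reached (then flagged).
#' If the model contains free ideal-point locations, the latent orientation is
#' fixed through `sign_template`; a fit whose location estimates contradict
#' the template is refitted with a different seed.
#'
#' @param responses Integer matrix (persons x items), categories `0..K_scale`,
#'   `NA` for missing responses (dropped item-wise).
#' @param spec A `ditree_spec` (e.g. [irtree_ideal_ers()], [irtree_midscale()]).
#' @param priors A [ditree_priors()].
#' @param control A [mcmc_control()].
#' @param sign_template `+1`/`-1` per item fixing the orientation of the
#'   latent continuum (required reading: [fix_orientation()]). Defaults to all
#'   `+1` when the model has free locations.
#' @param inits Optional list with `theta` (persons x traits) and
#'   `phi_natural` (named vector of item parameters); overrides the warm start.
#' @param warm_start Fit the constrained model first to create initial values.
#' @param constrained Fit the constrained model itself (shared
#'   discriminations/intercepts; used internally by the warm start).
#' @param rt Optional positive matrix of response times (persons x items) for
#'   the joint response-time model (five-point midscale trees only).
#' @return An object of class `ditree_fit`.
#' @export
fit_irtree <- function(responses, spec, priors = ditree_priors(),
                       control = mcmc_control(), sign_template = NULL,
                       inits = NULL, warm_start = TRUE, constrained = FALSE,
                       rt = NULL) {
  stopifnot(inherits(spec, "ditree_spec"))
  responses <- as.matrix(responses)
  if (ncol(responses) != spec$I) {
    stop(sprintf("spec expects %d items, data has %d columns", spec$I,
                 ncol(responses)), call. = FALSE)
  }
  ymax <- max(responses, na.rm = TRUE)
  if (ymax > spec$scale_points - 1L || min(responses, na.rm = TRUE) < 0L) {
    stop("responses outside the spec's category range", call. = FALSE)
  }
  map <- make_par_map(spec, constrained = constrained)
  has_loc <- length(map$loc_free) > 0L
  if (is.null(sign_template) && has_loc) sign_template <- rep(1, spec$I)

  X <- decompose_matrix(responses, spec$mapping)
  X[is.na(X)] <- -1L
  comp <- compile_spec(spec)
  rtd <- NULL
  if (!is.null(rt)) {
    if (spec$scale_points != 5L) {
      stop("the joint response-time model requires a five-point midscale tree",
           call. = FALSE)
    }
    rtd <- prep_rt_data(responses, rt, map)
  }

  ctx <- list(spec = spec, map = map, comp = comp, X = X, N = nrow(responses),
              priors = priors, control = control, rtd = rtd)

  # constrained warm start
  warm <- NULL
  if (is.null(inits) && warm_start && !constrained) {
    warm <- fit_constrained_warmstart(responses, spec, priors, control,
                                      sign_template)
    inits <- warm$inits
  }
  if (is.null(inits)) {
    inits <- list(theta = NULL, phi_natural = NULL)
    if (has_loc) {
      phi_nat <- stats::setNames(rep(0, length(map$free_names)), map$free_names)
      phi_nat[map$free_type == "disc"] <- 1
      phi_nat[map$loc_free] <- rep(sign_template, length.out = length(map$loc_free))
      inits$phi_natural <- phi_nat
    }
  }

  # start all chains at the dominant mode of each item's conditional
  # posterior given the warm-start person parameters
  if (!constrained) {
    phi0 <- if (!is.null(inits$phi_natural)) {
      natural_to_phi(inits$phi_natural, map)
    } else {
      z <- numeric(length(map$free_names))
      z[map$loc_free] <- rep(sign_template, length.out = length(map$loc_free))
      z
    }
    theta0 <- inits$theta
    if (is.null(theta0)) {
      theta0 <- matrix(0, nrow(responses), length(spec$traits))
    }
    colnames(theta0) <- names(spec$traits)
    hyper0 <- list(mu = 0, log_sd = log(2.5))
    phi0 <- refine_item_inits(phi0, theta0, X, comp, map, priors, hyper0)
    inits$phi_natural <- phi_to_natural(phi0, map)
    inits$theta <- theta0
  }

  n_chains <- if (constrained) 1L else control$chains
  n_draws0 <- if (constrained) control$warmup else control$draws

  attempt <- 0
  seed <- control$seed
  repeat {
    attempt <- attempt + 1
    states <- lapply(seq_len(n_chains), function(ch)
      new_chain_state(ctx, inits, ch, seed))
    chains <- vector("list", n_chains)
    for (ch in seq_len(n_chains)) {
      set.seed(seed + 7901L * ch + 13L)
      chains[[ch]] <- run_segment(states[[ch]],
                                  n_draws = n_draws0,
                                  warmup_sweeps = control$warmup *
                                    control$sweeps_per_draw)
    }
    total <- n_draws0
    extensions <- 0L
    diag <- NULL
    converged <- TRUE
    if (!constrained) {
      repeat {
        diag <- diagnose_draws(chains)
        ok <- max(diag$rhat, na.rm = TRUE) <= control$rhat_max &&
          min(diag$ess_bulk, na.rm = TRUE) >= control$min_ess &&
          min(diag$ess_tail, na.rm = TRUE) >= control$min_ess
        if (ok) { converged <- TRUE; break }
        if (total >= control$max_draws) { converged <- FALSE; break }
        step <- min(control$extend_step, control$max_draws - total)
        for (ch in seq_len(n_chains)) {
          set.seed(seed + 7901L * ch + 131L * (extensions + 2L))
          chains[[ch]] <- rbind(chains[[ch]], run_segment(states[[ch]], step))
        }
        total <- total + step
        extensions <- extensions + 1L
        if (!control$quiet) {
          message(sprintf("extended sampling to %d draws per chain", total))
        }
      }
    }
    pooled <- do.call(rbind, chains)
    eap <- colMeans(pooled)
    orientation_ok <- TRUE
    if (has_loc && !constrained) {
      d_eap <- eap[paste0("delta[", seq_len(spec$I), "]")]
      orientation_ok <- mean(sign(d_eap[d_eap != 0]) ==
                               sign_template[d_eap != 0]) >= 0.5
    }
    # a chain occasionally commits to a local maximum or the inverted
    # orientation; in both cases the model is refitted with a different seed
    if ((orientation_ok && converged) || constrained ||
          attempt > control$refit_attempts) break
    seed <- seed + 1000L
    if (!control$quiet) {
      message(if (orientation_ok) "not converged; refitting with a new seed"
              else "orientation flipped; refitting with a new seed")
    }
  }

  fit <- structure(
    list(spec = spec, map = map, comp = comp, chains = chains,
         eap = eap, diagnostics = diag, converged = converged &&
           orientation_ok,
         orientation_ok = orientation_ok, extensions = extensions,
         total_draws = total, control = control, priors = priors,
         sign_template = sign_template, warm_start = warm$estimates,
         responses = responses, X = X, rt = rt, rtd = rtd,
         N = nrow(responses), constrained = constrained,
         seed_used = seed, attempts = attempt),
    class = "ditree_fit"
  )
  if (!constrained) fit$loglik <- loglik_matrix(fit)
  fit
}

#' Constrained warm-start fit
#'
#' Fits the constrained variant of a tree model (discriminations and category
#' intercepts shared across items, locations item-specific) with a single
#' short chain, and expands its EAP estimates item-wise into initial values
#' for the full model. The location inits are aligned with the sign template
#' via [fix_orientation()].
#'
#' @inheritParams fit_irtree
#' @return List with `estimates` (EAPs of the constrained model) and `inits`
#'   (initial values for [fit_irtree()]).
#' @export
fit_constrained_warmstart <- function(responses, spec,
                                      priors = ditree_priors(),
                                      control = mcmc_control(),
                                      sign_template = NULL) {
  ctrl <- control
  ctrl$chains <- 1L
  cfit <- fit_irtree(responses, spec, priors, ctrl,
                     sign_template = sign_template,
                     warm_start = FALSE, constrained = TRUE)
  eap <- cfit$eap
  full_map <- make_par_map(spec, constrained = FALSE)
  I <- spec$I
  phi_nat <- stats::setNames(numeric(length(full_map$free_names)),
                             full_map$free_names)
  for (p in seq_len(nrow(full_map$ptab))) {
    nm <- full_map$ptab$name[p]
    vals <- if (nm %in% names(eap)) rep(eap[[nm]], I)
            else eap[paste0(nm, "[", seq_len(I), "]")]
    phi_nat[paste0(nm, "[", seq_len(I), "]")] <- vals
  }
  traits <- names(spec$traits)
  theta <- vapply(traits, function(tr)
    eap[paste0(tr, "[", seq_len(nrow(responses)), "]")], numeric(nrow(responses)))
  colnames(theta) <- traits
  inits <- list(theta = theta, phi_natural = phi_nat)
  if (length(full_map$loc_free) && !is.null(sign_template)) {
    delta <- phi_nat[paste0("delta[", seq_len(I), "]")]
    adj <- fix_orientation(list(theta = theta, delta = delta), sign_template)
    inits$theta <- adj$theta
    inits$phi_natural[paste0("delta[", seq_len(I), "]")] <- adj$delta
  }
  list(estimates = eap, inits = inits, fit = cfit)
}

#' Posterior means of all parameters
#'
#' @param fit A `ditree_fit`.
#' @return Named numeric vector of EAP estimates (pooled post-warmup draws).
#' @export
eap_estimates <- function(fit) {
  stopifnot(inherits(fit, "ditree_fit"))
  fit$eap
}

# pointwise log-likelihood of the observed ordinal responses, evaluated on a
# pooled, evenly thinned subset of the stored draws
loglik_matrix <- function(fit, max_draws = fit$control$loglik_draws) {
  pooled <- do.call(rbind, fit$chains)
  S <- nrow(pooled)
  keep <- if (S > max_draws) round(seq(1, S, length.out = max_draws)) else seq_len(S)
  traits <- names(fit$spec$traits)
  N <- fit$N
  tcols <- lapply(traits, function(tr) match(paste0(tr, "[", seq_len(N), "]"),
                                             colnames(pooled)))
  pcols <- match(fit$map$free_names, colnames(pooled))
  obs_mask <- !is.na(fit$responses)
  out <- matrix(NA_real_, length(keep), sum(obs_mask))
  for (s in seq_along(keep)) {
    row <- pooled[keep[s], ]
    theta <- vapply(tcols, function(j) row[j], numeric(N))
    colnames(theta) <- traits
    ipar <- build_ipar_natural(row[pcols], fit$map)
    llm <- tree_loglik(theta, ipar, fit$X, fit$comp, reduce = "matrix")
    out[s, ] <- llm[obs_mask]
  }
  out
}

#' PSIS-LOO for a fitted IRTree model
#'
#' @param x A `ditree_fit`.
#' @param ... Unused.
#' @return A `ditree_loo` object (see [psis_loo()]).
#' @export
loo <- function(x, ...) UseMethod("loo")

#' @rdname loo
#' @export
loo.ditree_fit <- function(x, ...) {
  if (is.null(x$loglik)) stop("fit carries no pointwise log-likelihood",
                              call. = FALSE)
  psis_loo(x$loglik)
}

#' @export
print.ditree_fit <- function(x, ...) {
  cat(sprintf("IRTree fit: model %s, N = %d, I = %d%s\n", x$spec$model, x$N,
              x$spec$I, if (x$constrained) " (constrained warm-start model)" else ""))
  cat(sprintf("%d chain(s), %d stored draws each (%d extension(s))\n",
              length(x$chains), x$total_draws, x$extensions))
  if (!is.null(x$diagnostics)) {
    cat(sprintf("max R-hat %.3f, min bulk ESS %.0f, min tail ESS %.0f -- %s\n",
                max(x$diagnostics$rhat, na.rm = TRUE),
                min(x$diagnostics$ess_bulk, na.rm = TRUE),
                min(x$diagnostics$ess_tail, na.rm = TRUE),
                if (x$converged) "converged" else "NOT converged"))
  }
  invisible(x)
}

#' Fit the joint model of responses and response times
#'
#' One posterior over the five-point midscale IRTree parameters and the
#' log-RT linear mixed model: log RTs are normal with fixed effects for the
#' manifest midscale/extreme indicators, cross-level interactions with the
#' MRS and ERS levels, the latent person-item distance `|theta - beta_2|`
#' (the same quantity that drives the midscale node's ideal-point process),
#' and random person and item intercepts.
#'
#' @inheritParams fit_irtree
#' @param rt Positive matrix of response times in seconds (persons x items).
#' @return A `ditree_fit` with RT coefficients among the parameters; see
#'   [rt_fixed_effects()].
#' @export
fit_joint_rt_model <- function(responses, rt, spec = irtree_midscale(ncol(responses)),
                               priors = ditree_priors(),
                               control = mcmc_control(), ...) {
  if (any(rt <= 0, na.rm = TRUE)) stop("response times must be positive",
                                       call. = FALSE)
  fit_irtree(responses, spec, priors, control, rt = rt, ...)
}
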