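# Bayesian estimation: correctness against a quadrature oracle, orientation
# handling, warm start, convergence bookkeeping

test_that("posterior means match an exact quadrature oracle on a toy model", {
  spec <- toy_binary_spec(I = 3)
  set.seed(42)
  N <- 150
  th <- rnorm(N)
  a0 <- 1.2; t0 <- -0.4
  Y <- matrix(rbinom(N * 3, 1, stats::plogis(a0 * rep(th, 3) - t0)), N, 3)

  # constrained fit: one shared alpha and tau -> 2-d quadrature with theta
  # integrated out on a fine grid
  tg <- seq(-7, 7, length.out = 201)
  wg <- dnorm(tg); wg <- wg / sum(wg)
  ag <- seq(0.05, 5, length.out = 220)
  taug <- seq(-3, 2.5, length.out = 240)
  pat <- Y %*% c(1, 2, 4)
  cnt <- tabulate(pat + 1, 8)
  ysum <- vapply(0:7, function(k) (k %% 2) + (k %/% 2) %% 2 + (k %/% 4) %% 2, 0)
  lp <- matrix(NA_real_, length(ag), length(taug))
  for (i in seq_along(ag)) {
    p <- stats::plogis(ag[i] * tg)   # tau folded in below
    for (j in seq_along(taug)) {
      pj <- stats::plogis(ag[i] * tg - taug[j])
      pp <- vapply(0:7, function(k)
        sum(wg * pj^ysum[k + 1] * (1 - pj)^(3 - ysum[k + 1])), 0)
      lp[i, j] <- sum(cnt * log(pp)) +
        dgamma(ag[i], 1.5, rate = 1.5, log = TRUE) +
        dnorm(taug[j], 0, 5, log = TRUE)
    }
  }
  w <- exp(lp - max(lp)); w <- w / sum(w)
  eap_alpha_q <- sum(rowSums(w) * ag)
  eap_tau_q <- sum(colSums(w) * taug)

  ctrl <- mcmc_control(chains = 1, warmup = 2000, sweeps_per_draw = 2, seed = 3)
  fit <- fit_irtree(Y, spec, control = ctrl, warm_start = FALSE,
                    constrained = TRUE)
  expect_lt(abs(fit$eap[["alpha"]] - eap_alpha_q), 0.08)
  expect_lt(abs(fit$eap[["tau1_1"]] - eap_tau_q), 0.08)
})

test_that("sign-flipping traits and locations leaves the tree likelihood unchanged", {
  sim <- draw_population(sim_design("I-DI", N = 40, I = 4, seed = 61))
  Y <- simulate_responses(sim)
  spec <- sim$spec
  comp <- ditree:::compile_spec(spec)
  X <- ditree:::decompose_matrix(Y, spec$mapping); X[is.na(X)] <- -1L
  ipar <- ditree:::items_to_ipar(spec, sim$items)
  tm <- as.matrix(sim$persons[, c("theta", "eta")])
  ll1 <- ditree:::tree_loglik(tm, ipar, X, comp, reduce = "sum")
  ipar2 <- ipar; ipar2[, "delta"] <- -ipar2[, "delta"]
  tm2 <- tm; tm2[, "theta"] <- -tm2[, "theta"]
  ll2 <- ditree:::tree_loglik(tm2, ipar2, X, comp, reduce = "sum")
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("orientation fixing aligns inits with the sign template", {
  inits <- list(theta = cbind(theta = c(0.5, -1)), delta = c(2, -1, 0.5))
  out <- fix_orientation(inits, c(1, -1, 1))
  expect_equal(out$delta, c(2, -1, 0.5))
  expect_equal(out$theta[, "theta"], c(0.5, -1))
  # majority-inverted solution: everything flips jointly
  out2 <- fix_orientation(list(theta = cbind(theta = c(0.5, -1)),
                               delta = c(-2, 1, -0.5)), c(1, -1, 1))
  expect_equal(out2$delta, c(2, -1, 0.5))
  expect_equal(out2$theta[, "theta"], c(-0.5, 1))
  # unit-magnitude template start
  out3 <- fix_orientation(list(theta = NULL, delta = c(0, 0, 0)), c(1, -1, 1))
  expect_equal(out3$delta, c(1, -1, 1))
  expect_error(fix_orientation(inits, c(1, 0, 1)), "zero")
})

test_that("constrained warm start shares parameters and expands item-wise", {
  sim <- sim_dataset(sim_design("I-DI", N = 120, I = 5, seed = 63))
  ws <- fit_constrained_warmstart(sim$responses, sim$spec,
                                  control = quick_ctrl(),
                                  sign_template = sign(sim$items$delta))
  # constrained model has fewer free parameters than the full model
  n_con <- length(ditree:::make_par_map(sim$spec, TRUE)$free_names)
  n_full <- length(ditree:::make_par_map(sim$spec, FALSE)$free_names)
  expect_lt(n_con, n_full)
  # expanded inits: every item gets the same shared discrimination
  a <- ws$inits$phi_natural[paste0("alpha[", 1:5, "]")]
  expect_equal(unname(a), rep(unname(a[1]), 5))
  # locations follow the template's signs
  d <- ws$inits$phi_natural[paste0("delta[", 1:5, "]")]
  expect_equal(sign(unname(d)), unname(sign(sim$items$delta)))
  expect_equal(dim(ws$inits$theta), c(120L, 2L))
})

test_that("the extension loop respects the draw cap and records extensions", {
  sim <- sim_dataset(sim_design("I-DI", N = 60, I = 4, seed = 65))
  # deliberately short chains so extension triggers
  ctrl <- mcmc_control(chains = 2, warmup = 50, draws = 50, extend_step = 50,
                       max_draws = 150, sweeps_per_draw = 1, seed = 2,
                       loglik_draws = 100, refit_attempts = 0)
  fit <- fit_irtree(sim$responses, sim$spec, control = ctrl,
                    sign_template = sign(sim$items$delta))
  expect_lte(fit$total_draws, 150)
  expect_equal(nrow(fit$chains[[1]]), fit$total_draws)
  expect_gte(fit$extensions, 1)
  expect_false(fit$converged)   # far too few draws by construction
  expect_s3_class(glance(fit), "tbl_df")
  # every free parameter has diagnostics
  expect_true(all(!is.na(fit$diagnostics$rhat)))
  expect_equal(nrow(fit$diagnostics), ncol(fit$chains[[1]]))
})

test_that("a moderate fit recovers traits and carries a valid loglik matrix", {
  ref <- reference_idi_fit()
  fit <- ref$fit
  sim <- ref$sim
  pr <- person_recovery(fit, sim)
  expect_gt(pr$cor[pr$trait == "theta"], 0.7)
  expect_gt(pr$cor[pr$trait == "eta"], 0.6)
  # pointwise log-likelihood: draws x observed responses, all finite negative
  expect_equal(ncol(fit$loglik), sum(!is.na(sim$responses)))
  expect_true(all(is.finite(fit$loglik)))
  expect_true(all(fit$loglik < 0))
  # tidy() output is complete and joins diagnostics
  td <- tidy(fit, pars = "^delta\\[")
  expect_equal(nrow(td), 8)
  expect_true(all(c("estimate", "conf.low", "rhat", "ess_bulk") %in% names(td)))
  # orientation matches the generating template
  expect_true(fit$orientation_ok)
})

test_that("posterior credible intervals for persons are roughly calibrated", {
  ref <- reference_idi_fit()
  fit <- ref$fit
  sim <- ref$sim
  td <- tidy(fit, pars = "^theta\\[", level = 0.9)
  truth <- sim$persons$theta
  covered <- mean(truth >= td$conf.low & truth <= td$conf.high)
  # nominal 0.9; persons share item-parameter uncertainty, so the band is wide
  expect_gt(covered, 0.80)
  expect_lt(covered, 0.97)
})

test_that("missing responses are dropped item-wise, not person-wise", {
  sim <- sim_dataset(sim_design("I-DI", N = 80, I = 4, seed = 67))
  Y <- sim$responses
  Y[1, 1] <- NA; Y[2, ] <- NA
  fit <- fit_irtree(Y, sim$spec, control = quick_ctrl(),
                    sign_template = sign(sim$items$delta))
  expect_equal(ncol(fit$loglik), sum(!is.na(Y)))
  # the all-missing person's posterior is the prior (mean near 0, sd near 1)
  td <- tidy(fit, pars = "^theta\\[2\\]$")
  expect_lt(abs(td$estimate), 0.5)
  expect_gt(td$std.error, 0.6)
})

test_that("EAP estimates are means of the pooled draws", {
  ref <- reference_idi_fit()
  fit <- ref$fit
  pooled <- do.call(rbind, fit$chains)
  expect_equal(eap_estimates(fit), colMeans(pooled))
})
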