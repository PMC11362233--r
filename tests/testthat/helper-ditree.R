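# shared fixtures, built in code

# single-node binary dominance tree used as a minimal test bed
toy_binary_spec <- function(I = 3L) {
  mapping <- tree_mapping(cbind(X1 = c(0L, 1L)))
  ditree:::new_tree_spec(
    "toy", 2L, mapping,
    nodes = list(list(K = 1L, label = "resp",
                      processes = list(list(kind = "dominance",
                                            trait = "theta",
                                            weights = c(0, 1),
                                            disc = "alpha")),
                      tau = "tau1_1")),
    traits = c(theta = "trait"), I = I)
}

# random pseudo-item with co-occurring processes (at most one ideal point)
random_pseudo_item <- function(K = 2L, n_dom = 1L, n_ip = 1L) {
  procs <- c(
    lapply(seq_len(n_dom), function(r)
      process_spec("dominance", paste0("d", r), weights = 0:K,
                   discrimination = rlnorm(1, 0, 0.4))),
    lapply(seq_len(n_ip), function(r)
      process_spec("ideal_point", paste0("i", r), weights = sample(0:K),
                   discrimination = rlnorm(1, 0, 0.4),
                   location = runif(1, -2, 2)))
  )
  pseudo_item(procs, intercepts = rnorm(K, -0.5, 0.8))
}

random_traits <- function(item) {
  tr <- vapply(item$processes, `[[`, "", "trait")
  stats::setNames(rnorm(length(unique(tr))), unique(tr))
}

# small shared reference fit, computed once per test run
ref_fit_env <- new.env()

reference_idi_fit <- function() {
  if (!is.null(ref_fit_env$fit)) return(ref_fit_env)
  sim <- sim_dataset(sim_design("I-DI", N = 200, I = 8, seed = 31))
  ctrl <- mcmc_control(chains = 2, warmup = 300, draws = 400,
                       extend_step = 400, max_draws = 1200,
                       sweeps_per_draw = 2, seed = 9, loglik_draws = 400,
                       refit_attempts = 0)
  fit <- fit_irtree(sim$responses, sim$spec, control = ctrl,
                    sign_template = sign(sim$items$delta))
  ref_fit_env$sim <- sim
  ref_fit_env$fit <- fit
  ref_fit_env
}

quick_ctrl <- function(seed = 7, ...) {
  mcmc_control(chains = 1, warmup = 200, draws = 250, extend_step = 250,
               max_draws = 500, sweeps_per_draw = 1, seed = seed,
               loglik_draws = 200, refit_attempts = 0, ...)
}
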