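#' Mean absolute bias
#'
#' Mean of `|estimate - truth|` over aligned vectors.
#'
#' @param estimates,truths Numeric vectors of equal length.
#' @return Nonnegative scalar.
#' @export
mean_absolute_bias <- function(estimates, truths) {
  if (length(estimates) != length(truths)) {
    stop("estimates and truths have different lengths", call. = FALSE)
  }
  mean(abs(estimates - truths))
}

#' Person-parameter recovery of a fit against simulation truth
#'
#' @param fit A `ditree_fit`.
#' @param sim The generating [sim_dataset()] (or any list with `persons`).
#' @return Tibble with one row per trait shared by fit and truth: MAB and the
#'   correlation of EAP estimates with the true levels.
#' @export
person_recovery <- function(fit, sim) {
  traits <- intersect(names(fit$spec$traits), names(sim$persons))
  eap <- fit$eap
  purrr::map_dfr(traits, function(tr) {
    est <- eap[paste0(tr, "[", seq_len(fit$N), "]")]
    truth <- sim$persons[[tr]]
    tibble::tibble(trait = tr, mab = mean_absolute_bias(est, truth),
                   cor = cor(est, truth))
  })
}

#' Item-parameter recovery of a fit against simulation truth
#'
#' Parameter families are compared on the estimation scale (category
#' intercepts `tau`, locations `delta`, discriminations); a family is skipped
#' when the fitted model does not contain it.
#'
#' @inheritParams person_recovery
#' @return Tibble with columns `family` and `mab`.
#' @export
item_recovery <- function(fit, sim) {
  eap <- fit$eap
  items <- sim$items
  ptab <- fit$spec$params
  fam_of <- function(nm) {
    if (grepl("^tau", nm)) "tau" else nm
  }
  fams <- unique(vapply(ptab$name, fam_of, ""))
  purrr::map_dfr(fams, function(f) {
    nms <- ptab$name[vapply(ptab$name, fam_of, "") == f]
    nms <- nms[nms %in% names(items)]
    if (!length(nms)) return(NULL)
    est <- unlist(lapply(nms, function(nm)
      eap[paste0(nm, "[", seq_len(fit$spec$I), "]")]))
    truth <- unlist(lapply(nms, function(nm) items[[nm]]))
    tibble::tibble(family = f, mab = mean_absolute_bias(est, truth))
  })
}

#' Run one replication of the recovery study
#'
#' Simulates a dataset from `design` and fits each requested analysis model,
#' returning one row per fitted model with person/item MABs, EAP-truth
#' correlations, the LOO criterion, and convergence bookkeeping.
#'
#' @param design A [sim_design()].
#' @param fit_models Character vector of analysis models (subset of
#'   `"I-DI"`, `"I-D"`, `"I-I"`).
#' @param control,priors Passed to [fit_irtree()].
#' @param settings Passed to [draw_population()].
#' @return Tibble, one row per fitted model.
#' @export
run_recovery_rep <- function(design, fit_models = c("I-DI", "I-D", "I-I"),
                             control = mcmc_control(),
                             priors = ditree_priors(),
                             settings = population_settings()) {
  sim <- sim_dataset(design, settings)
  template <- sign(sim$items$delta)
  purrr::map_dfr(fit_models, function(m) {
    spec <- spec_for_design(sim_design(m, design$N, design$I,
                                       design$scale_points, design$seed,
                                       design$rep))
    fit <- fit_irtree(sim$responses, spec, priors, control,
                      sign_template = template)
    pr <- person_recovery(fit, sim)
    ir <- item_recovery(fit, sim)
    lo <- loo(fit)
    row <- tibble::tibble(
      generation = design$model, analysis = m,
      N = design$N, I = design$I, rep = design$rep, seed = design$seed,
      looic = lo$looic, looic_se = lo$se,
      converged = fit$converged, max_rhat = max(fit$diagnostics$rhat,
                                                na.rm = TRUE)
    )
    for (k in seq_len(nrow(pr))) {
      row[[paste0(pr$trait[k], "_mab")]] <- pr$mab[k]
      row[[paste0(pr$trait[k], "_cor")]] <- pr$cor[k]
    }
    for (k in seq_len(nrow(ir))) {
      row[[paste0(ir$family[k], "_mab")]] <- ir$mab[k]
    }
    row
  })
}

#' Run a grid of recovery replications
#'
#' The full-scale study (2 sample sizes x 2 questionnaire lengths x 3
#' generating models x 100 replications, each analyzed by all three models) is
#' a multi-day single-CPU job; restrict `grid` to the cells and replications
#' of interest for smaller runs.
#'
#' @param grid Tibble from [sim_condition_grid()] (optionally filtered).
#' @inheritParams run_recovery_rep
#' @return Tibble of stacked [run_recovery_rep()] results.
#' @export
run_recovery_grid <- function(grid, fit_models = c("I-DI", "I-D", "I-I"),
                              control = mcmc_control(),
                              priors = ditree_priors(),
                              settings = population_settings()) {
  purrr::map_dfr(seq_len(nrow(grid)), function(r) {
    g <- grid[r, ]
    design <- sim_design(g$model, g$N, g$I, seed = g$design_seed, rep = g$rep)
    run_recovery_rep(design, fit_models, control, priors, settings)
  })
}

#' Aggregate recovery and model-comparison tables
#'
#' Produces the two standard summaries of a recovery grid: a recovery table of
#' mean MABs per (generating model, analysis model) and condition, and a
#' comparison table with mean LOO, mean LOO standard error, and the proportion
#' of replications in which each analysis model attained the smallest LOO
#' (proportions sum to 1 within a generating condition).
#'
#' @param results Tibble from [run_recovery_rep()] / [run_recovery_grid()].
#' @param recovery_by,comparison_by Condition columns kept as table axes
#'   (e.g. `"I"` for a person-parameter table aggregated over N, `c("N","I")`
#'   for the comparison table).
#' @return List with tibbles `recovery` and `comparison`.
#' @export
recovery_summary <- function(results, recovery_by = "I",
                             comparison_by = c("N", "I")) {
  mab_cols <- grep("_mab$", names(results), value = TRUE)
  recovery <- results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("generation", "analysis", recovery_by)))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(mab_cols),
                                   ~ mean(.x, na.rm = TRUE)),
                     n_reps = dplyr::n(), .groups = "drop")

  per_rep <- results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("generation", comparison_by, "rep")))) |>
    dplyr::mutate(smallest = .data$looic == min(.data$looic)) |>
    dplyr::ungroup()
  comparison <- per_rep |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("generation", "analysis", comparison_by)))) |>
    dplyr::summarise(looic = mean(.data$looic), se = mean(.data$looic_se),
                     prop_best = mean(.data$smallest),
                     n_reps = dplyr::n(), .groups = "drop")
  list(recovery = recovery, comparison = comparison)
}
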