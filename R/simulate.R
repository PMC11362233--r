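#' @importFrom dplyr bind_rows bind_cols mutate select arrange group_by
#'   summarise ungroup left_join
NULL

# one global stream per replication, substreamed by purpose so that e.g.
# adding response times never perturbs the responses
substream_seed <- function(seed, rep = 1L, purpose = 1L) {
  as.integer((abs(seed) %% 1000003L) * 1009L + rep * 101L + purpose * 7L) %% 2147483647L
}

#' Describe one cell of a simulation design
#'
#' @param model Generating model: `"I-DI"` (co-occurring trait + ERS intensity),
#'   `"I-D"` (ERS-only intensity), `"I-I"` (trait-only intensity), or
#'   `"midscale"` (five-point midscale/agreement/extreme family).
#' @param N Number of persons (>= 2).
#' @param I Number of items (>= 2).
#' @param scale_points Rating-scale length for the ideal-point family (4 or 6;
#'   ignored for `"midscale"`, which is five-point).
#' @param seed Integer seed of the replication's RNG stream.
#' @param rep Replication index.
#' @return A list of class `ditree_design`.
#' @export
sim_design <- function(model = c("I-DI", "I-D", "I-I", "midscale"),
                       N = 500, I = 10, scale_points = 6, seed = 1, rep = 1) {
  model <- match.arg(model)
  stopifnot(N >= 2, I >= 2)
  structure(list(model = model, N = as.integer(N), I = as.integer(I),
                 scale_points = if (model == "midscale") 5L else as.integer(scale_points),
                 seed = as.integer(seed), rep = as.integer(rep)),
            class = "ditree_design")
}

#' Generator settings for synthetic populations
#'
#' Defaults follow the simulation conditions used throughout the package:
#' traits are independent standard normal; discriminations are log-normal with
#' log-mean 0 and log-variance 0.25 (i.e. `sdlog = 0.5`; the second argument
#' of the log-normal is read as a variance, configurable via `disc_sdlog`);
#' ideal-point locations are uniform on (-3, 3); ideal-point thresholds have
#' means -2.2 and -1.3 (intense disagreement), -1.0 (agreement), -0.8 and
#' -0.2 (intense agreement), each with sd 0.2; dominance thresholds are an
#' item location from U(-1, 1) plus category deviations from N(-0.5, 0.2) and
#' N(0.5, 0.2) (second arguments read as standard deviations, configurable).
#'
#' @param disc_sdlog sdlog of discriminations.
#' @param delta_range Support of ideal-point item locations.
#' @param xi_means,xi_sd Means/sd of the ideal-point threshold distributions,
#'   ordered across ordinal categories (intense disagreement x2, agreement,
#'   intense agreement x2).
#' @param beta_loc_range Support of the dominance item location.
#' @param zeta_means,zeta_sd Means/sd of dominance category deviations.
#' @return List of generator settings.
#' @export
population_settings <- function(disc_sdlog = 0.5,
                                delta_range = c(-3, 3),
                                xi_means = c(-2.2, -1.3, -1.0, -0.8, -0.2),
                                xi_sd = 0.2,
                                beta_loc_range = c(-1, 1),
                                zeta_means = c(-0.5, 0.5),
                                zeta_sd = 0.2) {
  list(disc_sdlog = disc_sdlog, delta_range = delta_range, xi_means = xi_means,
       xi_sd = xi_sd, beta_loc_range = beta_loc_range,
       zeta_means = zeta_means, zeta_sd = zeta_sd)
}

#' Draw person and item parameters for a simulated dataset
#'
#' Samples a population according to the design (see [population_settings()]
#' for the distributions) and returns generation-side parameters together with
#' the estimation-scale parameters (category intercepts computed as the
#' discrimination-weighted sums of the process-specific thresholds).
#'
#' @param design A [sim_design()].
#' @param settings A [population_settings()].
#' @return List with `persons` (tibble), `items` (tibble: generation and
#'   estimation columns), `spec` (the matching `ditree_spec`), and `design`.
#' @export
draw_population <- function(design, settings = population_settings()) {
  stopifnot(inherits(design, "ditree_design"))
  N <- design$N; I <- design$I
  set.seed(substream_seed(design$seed, design$rep, 1L))
  persons <- if (design$model == "midscale") {
    tibble::tibble(person = seq_len(N), theta = rnorm(N), eta1 = rnorm(N),
                   eta2 = rnorm(N))
  } else {
    tibble::tibble(person = seq_len(N), theta = rnorm(N), eta = rnorm(N))
  }
  set.seed(substream_seed(design$seed, design$rep, 2L))
  items <- if (design$model == "midscale") {
    draw_items_midscale(I, settings)
  } else {
    draw_items_ideal_ers(I, design$scale_points, design$model, settings)
  }
  spec <- spec_for_design(design)
  list(persons = persons, items = items, spec = spec, design = design)
}

spec_for_design <- function(design) {
  switch(design$model,
    "I-DI" = irtree_ideal_ers(design$scale_points, design$I, "both"),
    "I-D" = irtree_ideal_ers(design$scale_points, design$I, "ers"),
    "I-I" = irtree_ideal_ers(design$scale_points, design$I, "trait"),
    "midscale" = irtree_midscale(design$I)
  )
}

draw_items_ideal_ers <- function(I, scale_points, model, st) {
  Kh <- scale_points / 2L - 1L
  it <- tibble::tibble(
    item = seq_len(I),
    alpha = rlnorm(I, 0, st$disc_sdlog),
    lambda1 = rlnorm(I, 0, st$disc_sdlog),
    lambda2 = rlnorm(I, 0, st$disc_sdlog),
    delta = runif(I, st$delta_range[1], st$delta_range[2]),
    xi1 = rnorm(I, st$xi_means[3], st$xi_sd),
    beta_loc = runif(I, st$beta_loc_range[1], st$beta_loc_range[2])
  )
  if (Kh == 2L) {
    it$xi2_1 <- rnorm(I, st$xi_means[4], st$xi_sd)
    it$xi2_2 <- rnorm(I, st$xi_means[5], st$xi_sd)
    it$xi3_1 <- rnorm(I, st$xi_means[2], st$xi_sd)
    it$xi3_2 <- rnorm(I, st$xi_means[1], st$xi_sd)
    it$beta1_1 <- it$beta_loc + rnorm(I, st$zeta_means[1], st$zeta_sd)
    it$beta1_2 <- it$beta_loc + rnorm(I, st$zeta_means[2], st$zeta_sd)
    it$beta2_1 <- it$beta_loc + rnorm(I, st$zeta_means[1], st$zeta_sd)
    it$beta2_2 <- it$beta_loc + rnorm(I, st$zeta_means[2], st$zeta_sd)
  } else {
    # four-point variant: one threshold per intensity node, centred at the
    # midpoint of the corresponding six-point pair
    it$xi2_1 <- rnorm(I, mean(st$xi_means[4:5]), st$xi_sd)
    it$xi3_1 <- rnorm(I, mean(st$xi_means[1:2]), st$xi_sd)
    it$beta1_1 <- it$beta_loc + rnorm(I, mean(st$zeta_means), st$zeta_sd)
    it$beta2_1 <- it$beta_loc + rnorm(I, mean(st$zeta_means), st$zeta_sd)
  }
  # estimation-scale category intercepts, tau_k = sum_r disc_r * threshold_rk
  it$tau1_1 <- it$lambda1 * it$xi1
  for (k in seq_len(Kh)) {
    b1 <- it[[paste0("beta1_", k)]]; b2 <- it[[paste0("beta2_", k)]]
    x2 <- it[[paste0("xi2_", k)]]; x3 <- it[[paste0("xi3_", k)]]
    it[[paste0("tau2_", k)]] <- switch(model,
      "I-DI" = it$alpha * b1 + it$lambda2 * x2,
      "I-D" = it$alpha * b1,
      "I-I" = it$lambda2 * x2)
    it[[paste0("tau3_", k)]] <- switch(model,
      "I-DI" = it$alpha * b2 + it$lambda2 * x3,
      "I-D" = it$alpha * b2,
      "I-I" = it$lambda2 * x3)
  }
  it
}

draw_items_midscale <- function(I, st) {
  it <- tibble::tibble(
    item = seq_len(I),
    alpha1 = rlnorm(I, 0, st$disc_sdlog),
    alpha2 = rlnorm(I, 0, st$disc_sdlog),
    alpha3 = rlnorm(I, 0, st$disc_sdlog),
    alpha4 = rlnorm(I, 0, st$disc_sdlog),
    lambda = rlnorm(I, 0, st$disc_sdlog),
    beta2 = runif(I, st$beta_loc_range[1], st$beta_loc_range[2]),
    # midscale threshold and ideal-point threshold chosen so that the implied
    # category shares are realistic for five-point rating data
    # (roughly 20/22/23/18/16% across the scale at standard-normal traits)
    beta1 = rnorm(I, 1.25, 0.3),
    xi = rnorm(I, -0.5, st$xi_sd),
    beta3 = rnorm(I, 0.3, st$zeta_sd),
    beta4 = rnorm(I, 0.3, st$zeta_sd),
    beta5 = rnorm(I, 0.3, st$zeta_sd),
    beta6 = rnorm(I, 0.3, st$zeta_sd)
  )
  # the midscale ideal-point location is tied to the agreement threshold
  it$delta <- it$beta2
  it$tau1_1 <- it$alpha1 * it$beta1 + it$lambda * it$xi
  it$tau2_1 <- it$alpha2 * it$beta2
  it$tau3_1 <- it$alpha3 * it$beta3 + it$alpha4 * it$beta4
  it$tau4_1 <- it$alpha3 * it$beta5 + it$alpha4 * it$beta6
  it
}

#' Sample item responses from the model-implied probabilities
#'
#' @param population Output of [draw_population()] (or a list with `persons`,
#'   `items`, `spec`, `design`).
#' @param seed Optional override of the response substream seed.
#' @return Integer matrix persons x items with categories `0..K_scale`.
#' @export
simulate_responses <- function(population, seed = NULL) {
  spec <- population$spec
  persons <- population$persons
  items <- population$items
  if (spec$I != nrow(items)) stop("spec/item mismatch", call. = FALSE)
  if (is.null(seed)) {
    seed <- substream_seed(population$design$seed, population$design$rep, 3L)
  }
  set.seed(seed)
  tm <- as.matrix(persons[, names(spec$traits), drop = FALSE])
  N <- nrow(tm)
  Y <- matrix(NA_integer_, N, spec$I)
  for (i in seq_len(spec$I)) {
    probs <- tree_category_probs(spec, tm, items[i, ])
    u <- runif(N)
    cum <- t(apply(probs, 1L, cumsum))
    Y[, i] <- rowSums(u > cum)
  }
  Y
}

#' Response-time generator coefficients
#'
#' Fixed effects of the log response-time mixed model: an intercept, the
#' manifest midscale and extreme indicators, cross-level interactions with the
#' MRS and ERS levels, and the person-item distance `|theta - beta_2|`.
#' Interaction and distance defaults are the magnitudes reported for the
#' empirical leadership data (middle x MRS -0.116, extreme x ERS -0.127,
#' distance -0.086); the intercept defaults to log(5 seconds). Variance
#' components default to person/item/residual sds of 0.3 / 0.1 / 0.5.
#'
#' @param intercept,middle,extreme,mrs_middle,ers_extreme,distance Fixed
#'   effects (gamma_000, gamma_100, gamma_200, gamma_110, gamma_220,
#'   gamma_011).
#' @param sd_person,sd_item,sd_resid Random-intercept and residual sds (>= 0).
#' @return Named list of coefficients.
#' @export
rt_coefficients <- function(intercept = log(5), middle = 0.041,
                            extreme = -0.068, mrs_middle = -0.116,
                            ers_extreme = -0.127, distance = -0.086,
                            sd_person = 0.3, sd_item = 0.1, sd_resid = 0.5) {
  if (any(c(sd_person, sd_item, sd_resid) < 0)) {
    stop("variance components must be nonnegative", call. = FALSE)
  }
  list(intercept = intercept, middle = middle, extreme = extreme,
       mrs_middle = mrs_middle, ers_extreme = ers_extreme, distance = distance,
       sd_person = sd_person, sd_item = sd_item, sd_resid = sd_resid)
}

#' Simulate response times for five-point midscale-family responses
#'
#' Log response times follow a linear mixed model with the tree-derived
#' indicators (midscale; extreme on either side), random person and item
#' intercepts, cross-level interactions with the MRS and ERS levels, and the
#' latent person-item distance `|theta_v - beta_2i|` -- the same distance that
#' drives the midscale node's ideal-point process.
#'
#' @param responses Integer matrix persons x items on a five-point scale.
#' @param persons Tibble with `theta`, `eta1`, `eta2`.
#' @param items Tibble with `alpha2` and `tau2_1` (defining
#'   `beta_2 = tau2_1 / alpha2`).
#' @param coef [rt_coefficients()].
#' @param seed RNG seed for the RT substream.
#' @return Numeric matrix persons x items of response times in seconds.
#' @export
simulate_response_times <- function(responses, persons, items,
                                    coef = rt_coefficients(), seed = 1) {
  stopifnot(max(responses, na.rm = TRUE) <= 4L)
  set.seed(seed)
  N <- nrow(responses); I <- ncol(responses)
  des <- build_rt_design(responses)
  beta2 <- items$tau2_1 / items$alpha2
  dist <- abs(outer(persons$theta, beta2, `-`))
  u_p <- rnorm(N, 0, coef$sd_person)
  u_i <- rnorm(I, 0, coef$sd_item)
  mu <- coef$intercept +
    (coef$middle + coef$mrs_middle * persons$eta1) * des$middle +
    (coef$extreme + coef$ers_extreme * persons$eta2) * des$extreme +
    coef$distance * dist +
    matrix(u_p, N, I) + matrix(u_i, N, I, byrow = TRUE)
  rt <- exp(mu + matrix(rnorm(N * I, 0, coef$sd_resid), N, I))
  rt[is.na(responses)] <- NA_real_
  rt
}

#' Simulate a complete dataset (parameters, responses, optional RTs)
#'
#' @inheritParams draw_population
#' @param response_times Also generate response times (midscale designs only).
#' @param rt_coef [rt_coefficients()] used when `response_times = TRUE`.
#' @return A list of class `ditree_sim` with `responses`, `persons`, `items`,
#'   `spec`, `design`, and optionally `rt`.
#' @export
sim_dataset <- function(design, settings = population_settings(),
                        response_times = FALSE, rt_coef = rt_coefficients()) {
  pop <- draw_population(design, settings)
  Y <- simulate_responses(pop)
  out <- c(pop, list(responses = Y))
  if (response_times) {
    if (design$model != "midscale") {
      stop("response times are defined for the five-point midscale family",
           call. = FALSE)
    }
    out$rt <- simulate_response_times(
      Y, pop$persons, pop$items, rt_coef,
      seed = substream_seed(design$seed, design$rep, 4L))
    out$rt_coef <- rt_coef
  }
  structure(out, class = "ditree_sim")
}

#' @export
print.ditree_sim <- function(x, ...) {
  d <- x$design
  cat(sprintf("Simulated %s dataset: N = %d persons, I = %d items, %d-point scale (seed %d, rep %d)\n",
              d$model, d$N, d$I, d$scale_points, d$seed, d$rep))
  if (!is.null(x$rt)) cat("Includes response times.\n")
  invisible(x)
}

#' Full simulation-study condition grid
#'
#' The crossed recovery design: sample sizes x questionnaire lengths x
#' generating models, with replications. Each row carries the substreamed
#' seeds needed to regenerate its dataset, so any cell of a recovery table can
#' be re-run in isolation.
#'
#' @param N,I,models Condition levels.
#' @param reps Replications per cell (default 100).
#' @param seed Master seed.
#' @return Tibble with one row per (cell, replication).
#' @export
sim_condition_grid <- function(N = c(500, 1000), I = c(10, 20),
                               models = c("I-DI", "I-D", "I-I"),
                               reps = 100, seed = 1) {
  grid <- tidyr::expand_grid(model = models, N = N, I = I, rep = seq_len(reps))
  grid$cell <- paste(grid$model, grid$N, grid$I, sep = "/")
  cell_idx <- match(grid$cell, unique(grid$cell))
  # distinct stream per design cell so cells are independent of each other
  grid$design_seed <- (as.integer(seed) + 131L * cell_idx) %% 2147483647L
  grid$seed_persons <- mapply(substream_seed, grid$design_seed, grid$rep, 1L)
  grid$seed_items <- mapply(substream_seed, grid$design_seed, grid$rep, 2L)
  grid$seed_responses <- mapply(substream_seed, grid$design_seed, grid$rep, 3L)
  tibble::as_tibble(grid)
}
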