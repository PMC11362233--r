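# synthetic-data generator: distributions, determinism, provenance

test_that("person parameters follow independent standard normals", {
  pop <- draw_population(sim_design("I-DI", N = 1e5, I = 2, seed = 1))
  se <- 1 / sqrt(1e5)
  expect_lt(abs(mean(pop$persons$theta)), 3 * se)
  expect_lt(abs(mean(pop$persons$eta)), 3 * se)
  expect_lt(abs(sd(pop$persons$theta) - 1), 3 * se)
  expect_lt(abs(cor(pop$persons$theta, pop$persons$eta)), 3 * se)
})

test_that("item parameters follow the stated generating distributions", {
  pop <- draw_population(sim_design("I-DI", N = 2, I = 4000, seed = 2))
  it <- pop$items
  expect_true(all(it$delta >= -3 & it$delta <= 3))
  expect_true(all(it$alpha > 0 & it$lambda1 > 0 & it$lambda2 > 0))
  # LogN(0, 0.25) read as log-variance: sd(log alpha) = 0.5
  expect_lt(abs(sd(log(it$alpha)) - 0.5), 3 * 0.5 / sqrt(2 * 4000))
  expect_lt(abs(mean(log(it$lambda2))), 3 * 0.5 / sqrt(4000))
  # ideal-point threshold means, ordered across ordinal categories:
  # intense disagreement (-2.2, -1.3), agreement -1.0, intense agreement
  # (-0.8, -0.2), each sd 0.2
  se <- 3 * 0.2 / sqrt(4000)
  expect_lt(abs(mean(it$xi3_2) - (-2.2)), se)
  expect_lt(abs(mean(it$xi3_1) - (-1.3)), se)
  expect_lt(abs(mean(it$xi1) - (-1.0)), se)
  expect_lt(abs(mean(it$xi2_1) - (-0.8)), se)
  expect_lt(abs(mean(it$xi2_2) - (-0.2)), se)
  # dominance thresholds: item location U(-1,1) plus deviations
  # N(-0.5, 0.2), N(0.5, 0.2)
  expect_true(all(it$beta_loc >= -1 & it$beta_loc <= 1))
  dev1 <- it$beta1_1 - it$beta_loc
  dev2 <- it$beta1_2 - it$beta_loc
  expect_lt(abs(mean(dev1) - (-0.5)), se)
  expect_lt(abs(mean(dev2) - 0.5), se)
  expect_lt(abs(sd(dev1) - 0.2), 3 * 0.2 / sqrt(2 * 4000))
})

test_that("category intercepts are recomputable from the generating thresholds", {
  for (model in c("I-DI", "I-D", "I-I")) {
    it <- draw_population(sim_design(model, N = 2, I = 50, seed = 4))$items
    expect_equal(it$tau1_1, it$lambda1 * it$xi1)
    expected_tau2 <- switch(model,
      "I-DI" = it$alpha * it$beta1_1 + it$lambda2 * it$xi2_1,
      "I-D" = it$alpha * it$beta1_1,
      "I-I" = it$lambda2 * it$xi2_1)
    expect_equal(it$tau2_1, expected_tau2)
  }
  itm <- draw_population(sim_design("midscale", N = 2, I = 50, seed = 4))$items
  expect_equal(itm$tau1_1, itm$alpha1 * itm$beta1 + itm$lambda * itm$xi)
  expect_equal(itm$tau3_1, itm$alpha3 * itm$beta3 + itm$alpha4 * itm$beta4)
  expect_equal(itm$delta, itm$tau2_1 / itm$alpha2)
})

test_that("response simulation is deterministic under the design seed", {
  d <- sim_design("I-DI", N = 80, I = 5, seed = 9)
  s1 <- sim_dataset(d)
  s2 <- sim_dataset(d)
  expect_identical(s1$responses, s2$responses)
  expect_identical(s1$items, s2$items)
  s3 <- sim_dataset(sim_design("I-DI", N = 80, I = 5, seed = 10))
  expect_false(identical(s1$responses, s3$responses))
})

test_that("adding response times never perturbs the responses", {
  d <- sim_design("midscale", N = 60, I = 4, seed = 12)
  plain <- sim_dataset(d)
  with_rt <- sim_dataset(d, response_times = TRUE)
  expect_identical(plain$responses, with_rt$responses)
  expect_identical(plain$persons, with_rt$persons)
  expect_true(all(with_rt$rt > 0))
})

test_that("empirical category frequencies match the model-implied probabilities", {
  pop <- draw_population(sim_design("I-DI", N = 1e5, I = 2, seed = 21))
  Y <- simulate_responses(pop)
  tm <- as.matrix(pop$persons[, c("theta", "eta")])
  for (i in 1:2) {
    p_true <- colMeans(tree_category_probs(pop$spec, tm, pop$items[i, ]))
    freq <- tabulate(Y[, i] + 1L, 6) / 1e5
    se <- sqrt(p_true * (1 - p_true) / 1e5)
    expect_true(all(abs(freq - p_true) < 3 * se + 1e-4))
  }
})

test_that("a branch with vanishing probability is never taken", {
  pop <- draw_population(sim_design("I-DI", N = 500, I = 2, seed = 23))
  pop$items$tau1_1 <- -50   # agreement node forced to X1 = 1
  Y <- simulate_responses(pop)
  expect_true(all(Y >= 3))
})

test_that("response times follow the mixed-model structure", {
  d <- sim_design("midscale", N = 50, I = 4, seed = 31)
  pop <- draw_population(d)
  Y <- simulate_responses(pop)
  # all gammas zero except the intercept, zero variances: RT = exp(c)
  co <- rt_coefficients(intercept = 1.4, middle = 0, extreme = 0,
                        mrs_middle = 0, ers_extreme = 0, distance = 0,
                        sd_person = 0, sd_item = 0, sd_resid = 0)
  rt <- simulate_response_times(Y, pop$persons, pop$items, co, seed = 5)
  expect_equal(unique(as.vector(rt)), exp(1.4))
  # only the distance effect: log RT strictly decreasing in |theta - beta_2|
  co2 <- rt_coefficients(intercept = 1, middle = 0, extreme = 0,
                         mrs_middle = 0, ers_extreme = 0, distance = -0.086,
                         sd_person = 0, sd_item = 0, sd_resid = 0)
  rt2 <- simulate_response_times(Y, pop$persons, pop$items, co2, seed = 5)
  beta2 <- pop$items$tau2_1 / pop$items$alpha2
  dist <- abs(outer(pop$persons$theta, beta2, `-`))
  o <- order(dist)
  expect_true(all(diff(log(rt2)[o]) <= 1e-12))
  # reproducible under a fixed seed
  rt3 <- simulate_response_times(Y, pop$persons, pop$items, seed = 77)
  rt4 <- simulate_response_times(Y, pop$persons, pop$items, seed = 77)
  expect_identical(rt3, rt4)
  expect_error(rt_coefficients(sd_person = -1), "nonnegative")
})

test_that("the condition grid reproduces the full crossed design", {
  g <- sim_condition_grid(seed = 3)
  expect_equal(nrow(g), 2 * 2 * 3 * 100)
  expect_equal(sort(unique(g$N)), c(500, 1000))
  expect_equal(sort(unique(g$I)), c(10, 20))
  expect_setequal(unique(g$model), c("I-DI", "I-D", "I-I"))
  expect_equal(max(table(g$cell)), 100)
  # provenance: each row regenerates its dataset from the stored seeds
  row <- g[g$model == "I-DI" & g$N == 500 & g$I == 10 & g$rep == 7, ]
  d <- sim_design(row$model, row$N, row$I, seed = row$design_seed, rep = row$rep)
  s1 <- sim_dataset(d)
  s2 <- sim_dataset(d)
  expect_identical(s1$responses, s2$responses)
  # distinct cells use distinct streams
  expect_equal(anyDuplicated(unique(g[, c("cell", "design_seed")])$design_seed), 0L)
})
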