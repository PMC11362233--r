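# co-occurring processes: linear-predictor and probability-aggregation forms

test_that("category intercepts are discrimination-weighted threshold sums", {
  # single dominance process, zero threshold
  p1 <- process_spec("dominance", "theta", c(0, 1), 1)
  expect_equal(unname(category_intercepts(list(p1), list(0))), c(0, 0))
  # one dominance (alpha=1, beta1=0) + one ideal point (lambda=1, xi1=-1)
  pr <- list(process_spec("dominance", "t1", c(0, 1), 1),
             process_spec("ideal_point", "t2", c(0, 1), 1, location = 0.5))
  expect_equal(unname(category_intercepts(pr, list(0, -1))), c(0, -1))
  # two dominance processes: 2 * 0.5 + 1 * (-1) = 0
  pr2 <- list(process_spec("dominance", "a", c(0, 1), 2),
              process_spec("dominance", "b", c(0, 1), 1))
  expect_equal(unname(category_intercepts(pr2, list(0.5, -1))), c(0, 0))
  expect_error(category_intercepts(pr, list(0, c(-1, -2))), "same number")
})

test_that("single-process pseudo-items reduce exactly to GPCM / GGUM", {
  set.seed(21)
  for (r in 1:40) {
    K <- sample(1:3, 1)
    a <- rlnorm(1, 0, 0.4); beta <- rnorm(K); th <- rnorm(1, 0, 2)
    item <- pseudo_item(list(process_spec("dominance", "theta", 0:K, a)),
                        intercepts = a * beta)
    expect_equal(dimirt_probs(c(theta = th), item),
                 gpcm_probs(th, a, beta), tolerance = 1e-14)
    lam <- rlnorm(1, 0, 0.4); del <- runif(1, -2, 2); xi <- rnorm(K, -1, 0.5)
    item2 <- pseudo_item(list(process_spec("ideal_point", "theta", 0:K, lam,
                                           location = del)),
                         intercepts = lam * xi)
    expect_equal(dimirt_probs(c(theta = th), item2),
                 ggum_probs(th, lam, del, xi), tolerance = 1e-14)
  }
})

test_that("co-occurring binary item reproduces hand-evaluated probabilities", {
  # alpha = 1, beta1 = 0, lambda = 1, xi1 = -1, s = (0,1) for both processes:
  # at theta1 = 0 (dominance) and theta2 = delta (ideal point) the dominance
  # term contributes 0 and p(endorse) = e / (1 + e)
  item <- pseudo_item(
    list(process_spec("dominance", "t1", c(0, 1), 1),
         process_spec("ideal_point", "t2", c(0, 1), 1, location = 0.5)),
    intercepts = -1)
  p <- dimirt_probs(c(t1 = 0, t2 = 0.5), item)
  expect_equal(p[2], exp(1) / (1 + exp(1)), tolerance = 1e-12)
  # dominance trait dominating both exponents drives endorsement to 1
  p_hi <- dimirt_probs(c(t1 = 40, t2 = 0.5), item)
  expect_gt(p_hi[2], 1 - 1e-10)
})

test_that("missing trait levels are reported by name", {
  item <- pseudo_item(list(process_spec("dominance", "eta", c(0, 1), 1)), 0)
  expect_error(dimirt_probs(c(theta = 0), item), "eta")
})

test_that("aggregation form is softmax of summed log probabilities", {
  d <- c(0.2, 0.5, 0.3)
  expect_equal(aggregate_probability_form(list(d)), d)
  u <- rep(1 / 4, 4)
  expect_equal(aggregate_probability_form(list(u, u)), u)
  expect_error(aggregate_probability_form(list(c(0.5, 0.5), c(0, 1))),
               "strictly positive")
})

test_that("linear-predictor and aggregation forms agree with <= 1 ideal point", {
  set.seed(31)
  for (r in 1:1000) {
    K <- sample(1:3, 1)
    n_dom <- sample(0:2, 1)
    n_ip <- sample(0:1, 1)
    if (n_dom + n_ip == 0) n_dom <- 1
    item <- random_pseudo_item(K, n_dom, n_ip)
    traits <- random_traits(item)
    # process-specific thresholds that sum (weighted) to the intercepts
    R <- length(item$processes)
    thr <- lapply(seq_len(R), function(j) rnorm(K, 0, 0.7))
    resid <- item$intercepts -
      Reduce(`+`, lapply(seq_len(R), function(j)
        item$processes[[j]]$discrimination * thr[[j]]))
    thr[[1]] <- thr[[1]] + resid / item$processes[[1]]$discrimination
    agg <- aggregate_probability_form(
      process_distributions(traits, item, thr))
    expect_equal(agg, unname(dimirt_probs(traits, item)), tolerance = 1e-12)
  }
})

test_that("with two ideal-point processes the two forms can differ", {
  # the product of two two-term components has cross terms absent from the
  # linear-predictor form; both paths must still give valid distributions
  item <- pseudo_item(
    list(process_spec("ideal_point", "i1", c(0, 1, 2), 1.2, location = -0.5),
         process_spec("ideal_point", "i2", c(2, 1, 0), 0.8, location = 1.0)),
    intercepts = c(-1, -0.4))
  traits <- c(i1 = 0.9, i2 = -0.3)
  lin <- dimirt_probs(traits, item)
  agg <- aggregate_probability_form(
    process_distributions(traits, item, list(c(-1, -0.4) / 1.2, c(0, 0))))
  expect_equal(sum(lin), 1)
  expect_equal(sum(agg), 1)
  expect_gt(max(abs(lin - agg)), 1e-6)
})

test_that("top-category probability is monotone in a dominance trait", {
  item <- pseudo_item(
    list(process_spec("dominance", "eta", c(0, 1, 2), 1.1),
         process_spec("ideal_point", "theta", c(0, 1, 2), 0.9, location = 0.3)),
    intercepts = c(-0.8, -0.2))
  eta <- seq(-4, 4, length.out = 81)
  tm <- cbind(eta = eta, theta = rep(0.5, 81))
  p_top <- dimirt_probs(tm, item)[, 3]
  expect_true(all(diff(p_top) >= -1e-12))
})

test_that("adding a constant to both linear predictors leaves probabilities unchanged", {
  set.seed(5)
  item <- random_pseudo_item(2, 1, 1)
  tm <- ditree:::resolve_traits(random_traits(item), c("d1", "i1"))
  lw <- ditree:::dimirt_log_weights(tm, item)
  expect_equal(ditree:::softmax_rows(lw), ditree:::softmax_rows(lw + 3.7),
               tolerance = 1e-14)
})

test_that("pseudo-item constructor validates dimensions and positivity", {
  expect_error(process_spec("dominance", "t", c(0, 1), discrimination = -1),
               "> 0")
  expect_error(process_spec("ideal_point", "t", c(0, 1), 1), "location")
  expect_error(process_spec("dominance", "t", c(0, 1), 1, location = 0),
               "no location")
  p <- process_spec("dominance", "t", c(0, 1), 1)
  expect_error(pseudo_item(list(p), intercepts = c(0, 0), label = "node X9"),
               "node X9")
})
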