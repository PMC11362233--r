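# tree mappings, decomposition, response probabilities, model builders

test_that("four-point decomposition matches the published pseudo-item table", {
  m <- mapping_agreement_intensity(4)
  expect_equal(unname(decompose_response(3, m)), c(1L, 1L, -1L))
  expect_equal(unname(decompose_response(0, m)), c(0L, -1L, 1L))
  expect_equal(unname(decompose_response(1, m)), c(0L, -1L, 0L))
  expect_equal(unname(decompose_response(2, m)), c(1L, 0L, -1L))
})

test_that("six-point decomposition orders intensity from least to most intense", {
  m <- mapping_agreement_intensity(6)
  expect_equal(unname(decompose_response(0, m)), c(0L, -1L, 2L))
  expect_equal(unname(decompose_response(2, m)), c(0L, -1L, 0L))
  expect_equal(unname(decompose_response(5, m)), c(1L, 2L, -1L))
  expect_error(decompose_response(6, m), "out of range")
  expect_error(decompose_response(-1, m), "out of range")
})

test_that("five-point midscale decomposition follows the chosen coding", {
  m <- mapping_midscale()
  expect_equal(unname(decompose_response(2, m)), c(1L, -1L, -1L, -1L))
  expect_equal(unname(decompose_response(4, m)), c(0L, 1L, 1L, -1L))
  expect_equal(unname(decompose_response(0, m)), c(0L, 0L, -1L, 1L))
})

test_that("tree probabilities sum to one over categories", {
  set.seed(41)
  for (model in c("I-DI", "I-D", "I-I", "midscale")) {
    sim <- draw_population(sim_design(model, N = 20, I = 3, seed = 5))
    tm <- as.matrix(sim$persons[, names(sim$spec$traits)])
    for (i in 1:3) {
      p <- tree_category_probs(sim$spec, tm, sim$items[i, ])
      expect_equal(rowSums(p), rep(1, 20), tolerance = 1e-12)
    }
  }
})

test_that("tree probability equals the brute-force product of node probabilities", {
  set.seed(43)
  sim <- draw_population(sim_design("I-DI", N = 6, I = 2, seed = 13))
  spec <- sim$spec
  tm <- as.matrix(sim$persons[, c("theta", "eta")])
  for (i in 1:2) {
    ip <- sim$items[i, ]
    # hand product: evaluate each node distribution separately via the
    # irf-level kernels and multiply along each category's path
    agree <- ggum_probs(tm[, "theta"], ip$lambda1, ip$delta,
                        ip$tau1_1 / ip$lambda1)
    # intensity nodes: co-occurring ERS dominance + trait ideal point,
    # aggregated at the probability level (equivalent for one ideal point)
    n2 <- t(sapply(seq_len(nrow(tm)), function(v) {
      aggregate_probability_form(list(
        gpcm_probs(tm[v, "eta"], ip$alpha, c(ip$beta1_1, ip$beta1_2)),
        ggum_probs(tm[v, "theta"], ip$lambda2, ip$delta, c(ip$xi2_1, ip$xi2_2))
      ))
    }))
    n3 <- t(sapply(seq_len(nrow(tm)), function(v) {
      aggregate_probability_form(list(
        gpcm_probs(tm[v, "eta"], ip$alpha, c(ip$beta2_1, ip$beta2_2)),
        ggum_probs(tm[v, "theta"], ip$lambda2, ip$delta, c(ip$xi3_1, ip$xi3_2),
                   weights = c(2, 1, 0))
      ))
    }))
    byhand <- cbind(
      (1 - agree[, 2]) * n3[, 3], (1 - agree[, 2]) * n3[, 2],
      (1 - agree[, 2]) * n3[, 1],
      agree[, 2] * n2[, 1], agree[, 2] * n2[, 2], agree[, 2] * n2[, 3]
    )
    p <- tree_category_probs(spec, tm, ip)
    expect_equal(unname(p), unname(byhand), tolerance = 1e-12)
  }
})

test_that("degenerate node probabilities eliminate branches", {
  spec <- irtree_ideal_ers(6, 1)
  ip <- list(lambda1 = 1, alpha = 1, lambda2 = 1, delta = 0,
             tau1_1 = -60, tau2_1 = 0, tau2_2 = 0, tau3_1 = 0, tau3_2 = 0)
  # tau1 -> -inf pushes p(X1 = 1) -> 1: the disagreement branch dies
  p <- tree_category_probs(spec, c(theta = 0, eta = 0), ip)
  expect_lt(sum(p[1, 1:3]), 1e-10)
})

test_that("agreement/intensity builder reproduces the published structure", {
  spec6 <- irtree_ideal_ers(6, 4)
  expect_equal(vapply(spec6$nodes, `[[`, 0L, "K"), c(1L, 2L, 2L))
  # disagree-side trait weights are reversed: (2, 1, 0)
  n3 <- spec6$nodes[[3]]
  ip_proc <- n3$processes[[which(vapply(n3$processes, `[[`, "", "kind") ==
                                   "ideal_point")]]
  expect_equal(ip_proc$weights, c(2, 1, 0))
  # shared parameters: same ERS discrimination and trait intensity
  # discrimination across both intensity nodes, shared location everywhere
  n2 <- spec6$nodes[[2]]
  expect_equal(n2$processes[[1]]$disc, n3$processes[[1]]$disc)
  expect_equal(n2$processes[[2]]$disc, n3$processes[[2]]$disc)
  expect_equal(unique(unlist(lapply(spec6$nodes, function(nd)
    lapply(nd$processes, function(p) if (!is.null(p$loc)) p$loc$name)))),
    "delta")
  spec4 <- irtree_ideal_ers(4, 4)
  expect_equal(vapply(spec4$nodes, `[[`, 0L, "K"), c(1L, 1L, 1L))
  expect_error(irtree_ideal_ers(5, 4), "even")
  # sequential variants drop one intensity process
  expect_equal(length(irtree_ideal_ers(6, 4, "ers")$nodes[[2]]$processes), 1L)
  expect_equal(length(irtree_ideal_ers(6, 4, "trait")$nodes[[2]]$processes), 1L)
})

test_that("midscale builder ties the location to the agreement threshold", {
  spec <- irtree_midscale(3)
  ip_proc <- spec$nodes[[1]]$processes[[2]]
  expect_equal(ip_proc$loc$type, "ratio")
  expect_equal(ip_proc$loc$num, "tau2_1")
  expect_equal(ip_proc$loc$den, "alpha2")
  # trait weights reversed on the disagree-side extreme node
  expect_equal(spec$nodes[[4]]$processes[[2]]$weights, c(1, 0))
  expect_equal(spec$nodes[[3]]$processes[[2]]$weights, c(0, 1))
  # ERS and trait extreme discriminations shared across the two extreme nodes
  expect_equal(spec$nodes[[3]]$processes[[1]]$disc,
               spec$nodes[[4]]$processes[[1]]$disc)
  expect_equal(spec$nodes[[3]]$processes[[2]]$disc,
               spec$nodes[[4]]$processes[[2]]$disc)
  # changing the agreement parameters moves the midscale ideal-point location
  ipar <- list(alpha1 = 1, lambda = 1, alpha2 = 1.5, alpha3 = 1, alpha4 = 1,
               tau1_1 = -0.5, tau2_1 = 0.9, tau3_1 = 0.3, tau4_1 = 0.3)
  p1 <- tree_category_probs(spec, c(theta = 0.9 / 1.5, eta1 = 0, eta2 = 0), ipar)
  ipar2 <- ipar; ipar2$tau2_1 <- -0.9
  p2 <- tree_category_probs(spec, c(theta = -0.9 / 1.5, eta1 = 0, eta2 = 0), ipar2)
  # at theta equal to the implied location the midscale probability is at its
  # peak; moving the tie moves the peak symmetrically
  expect_equal(p1[1, 3], p2[1, 3], tolerance = 1e-12)
})

test_that("midscale responding fades with person-item distance, grows with MRS", {
  spec <- irtree_midscale(1)
  ipar <- list(alpha1 = 1.2, lambda = 1, alpha2 = 1, alpha3 = 1, alpha4 = 1,
               tau1_1 = -0.2, tau2_1 = 0, tau3_1 = 0, tau4_1 = 0)
  # the tied location is tau2/alpha2 = 0: increasing |theta| = distance
  dist <- seq(0, 6, by = 0.5)
  for (eta1 in c(-1, 0, 1)) {
    p_mid <- vapply(dist, function(d)
      tree_category_probs(spec, c(theta = d, eta1 = eta1, eta2 = 0),
                          ipar)[1, 3], 0)
    expect_true(all(diff(p_mid) < 0))
  }
  # at fixed distance, higher MRS raises the midscale probability
  p_by_mrs <- vapply(c(-1, 0, 1), function(m)
    tree_category_probs(spec, c(theta = 0.8, eta1 = m, eta2 = 0), ipar)[1, 3], 0)
  expect_true(all(diff(p_by_mrs) > 0))
})

test_that("compiled engine agrees with the R probability path", {
  set.seed(47)
  for (model in c("I-DI", "I-D", "I-I", "midscale")) {
    sim <- sim_dataset(sim_design(model, N = 25, I = 3, seed = 17))
    spec <- sim$spec
    comp <- ditree:::compile_spec(spec)
    ipar <- ditree:::items_to_ipar(spec, sim$items)
    tm <- as.matrix(sim$persons[, names(spec$traits)])
    X <- ditree:::decompose_matrix(sim$responses, spec$mapping)
    X[is.na(X)] <- -1L
    llm <- ditree:::tree_loglik(tm, ipar, X, comp, reduce = "matrix")
    ll_r <- sapply(1:3, function(i) {
      p <- tree_category_probs(spec, tm, sim$items[i, ])
      log(p[cbind(seq_len(25), sim$responses[, i] + 1)])
    })
    expect_equal(llm, ll_r, tolerance = 1e-12)
    expect_equal(rowSums(llm),
                 ditree:::tree_loglik(tm, ipar, X, comp, reduce = "person"))
    expect_equal(colSums(llm),
                 ditree:::tree_loglik(tm, ipar, X, comp, reduce = "item"))
  }
})

test_that("mapping and spec serializations round-trip", {
  m <- mapping_midscale()
  f <- withr::local_tempfile(fileext = ".csv")
  write_mapping(m, f)
  expect_true(any(grepl("-", readLines(f), fixed = TRUE)))
  m2 <- read_mapping(f)
  expect_identical(unclass(m)[, ], unclass(m2)[, ])

  spec <- irtree_ideal_ers(6, 5)
  fj <- withr::local_tempfile(fileext = ".json")
  write_spec_json(spec, fj)
  spec2 <- read_spec_json(fj)
  c1 <- ditree:::compile_spec(spec)
  c2 <- ditree:::compile_spec(spec2)
  expect_identical(c1$param_names, c2$param_names)
  expect_equal(c1$nodes, c2$nodes)
})

test_that("parameter tables round-trip at full precision", {
  sim <- draw_population(sim_design("I-DI", N = 5, I = 4, seed = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_param_table(sim$items, f)
  back <- read_param_table(f)
  for (nm in setdiff(names(sim$items), "item")) {
    expect_identical(back[[nm]], sim$items[[nm]])
  }
})
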