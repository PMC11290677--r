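test_that("true site diversity is the pooled community's alpha", {
  sim <- toy_survey()
  sm <- sim$samples
  for (s in sm_sites(sm)) {
    rows <- which(sm$site == s)
    pooled <- colnames(sm$abundance)[colSums(sm$abundance[rows, , drop = FALSE]) > 0]
    expect_equal(true_alpha(sm, s, sim$tree), alpha_div(pooled, sim$tree))
  }
  expect_error(true_alpha(sm, "nowhere", sim$tree), "unknown site")
})

test_that("expected alpha proportion hits its boundary cases", {
  sim <- toy_survey()
  cfg <- optimizer_config(runs = 50, seed = 1, exact_threshold = 500)
  full <- c(A = 3, B = 3)
  expect_equal(as.numeric(expected_alpha_proportion(full, sim$samples, sim$tree, cfg)), 1)
  expect_equal(as.numeric(expected_alpha_proportion(c(A = 0, B = 0),
                                                    sim$samples, sim$tree, cfg)), 0)
  expect_error(expected_alpha_proportion(c(A = 4), sim$samples, sim$tree, cfg),
               "exceeds")
})

test_that("monte-carlo expectation agrees with exact subset enumeration", {
  sim <- toy_survey()
  cfg_mc <- optimizer_config(runs = 4000, seed = 5, exact_threshold = 0)  # force MC
  cfg_ex <- optimizer_config(runs = 10, seed = 5, exact_threshold = 500)
  for (n in list(c(A = 1, B = 1), c(A = 2, B = 0), c(A = 2, B = 3))) {
    mc <- expected_alpha_proportion(n, sim$samples, sim$tree, cfg_mc)
    exact <- expected_alpha_proportion(n, sim$samples, sim$tree, cfg_ex)
    expect_equal(attr(exact, "se"), 0)
    expect_lt(abs(as.numeric(mc) - as.numeric(exact)),
              3 * max(attr(mc, "se"), 1e-12))
    # the package's exact mode matches the independent oracle exactly
    expect_equal(as.numeric(exact), oracle_expected_alpha(sim$samples, sim$tree, n),
                 tolerance = 1e-12)
  }
})

test_that("exhaustive optimization finds the planted optimum", {
  ps <- planted_optimum_scenario(budget = 2, seed = 8)
  sim <- simulate_survey(ps$config)
  cfg <- optimizer_config(runs = 100, seed = 3, exact_threshold = 500)
  res <- optim_alpha(sim$samples, sim$tree, ps$cost_model, cfg)
  at2 <- res[res$cost == ps$budget, ]
  expect_equal(c(A = at2$n_A, B = at2$n_B), ps$best)
  expect_equal(at2$value, 1)
  # budget 1: the method covering 3/4 of the tree length wins
  at1 <- res[res$cost == 1, ]
  expect_equal(at1$n_A, 1)
  expect_equal(at1$value, 0.75)
  # every cost level's winner beats all same-cost alternatives (oracle check)
  grid <- expand.grid(A = 0:2, B = 0:2)
  for (i in seq_len(nrow(grid))) {
    n <- c(A = grid$A[i], B = grid$B[i])
    cost <- sum(n)
    row <- res[res$cost == cost, ]
    if (nrow(row) == 1)
      expect_gte(row$value + 1e-12,
                 oracle_expected_alpha(sim$samples, sim$tree, n))
  }
})

test_that("constrained pools and budgets restrict the search", {
  sim <- toy_survey()
  cm <- cost_model(fixed = c(A = 0, B = 0), variable = c(A = 1, B = 1))
  cfg <- optimizer_config(runs = 30, seed = 2, exact_threshold = 200)
  free <- optim_alpha(sim$samples, sim$tree, cm, cfg)
  empty_pool <- optim_alpha(sim$samples, sim$tree, cm, cfg,
                            pool = c(A = 0, B = 0))
  expect_equal(as.data.frame(free), as.data.frame(empty_pool))
  pooled <- optim_alpha(sim$samples, sim$tree, cm, cfg, pool = c(A = 2))
  expect_true(all(pooled$n_A >= 2))
  capped <- optim_alpha(sim$samples, sim$tree, cm, cfg, budget = 3)
  expect_true(all(capped$cost <= 3))
  tiny <- optimizer_config(runs = 10, seed = 1, max_combinations = 4)
  expect_error(optim_alpha(sim$samples, sim$tree, cm, tiny), "nested")
})

test_that("nested optimization builds a monotone accumulation curve", {
  sim <- toy_survey()
  cm <- cost_model(fixed = c(A = 0, B = 0), variable = c(A = 1, B = 1))
  cfg <- optimizer_config(runs = 30, seed = 4, exact_threshold = 500)
  nest <- optim_alpha(sim$samples, sim$tree, cm, cfg, mode = "nested")
  expect_equal(nrow(nest), 6)  # one row per added sample
  expect_true(all(diff(nest$cost) > 0))
  expect_true(all(diff(nest$value) >= -1e-12))  # exact mode: monotone
  expect_equal(nest$value[nrow(nest)], 1)       # complete set captures all
  # greedy curve never beats the per-cost exhaustive optimum
  ex <- optim_alpha(sim$samples, sim$tree, cm, cfg)
  for (i in seq_len(nrow(nest))) {
    match_row <- ex[ex$cost == nest$cost[i], ]
    if (nrow(match_row) == 1) expect_lte(nest$value[i], match_row$value + 1e-9)
  }
  # a single-method survey yields that method repeated
  one <- sim$samples
  keep <- one$method == "A"
  one <- sample_matrix(one$abundance[keep, , drop = FALSE],
                       one$site[keep], one$method[keep])
  n1 <- optim_alpha(one, sim$tree, cm, cfg, mode = "nested")
  expect_equal(n1$n_A, seq_len(nrow(n1)))
})

test_that("beta bias is zero at the full set and matches the oracle", {
  sim <- toy_survey()
  cfg <- optimizer_config(runs = 500, seed = 6, exact_threshold = 0)
  full <- beta_bias(c(A = 3, B = 3), sim$samples, sim$tree,
                    optimizer_config(runs = 5, seed = 1, exact_threshold = 500))
  expect_equal(as.numeric(full), 0)

  n <- c(A = 2, B = 2)
  want <- oracle_beta_bias(sim$samples, sim$tree, n)
  mc <- beta_bias(n, sim$samples, sim$tree, cfg)
  expect_lt(abs(as.numeric(mc) - want), 3 * max(attr(mc, "se"), 1e-12))

  one_site <- sample_matrix(
    sim$samples$abundance[sim$samples$site == "site01", , drop = FALSE],
    sim$samples$site[sim$samples$site == "site01"],
    sim$samples$method[sim$samples$site == "site01"])
  expect_error(beta_bias(c(A = 1), one_site, sim$tree, cfg), "2 sites")
})

test_that("beta optimization prefers least-biased combinations per cost", {
  sim <- toy_survey()
  cm <- cost_model(fixed = c(A = 0, B = 0), variable = c(A = 1, B = 1))
  cfg <- optimizer_config(runs = 40, seed = 7, exact_threshold = 40)
  res <- optim_beta(sim$samples, sim$tree, cm, cfg)
  expect_true(all(res$value >= 0 & res$value <= 1))
  expect_equal(res$value[res$cost == 6], 1)  # complete set: bias 0
  # winner at each cost at least ties the alternatives (exact scoring)
  grid <- expand.grid(A = 0:3, B = 0:3)
  for (cost in unique(res$cost)) {
    cand <- grid[grid$A + grid$B == cost, ]
    effs <- vapply(seq_len(nrow(cand)), function(i) {
      1 - as.numeric(beta_bias(c(A = cand$A[i], B = cand$B[i]),
                               sim$samples, sim$tree, cfg))
    }, numeric(1))
    expect_equal(res$value[res$cost == cost], max(effs), tolerance = 1e-9)
  }
})

test_that("results are reproducible given the master seed", {
  sim <- toy_survey()
  cm <- cost_model(fixed = c(A = 0, B = 1), variable = c(A = 1, B = 2))
  cfg <- optimizer_config(runs = 50, seed = 11, exact_threshold = 0)  # pure MC
  r1 <- optim_alpha(sim$samples, sim$tree, cm, cfg)
  r2 <- optim_alpha(sim$samples, sim$tree, cm, cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  b1 <- beta_bias(c(A = 1, B = 2), sim$samples, sim$tree, cfg)
  b2 <- beta_bias(c(A = 1, B = 2), sim$samples, sim$tree, cfg)
  expect_identical(b1, b2)
})
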