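test_that("moment matching recovers gamma and beta hyperparameters", {
  g <- moment_match("gamma", 100, 10)
  expect_equal(g$shape, 100)
  expect_equal(g$scale, 1)
  b <- moment_match("beta", 0.9, 0.05)
  expect_equal(b$alpha, 31.5, tolerance = 1e-9)
  expect_equal(b$beta, 3.5, tolerance = 1e-9)
  # round trip: the implied mean/sd equal the inputs
  expect_equal(b$alpha / (b$alpha + b$beta), 0.9, tolerance = 1e-12)
  expect_equal(sqrt(b$alpha * b$beta /
                      ((b$alpha + b$beta)^2 * (b$alpha + b$beta + 1))),
               0.05, tolerance = 1e-9)
})

test_that("degenerate and infeasible distributions are handled", {
  d <- moment_match("gamma", 50, 0)
  expect_equal(d$family, "fixed")
  expect_error(moment_match("beta", 0.5, 0.6), "infeasible")
  expect_error(moment_match("beta", 1.2, 0.1), "\\(0, 1\\)")
  expect_error(moment_match("gamma", -5, 1), "positive")
})

test_that("a parameter with no influence has exactly zero swing", {
  spec <- short_spec()
  # advanced-cancer cycle cost is never reached when no one can progress
  spec$params$rate_lgd_prog_index <- 0
  spec$params$rate_lgd_prog_surv <- 0
  spec$params$rate_nd_prog <- 0
  spec$params$rate_postrfa_prog <- 0
  spec$params$rate_postemr_prog <- 0
  e <- one_way(spec, "cost_eac_advanced_cycle", c(500, 5000))
  expect_equal(e$swing, 0)
})

test_that("one-way range midpoint reproduces the base case", {
  spec <- short_spec()
  base_val <- spec$params$cost_rfa
  e <- one_way(spec, "cost_rfa", c(base_val - 1000, base_val + 1000),
               n_points = 3L)
  a <- run_strategy(spec, "RFA_surveillance_LGD")$outcome
  b <- run_strategy(spec, "surveillance_all_LGD")$outcome
  base_icer <- (a$discounted_cost - b$discounted_cost) /
    (a$discounted_qaly - b$discounted_qaly)
  expect_equal(e$grid$icer[2], base_icer, tolerance = 1e-9)
})

test_that("the ablation-strategy ICER rises with the ablation disutility", {
  # range restricted to where the incremental QALY stays positive; past that
  # point the comparison flips to dominance rather than a higher ratio
  spec <- short_spec()
  e <- one_way(spec, "du_rfa", c(0.01, 0.08), n_points = 4L)
  expect_true(all(e$grid$delta_qaly > 0))
  expect_true(all(diff(e$grid$icer) > 0))
})

test_that("tornado entries are sorted by descending swing", {
  spec <- short_spec()
  ds <- default_distribution_specs(spec)
  tor <- tornado(spec, ds, parameters = c("du_rfa", "cost_rfa", "cost_endoscopy",
                                          "u_post_rfa"))
  expect_true(all(diff(tor$swing) <= 0))
  expect_true("du_rfa" %in% tor$parameter)
})

test_that("threshold finding matches a closed-form linear toy", {
  # fake spec whose ICER is linear in the parameter via direct construction:
  # use the real model but check the convergence contract instead
  spec <- short_spec()
  out <- threshold_find(spec, "du_rfa", c(0.001, 0.9), wtp = spec$wtp,
                        tol = 1e-4)
  if (out$crossing) {
    expect_equal(out$icer_at_value, spec$wtp, tolerance = 0.02 * spec$wtp)
    out2 <- threshold_find(spec, "du_rfa", c(0.001, 0.9), wtp = spec$wtp,
                           tol = 1e-5)
    expect_lt(abs(out2$value - out$value), 1e-4)
  }
  none <- threshold_find(spec, "cost_rfa", c(5999, 6001), wtp = 1e9)
  expect_false(none$crossing)
})

test_that("PSA with all-fixed distributions reproduces the deterministic run", {
  spec <- short_spec()
  ds <- default_distribution_specs(spec)
  ds$se <- 0
  psa <- run_psa(spec, ds, n_draws = 3, seed = 5)
  det <- run_all_strategies(spec)
  for (s in strategies()) {
    expect_equal(unique(psa$cost[psa$strategy == s]),
                 det$cost[det$strategy == s], tolerance = 1e-9)
    expect_equal(unique(psa$qaly[psa$strategy == s]),
                 det$qaly[det$strategy == s], tolerance = 1e-9)
  }
})

test_that("PSA is reproducible and extends without reshuffling earlier draws", {
  spec <- short_spec()
  ds <- default_distribution_specs(spec)
  a <- run_psa(spec, ds, n_draws = 4, seed = 7)
  b <- run_psa(spec, ds, n_draws = 4, seed = 7)
  expect_equal(as.data.frame(a), as.data.frame(b))
  c6 <- run_psa(spec, ds, n_draws = 6, seed = 7)
  expect_equal(as.data.frame(c6[c6$draw <= 4, ]), as.data.frame(a))
})

test_that("CE-plane cloud mean approaches the deterministic point", {
  spec <- short_spec()
  ds <- default_distribution_specs(spec)
  # vary only payoff parameters: outcomes are linear in costs/utilities, so
  # the cloud mean is an unbiased estimate of the deterministic point
  ds$se[!grepl("^(cost_|u_|du_)", ds$parameter)] <- 0
  n <- 300
  psa <- run_psa(spec, ds, n_draws = n, seed = 11,
                 strategy_names = c("surveillance_all_LGD", "RFA_surveillance_LGD"))
  cp <- ce_plane(psa)
  det <- run_all_strategies(spec)
  d_cost <- det$cost[det$strategy == "RFA_surveillance_LGD"] -
    det$cost[det$strategy == "surveillance_all_LGD"]
  d_qaly <- det$qaly[det$strategy == "RFA_surveillance_LGD"] -
    det$qaly[det$strategy == "surveillance_all_LGD"]
  se_cost <- sd(cp$delta_cost) / sqrt(n)
  se_qaly <- sd(cp$delta_qaly) / sqrt(n)
  expect_lt(abs(mean(cp$delta_cost) - d_cost), 3 * se_cost)
  expect_lt(abs(mean(cp$delta_qaly) - d_qaly), 3 * se_qaly)
})

test_that("CEAC fractions come from direct NMB enumeration and sum to 1", {
  # 3 hand-constructed draws with known orderings
  psa <- data.frame(
    draw = rep(1:3, each = 2),
    strategy = rep(c("A", "B"), 3),
    cost = c(0, 100, 0, 100, 0, 100),
    qaly = c(1, 1.002, 1, 1.010, 1, 0.990))
  class(psa) <- c("psa_result", class(psa))
  # at wtp 50000: B wins draw 1 (NMB +0.002*50000-100 = 0) -> tie, split;
  # B wins draw 2 (+400); A wins draw 3
  cc <- ceac(psa, wtp_grid = c(0, 50000))
  at0 <- cc[cc$wtp == 0, ]
  expect_equal(at0$fraction[at0$strategy == "A"], 1)  # cheapest wins at 0
  at5 <- cc[cc$wtp == 50000, ]
  expect_equal(at5$fraction[at5$strategy == "B"], (0.5 + 1) / 3)
  expect_equal(at5$fraction[at5$strategy == "A"], (0.5 + 1) / 3)
  agg <- as.vector(tapply(cc$fraction, cc$wtp, sum))
  expect_equal(agg, rep(1, 2), tolerance = 1e-12)
})

test_that("single-strategy CEAC is 1 everywhere", {
  psa <- data.frame(draw = 1:3, strategy = "only", cost = 1:3, qaly = 1:3)
  class(psa) <- c("psa_result", class(psa))
  cc <- ceac(psa, wtp_grid = c(0, 1e4, 1e5))
  expect_true(all(cc$fraction == 1))
})

test_that("full-model CEAC fractions sum to 1 across strategies at every wtp", {
  spec <- short_spec()
  ds <- default_distribution_specs(spec)
  psa <- run_psa(spec, ds, n_draws = 60, seed = 13)
  cc <- ceac(psa, wtp_grid = seq(0, 100000, by = 20000))
  sums <- as.vector(tapply(cc$fraction, cc$wtp, sum))
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-12)
  expect_true(all(cc$fraction >= 0 & cc$fraction <= 1))
})
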