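test_that("rate/probability conversions are exact and invertible", {
  expect_equal(rate_to_probability(0, 0.5), 0)
  expect_equal(rate_to_probability(0.021807, 0.5), 1 - exp(-0.0109035),
               tolerance = 1e-12)
  expect_equal(round(rate_to_probability(0.021807, 0.5), 6), 0.010844)
  r <- c(0.001, 0.05, 0.5, 2)
  expect_equal(probability_to_rate(rate_to_probability(r, 0.5), 0.5), r,
               tolerance = 1e-12)
  expect_error(rate_to_probability(-1), "non-negative")
  expect_error(probability_to_rate(1), "in \\[0, 1\\)")
})

test_that("discount factors follow discrete annual compounding", {
  expect_equal(discount_factor(5, 0, 0.5), 1)
  expect_equal(discount_factor(2, 0.05, 0.5), 1 / 1.05, tolerance = 1e-9)
  expect_equal(discount_factor(70, 0.05, 0.5), 1.05^-35, tolerance = 1e-9)
  expect_error(discount_factor(1, -1.5), "exceed -1")
})

test_that("identity transitions leave occupancy constant; absorption holds", {
  P <- diag(3); dimnames(P) <- list(letters[1:3], letters[1:3])
  tr <- markov_trace(P, c(0.2, 0.3, 0.5), 10)
  expect_true(all(apply(tr, 1, function(r) all(r == c(0.2, 0.3, 0.5)))))

  P2 <- two_state_P(0.1)
  tr2 <- markov_trace(P2, c(0, 1), 5)  # all mass absorbed at t = 0
  expect_true(all(tr2[, "dead"] == 1))
})

test_that("two-state survival follows the closed form 0.9^t", {
  tr <- markov_trace(two_state_P(0.1), c(1, 0), 20)
  expect_equal(tr[, "alive"], 0.9^(0:20), tolerance = 1e-12)
})

test_that("non-stochastic matrices are rejected with the offending row named", {
  P <- two_state_P(0.1); P["alive", "dead"] <- 0.2
  expect_error(markov_trace(P, c(1, 0), 5), "alive")
})

test_that("undiscounted QALY accrual matches the geometric-series closed form", {
  m <- toy_model(two_state_P(0.1), utilities = c(1, 0), n_cycles = 20L,
                 cycle_length = 0.5, discount_rate = 0)
  out <- accumulate_outcomes(run_cohort(m), m)
  expect_equal(out$discounted_qaly, 0.5 * (1 - 0.9^20) / 0.1, tolerance = 1e-9)
  expect_equal(out$discounted_cost, 0)
})

test_that("full health for the whole horizon yields horizon QALYs", {
  P <- diag(2); dimnames(P) <- list(c("a", "b"), c("a", "b"))
  m <- toy_model(P, utilities = c(1, 1), n_cycles = 70L, cycle_length = 0.5,
                 discount_rate = 0)
  out <- accumulate_outcomes(run_cohort(m), m)
  expect_equal(out$discounted_qaly, 35)
})

test_that("zero discounting equates discounted and undiscounted streams", {
  spec <- short_spec()
  spec$discount_rate <- 0
  o <- run_strategy(spec, "RFA_all_LGD")$outcome
  expect_equal(o$discounted_cost, o$undiscounted_cost, tolerance = 1e-12)
  expect_equal(o$discounted_qaly, o$undiscounted_qaly, tolerance = 1e-12)
})

test_that("traces conserve probability and mortality is monotone, all strategies", {
  spec <- default_model_spec()
  for (s in strategies()) {
    tr <- run_cohort(spec, s)
    expect_equal(unname(rowSums(tr)), rep(1, nrow(tr)), tolerance = 1e-9)
    dead <- tr[, "cancer_death"] + tr[, "other_death"]
    expect_true(all(diff(dead) >= -1e-12))
  }
})

test_that("cohort engine matches a microsimulation oracle on the 4-state toy", {
  P <- four_state_P()
  start <- c(1, 0, 0, 0)
  n_cycles <- 10L; n_ind <- 2e4
  det <- markov_trace(P, start, n_cycles)
  mc <- microsimulate(P, start, n_cycles, n_individuals = n_ind, seed = 2)
  se <- sqrt(pmax(det * (1 - det), 1e-12) / n_ind)
  z <- abs(mc - det) / se
  expect_true(all(z[n_cycles + 1, ] <= 3))  # final-cycle marginals
  expect_true(all(z <= 4))                  # joint band over the trajectory
})

test_that("surveillance strategy leaves the LGD rows unrewired", {
  spec <- default_model_spec()
  base <- build_strategy_model(spec, "surveillance_all_LGD")
  expect_gt(base$P["LGD_index", "NDBE_surv6m_index"], 0)
  expect_equal(base$P["LGD_index", "post_RFA"], 0)

  all_rfa <- build_strategy_model(spec, "RFA_all_LGD")
  # full ablation routing: no residual flow into the surveillance tunnel
  expect_equal(all_rfa$P["LGD_index", "NDBE_surv6m_index"], 0)
  expect_equal(all_rfa$P["LGD_surv", "NDBE_surv6m_surv"], 0)
  expect_gt(all_rfa$P["LGD_surv", "post_RFA"], 0)
})

test_that("ablating only surveillance-LGD is inert for an all-index cohort", {
  spec <- default_model_spec()
  spec$start_distribution[] <- 0
  spec$start_distribution["LGD_index"] <- 1
  a <- run_strategy(spec, "surveillance_all_LGD")
  b <- run_strategy(spec, "RFA_surveillance_LGD")
  expect_equal(a$trace, b$trace, tolerance = 1e-12)
  expect_equal(a$outcome$discounted_cost, b$outcome$discounted_cost,
               tolerance = 1e-9)
  expect_equal(a$outcome$discounted_qaly, b$outcome$discounted_qaly,
               tolerance = 1e-9)
})

test_that("raising the ablation disutility weakly hurts every strategy and the
           ablation strategies most", {
  # every strategy ablates at the HGD stage, so the procedure disutility
  # touches all four; LGD-ablation strategies apply it far more often
  spec <- short_spec()
  qalys <- function(sp) {
    sapply(strategies(), function(s) run_strategy(sp, s)$outcome$discounted_qaly)
  }
  q0 <- qalys(spec)
  spec2 <- spec
  spec2$params$du_rfa <- spec$params$du_rfa * 4
  q1 <- qalys(spec2)
  loss <- q0 - q1
  expect_true(all(loss >= 0))
  for (s in setdiff(strategies(), "surveillance_all_LGD")) {
    expect_gt(loss[s], loss["surveillance_all_LGD"])
  }
  # with ablation restricted to the LGD stage the surveillance arm is inert
  spec3 <- spec
  spec3$params$p_hgd_rfa <- 0
  spec3$params$p_t1a_treat <- 0  # no flow into the post-ablation states at all
  spec4 <- spec3
  spec4$params$du_rfa <- spec3$params$du_rfa * 4
  expect_equal(run_strategy(spec4, "surveillance_all_LGD")$outcome$discounted_qaly,
               run_strategy(spec3, "surveillance_all_LGD")$outcome$discounted_qaly,
               tolerance = 1e-9)
})

test_that("event payoffs are charged on transition flow", {
  # single certain transition with an event cost, one cycle
  P <- matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  ec <- matrix(0, 2, 2); ec[1, 2] <- 100
  m <- toy_model(P, utilities = c(0, 0), n_cycles = 3L, discount_rate = 0,
                 event_cost = ec)
  out <- accumulate_outcomes(run_cohort(m), m)
  expect_equal(out$discounted_cost, 100)  # charged once, on the move
})

test_that("cumulative EAC incidence counts inflow once and stays in [0, 1]", {
  spec <- default_model_spec()
  o <- run_strategy(spec, "surveillance_all_LGD")$outcome
  expect_gt(o$cumulative_eac_incidence, 0)
  expect_lt(o$cumulative_eac_incidence, 1)
  # ablating everyone must reduce cancer incidence
  o2 <- run_strategy(spec, "RFA_all_LGD")$outcome
  expect_lt(o2$cumulative_eac_incidence, o$cumulative_eac_incidence)
})
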