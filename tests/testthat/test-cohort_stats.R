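test_that("crude proportions match the published cohort percentages", {
  cases <- list(
    list(46, 914, 5.0), list(0, 914, 0.0), list(14, 90, 15.6),
    list(25, 727, 3.4), list(7, 97, 7.2)
  )
  for (cs in cases) {
    expect_equal(crude_proportion(cs[[1]], cs[[2]]), cs[[3]])
  }
  expect_error(crude_proportion(1, 0), "positive")
  expect_error(crude_proportion(10, 5), "\\[0, n\\]")
})

test_that("round_half_up rounds ties away from zero", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(15.55, 1), 15.6)
})

test_that("exact Poisson rates agree with a chi-square quantile oracle", {
  # oracle computed directly from the closed-form chi-square bounds
  oracle <- function(k, py, a = 0.05) {
    lo <- if (k == 0) 0 else qchisq(a / 2, 2 * k) / 2
    hi <- qchisq(1 - a / 2, 2 * k + 2) / 2
    c(100 * k / py, 100 * lo / py, 100 * hi / py)
  }
  for (cs in list(c(25, 3872), c(7, 699), c(14, 642), c(46, 5212), c(3, 17))) {
    r <- person_time_rate(cs[1], cs[2])
    o <- oracle(cs[1], cs[2])
    expect_equal(c(r$rate_per_100py, r$ci_low, r$ci_high), o, tolerance = 1e-9)
  }
  # frozen chi-square quantiles for the 7-event group
  expect_equal(qchisq(0.025, 14) / 2, 2.814363, tolerance = 1e-6)
  expect_equal(qchisq(0.975, 16) / 2, 14.42268, tolerance = 1e-6)
})

test_that("rounded rates reproduce the published surveillance table", {
  r1 <- person_time_rate(25, 3872)
  r2 <- person_time_rate(7, 699)
  r3 <- person_time_rate(14, 642)
  rp <- person_time_rate(46, 5212)
  expect_equal(round_half_up(c(r1$rate_per_100py, r1$ci_low, r1$ci_high)),
               c(0.6, 0.4, 1.0))
  expect_equal(round_half_up(c(r2$rate_per_100py, r2$ci_low, r2$ci_high)),
               c(1.0, 0.4, 2.1))
  expect_equal(round_half_up(c(r3$rate_per_100py, r3$ci_low, r3$ci_high)),
               c(2.2, 1.2, 3.7))
  expect_equal(round_half_up(c(rp$rate_per_100py, rp$ci_low, rp$ci_high)),
               c(0.9, 0.6, 1.2))
})

test_that("zero events give a zero rate and a zero lower bound", {
  r <- person_time_rate(0, 100)
  expect_equal(r$rate_per_100py, 0)
  expect_equal(r$ci_low, 0)
  expect_gt(r$ci_high, 0)
})

test_that("rate CI width decreases monotonically in person-years", {
  widths <- sapply(c(100, 200, 400, 800, 1600), function(py) {
    r <- person_time_rate(10, py)
    r$ci_high - r$ci_low
  })
  expect_true(all(diff(widths) < 0))
})

test_that("Garwood 95% intervals reach nominal coverage", {
  set.seed(11)
  rate <- 2.5; py <- 400
  ks <- rpois(1500, rate * py / 100)
  covered <- vapply(ks, function(k) {
    r <- person_time_rate(k, py)
    r$ci_low <= rate && rate <= r$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.94)
})

test_that("exact conditional IRRs reproduce the published ratios", {
  r1 <- incidence_rate_ratio(7, 699, 25, 3872)
  r2 <- incidence_rate_ratio(14, 642, 25, 3872)
  expect_equal(round_half_up(c(r1$irr, r1$ci_low, r1$ci_high)), c(1.6, 0.6, 3.7))
  expect_equal(round_half_up(c(r2$irr, r2$ci_low, r2$ci_high)), c(3.4, 1.6, 6.8))
})

test_that("IRR bounds agree with a Clopper-Pearson oracle", {
  # binomial-conditioning oracle built from qbeta directly
  k1 <- 7; k0 <- 25; n <- k1 + k0; scale <- 3872 / 699
  p_lo <- qbeta(0.025, k1, n - k1 + 1)
  p_hi <- qbeta(0.975, k1 + 1, n - k1)
  r <- incidence_rate_ratio(7, 699, 25, 3872)
  expect_equal(r$ci_low, p_lo / (1 - p_lo) * scale, tolerance = 1e-12)
  expect_equal(r$ci_high, p_hi / (1 - p_hi) * scale, tolerance = 1e-12)
})

test_that("IRR of a group against itself is 1 with a CI containing 1", {
  r <- incidence_rate_ratio(14, 642, 14, 642)
  expect_equal(r$irr, 1)
  expect_lt(r$ci_low, 1)
  expect_gt(r$ci_high, 1)
})

test_that("zero reference events flag an unbounded ratio without erroring", {
  r <- incidence_rate_ratio(3, 100, 0, 100)
  expect_true(r$reference_zero_events)
  expect_true(is.infinite(r$irr) || is.infinite(r$ci_high))
})

test_that("cohort_summary sums per-record exposure exactly", {
  set.seed(5)
  tab <- generate_cohort(synthetic_cohort_spec(
    group_sizes = c(ND = 50, LGD_entry = 20, LGD_surv = 20), seed = 5))
  s <- cohort_summary(tab)
  # independent per-record summation oracle
  for (g in cohort_groups()) {
    expect_equal(s$person_years[s$group == g],
                 sum(tab$person_years[tab$group == g]))
    expect_equal(s$events[s$group == g], sum(tab$event[tab$group == g]))
  }
  expect_equal(s$person_years[s$group == "All"], sum(tab$person_years))
})

test_that("cohort_summary rejects unknown labels and empty tables pass through", {
  empty <- data.frame(patient_id = integer(), group = character(),
                      person_years = numeric(), event = integer())
  expect_equal(nrow(cohort_summary(empty)), 0)
  bad <- data.frame(patient_id = 1, group = "HGD_entry",
                    person_years = 1, event = 0)
  expect_error(cohort_summary(bad), "unknown group label")
})

test_that("progression_rates reproduces the full published table layout", {
  tab <- progression_rates(fixture_table4())
  nd <- tab[tab$group == "ND", ]
  expect_equal(nd$irr, 1)
  surv <- tab[tab$group == "LGD_surv", ]
  expect_equal(round_half_up(c(surv$rate_per_100py, surv$ci_low, surv$ci_high)),
               c(2.2, 1.2, 3.7))
  expect_equal(round_half_up(c(surv$irr, surv$irr_low, surv$irr_high)),
               c(3.4, 1.6, 6.8))
  expect_true(is.na(tab$irr[tab$group == "All"]))
})

test_that("cohort CSV round-trips through read_cohort with validation", {
  tab <- generate_cohort(synthetic_cohort_spec(
    group_sizes = c(ND = 20, LGD_entry = 5, LGD_surv = 5), seed = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  back <- read_cohort(f)
  expect_equal(back$person_years, tab$person_years)
  bad <- tab; bad$event_type[bad$event == 0][1] <- "EAC"
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_cohort(f), "event_type")
})
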