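#' Method-of-moments distribution parameters for sensitivity analysis
#'
#' Gamma distributions for costs and beta distributions for probabilities
#' and utility values, parameterised from a mean and standard error:
#' gamma shape = mean^2/se^2, scale = se^2/mean; beta
#' nu = mean(1-mean)/se^2 - 1, alpha = mean*nu, beta = (1-mean)*nu. A beta
#' variance of at least mean(1-mean) is infeasible and rejected. `se = 0`
#' yields a degenerate draw at the mean for any family.
#'
#' @param family `"gamma"`, `"beta"` or `"fixed"`.
#' @param mean distribution mean (beta: in (0,1); gamma: > 0).
#' @param se standard error (>= 0).
#' @return list with `family`, `mean`, `se` and the derived parameters
#'   (`shape`/`scale` or `alpha`/`beta`).
#' @export
#' @examples
#' moment_match("gamma", 100, 10)   # shape 100, scale 1
#' moment_match("beta", 0.9, 0.05)  # alpha 31.5, beta 3.5
moment_match <- function(family = c("gamma", "beta", "fixed"), mean, se) {
  family <- match.arg(family)
  if (se < 0) stop("moment_match(): se must be non-negative", call. = FALSE)
  out <- list(family = family, mean = mean, se = se)
  if (se == 0 || family == "fixed") {
    out$family <- if (se == 0) "fixed" else family
    return(out)
  }
  if (family == "gamma") {
    if (mean <= 0) stop("moment_match(): gamma mean must be positive", call. = FALSE)
    out$shape <- mean^2 / se^2
    out$scale <- se^2 / mean
  } else {
    if (mean <= 0 || mean >= 1) {
      stop("moment_match(): beta mean must lie in (0, 1)", call. = FALSE)
    }
    if (se^2 >= mean * (1 - mean)) {
      stop("moment_match(): beta variance ", format(se^2),
           " is infeasible for mean ", format(mean), call. = FALSE)
    }
    nu <- mean * (1 - mean) / se^2 - 1
    out$alpha <- mean * nu
    out$beta <- (1 - mean) * nu
  }
  out
}

# one draw from a moment-matched distribution
.draw_param <- function(mm) {
  switch(mm$family,
    fixed = mm$mean,
    gamma = stats::rgamma(1, shape = mm$shape, scale = mm$scale),
    beta  = stats::rbeta(1, mm$alpha, mm$beta)
  )
}

#' Default distribution assignments for the model parameters
#'
#' Assigns gamma distributions to costs and beta distributions to
#' probabilities, utilities and disutilities. Annual rates are varied on
#' the per-cycle probability scale (family `"beta_rate"`: the rate is
#' converted to a cycle probability, drawn from a beta, and converted
#' back). Standard errors default to a fixed fraction of the mean because
#' the published parameter uncertainty tables are not reproduced here;
#' they are placeholders to be replaced with sourced values.
#'
#' @param spec a [model_spec()].
#' @param cost_cv coefficient of variation for cost parameters.
#' @param prob_cv coefficient of variation for probability/utility/rate
#'   parameters.
#' @return data frame with columns `parameter`, `family`, `mean`, `se`.
#' @export
default_distribution_specs <- function(spec, cost_cv = 0.2, prob_cv = 0.1) {
  p <- spec$params
  rows <- lapply(names(p), function(nm) {
    val <- p[[nm]]
    if (grepl("^cost_", nm)) {
      data.frame(parameter = nm, family = "gamma", mean = val, se = cost_cv * val)
    } else if (grepl("^rate_", nm)) {
      m <- rate_to_probability(val, spec$cycle_length)
      data.frame(parameter = nm, family = "beta_rate", mean = m,
                 se = min(prob_cv * m, 0.9 * sqrt(m * (1 - m))))
    } else {
      data.frame(parameter = nm, family = "beta", mean = val,
                 se = min(prob_cv * val, 0.9 * sqrt(val * (1 - val))))
    }
  })
  do.call(rbind, rows)
}

# apply one sampled parameter vector onto a spec
.spec_with_params <- function(spec, sampled) {
  spec$params[names(sampled)] <- sampled
  spec
}

# sample every distribution once; returns a named list of parameter values
.sample_params <- function(spec, dist_specs) {
  out <- list()
  for (i in seq_len(nrow(dist_specs))) {
    d <- dist_specs[i, ]
    fam <- d$family
    if (fam == "beta_rate") {
      mm <- moment_match("beta", d$mean, d$se)
      p <- .draw_param(mm)
      out[[d$parameter]] <- probability_to_rate(min(p, 1 - 1e-12), spec$cycle_length)
    } else {
      mm <- moment_match(fam, d$mean, d$se)
      out[[d$parameter]] <- .draw_param(mm)
    }
  }
  out
}

#' One-way deterministic sensitivity analysis for one parameter
#'
#' Re-runs a strategy pair over a grid of values of a single parameter with
#' everything else fixed, recording incremental cost, incremental QALYs and
#' the raw incremental ratio at each point. The tornado swing is the
#' absolute difference between the ratios at the range endpoints.
#'
#' @param spec a [model_spec()].
#' @param parameter name of the parameter to vary.
#' @param range numeric length-2 vector (low, high); probability-type
#'   parameters are clipped to [0, 1] with a warning.
#' @param strategy_pair character length-2: (comparator, baseline).
#' @param n_points grid size (default 2: the endpoints).
#' @return list of class `tornado_entry`: `parameter`, `low_input`,
#'   `high_input`, `icer_at_low`, `icer_at_high`, `swing`, and the full
#'   `grid` data frame (`value`, `delta_cost`, `delta_qaly`, `icer`).
#' @export
one_way <- function(spec, parameter, range,
                    strategy_pair = c("RFA_surveillance_LGD", "surveillance_all_LGD"),
                    n_points = 2L) {
  if (!parameter %in% names(spec$params)) {
    stop("one_way(): unknown parameter '", parameter, "'", call. = FALSE)
  }
  if (grepl("^(p_|u_|du_|frac_)", parameter) &&
      (range[1] < 0 || range[2] > 1)) {
    warning("one_way(): range for '", parameter, "' clipped to [0, 1]")
    range <- pmin(pmax(range, 0), 1)
  }
  grid <- seq(range[1], range[2], length.out = max(2L, n_points))
  rows <- lapply(grid, function(v) {
    sp <- spec
    sp$params[[parameter]] <- v
    a <- run_strategy(sp, strategy_pair[1])$outcome
    b <- run_strategy(sp, strategy_pair[2])$outcome
    dc <- a$discounted_cost - b$discounted_cost
    dq <- a$discounted_qaly - b$discounted_qaly
    data.frame(value = v, delta_cost = dc, delta_qaly = dq, icer = dc / dq)
  })
  grid_df <- do.call(rbind, rows)
  structure(
    list(parameter = parameter,
         low_input = range[1], high_input = range[2],
         icer_at_low = grid_df$icer[1],
         icer_at_high = grid_df$icer[nrow(grid_df)],
         swing = abs(grid_df$icer[nrow(grid_df)] - grid_df$icer[1]),
         grid = grid_df),
    class = "tornado_entry"
  )
}

#' Tornado analysis over several parameters
#'
#' @param spec a [model_spec()].
#' @param dist_specs data frame from [default_distribution_specs()]; one-way
#'   ranges default to mean +/- 2 se (clipped to validity), the standard
#'   choice when explicit ranges are not supplied.
#' @param strategy_pair passed to [one_way()].
#' @param parameters subset of parameters to vary (default: all with
#'   positive se).
#' @return data frame sorted by descending swing with columns `parameter`,
#'   `low_input`, `high_input`, `icer_at_low`, `icer_at_high`, `swing`.
#' @export
tornado <- function(spec, dist_specs = default_distribution_specs(spec),
                    strategy_pair = c("RFA_surveillance_LGD", "surveillance_all_LGD"),
                    parameters = NULL) {
  ds <- dist_specs[dist_specs$se > 0, ]
  if (!is.null(parameters)) ds <- ds[ds$parameter %in% parameters, ]
  rows <- lapply(seq_len(nrow(ds)), function(i) {
    d <- ds[i, ]
    base <- spec$params[[d$parameter]]
    half <- 2 * d$se
    if (d$family == "beta_rate") {
      rng <- probability_to_rate(
        pmin(pmax(c(d$mean - half, d$mean + half), 0), 1 - 1e-9),
        spec$cycle_length)
    } else {
      rng <- c(base - if (d$family == "gamma") 2 * d$se else half,
               base + if (d$family == "gamma") 2 * d$se else half)
      if (d$family == "beta") rng <- pmin(pmax(rng, 0), 1)
      if (d$family == "gamma") rng <- pmax(rng, 0)
    }
    e <- suppressWarnings(one_way(spec, d$parameter, rng, strategy_pair))
    data.frame(parameter = e$parameter, low_input = e$low_input,
               high_input = e$high_input, icer_at_low = e$icer_at_low,
               icer_at_high = e$icer_at_high, swing = e$swing)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing), ]
  rownames(out) <- NULL
  out
}

#' Find the parameter value at which the ICER crosses willingness-to-pay
#'
#' Bisection on the parameter: assumes the incremental ratio of the
#' strategy pair is monotone over the bracket. Returns a no-crossing result
#' (not an error) when the ratio does not cross the threshold inside the
#' bracket.
#'
#' @param spec a [model_spec()].
#' @param parameter parameter name.
#' @param bracket numeric length-2 search interval.
#' @param wtp willingness-to-pay threshold.
#' @param strategy_pair (comparator, baseline).
#' @param tol bisection stops when the parameter interval is below this.
#' @return list with `crossing` (logical), `value` (crossing point or `NA`),
#'   `icer_at_value`.
#' @export
threshold_find <- function(spec, parameter, bracket, wtp = spec$wtp,
                           strategy_pair = c("RFA_surveillance_LGD",
                                             "surveillance_all_LGD"),
                           tol = 1e-6) {
  icer_at <- function(v) {
    sp <- spec
    sp$params[[parameter]] <- v
    a <- run_strategy(sp, strategy_pair[1])$outcome
    b <- run_strategy(sp, strategy_pair[2])$outcome
    (a$discounted_cost - b$discounted_cost) /
      (a$discounted_qaly - b$discounted_qaly)
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- icer_at(lo) - wtp
  f_hi <- icer_at(hi) - wtp
  if (is.na(f_lo) || is.na(f_hi) || f_lo * f_hi > 0) {
    return(list(crossing = FALSE, value = NA_real_, icer_at_value = NA_real_))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- icer_at(mid) - wtp
    if (f_lo * f_mid <= 0) { hi <- mid; f_hi <- f_mid } else { lo <- mid; f_lo <- f_mid }
  }
  value <- (lo + hi) / 2
  list(crossing = TRUE, value = value, icer_at_value = icer_at(value))
}

#' Probabilistic sensitivity analysis
#'
#' Per draw, samples every parameter from its assigned distribution,
#' rebuilds the model and runs all strategies, recording cost, QALYs and
#' cumulative cancer incidence. Draw `i` uses the RNG substream
#' `seed + i`, so earlier draws are unchanged when `n_draws` grows.
#' Sampled rows whose outflows exceed 1 are renormalized and counted in
#' the `audit` attribute.
#'
#' @param spec a [model_spec()].
#' @param dist_specs data frame (`parameter`, `family`, `mean`, `se`); see
#'   [default_distribution_specs()].
#' @param n_draws number of simulations (published analyses typically use
#'   5000).
#' @param seed base RNG seed.
#' @param strategy_names strategies to run each draw.
#' @return data frame of class `psa_result` with columns `draw`, `strategy`,
#'   `cost`, `qaly`, `eac_incidence`; attribute `audit` counts renormalized
#'   rows per draw.
#' @export
run_psa <- function(spec, dist_specs = default_distribution_specs(spec),
                    n_draws = 5000L, seed = 1L,
                    strategy_names = strategies()) {
  if (n_draws < 1) stop("run_psa(): n_draws must be >= 1", call. = FALSE)
  res <- vector("list", n_draws)
  audit <- integer(0)
  for (i in seq_len(n_draws)) {
    set.seed(seed + i)
    sampled <- .sample_params(spec, dist_specs)
    sp <- .spec_with_params(spec, sampled)
    rows <- lapply(strategy_names, function(s) {
      model <- build_strategy_model(sp, s, renormalize = TRUE)
      rn <- attr(model, "renormalized_rows")
      if (length(rn)) audit[as.character(i)] <<- length(rn)
      trace <- run_cohort(model)
      o <- accumulate_outcomes(trace, model)
      data.frame(draw = i, strategy = s, cost = o$discounted_cost,
                 qaly = o$discounted_qaly,
                 eac_incidence = o$cumulative_eac_incidence)
    })
    res[[i]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("psa_result", class(out))
  attr(out, "audit") <- audit
  out
}

#' Cost-effectiveness plane points
#'
#' Incremental cost and QALYs of each strategy against a baseline, per
#' draw.
#'
#' @param psa a `psa_result` from [run_psa()].
#' @param baseline baseline strategy name.
#' @return data frame `draw`, `strategy`, `delta_cost`, `delta_qaly`.
#' @export
ce_plane <- function(psa, baseline = "surveillance_all_LGD") {
  base <- psa[psa$strategy == baseline, c("draw", "cost", "qaly")]
  names(base)[2:3] <- c("cost0", "qaly0")
  m <- merge(psa[psa$strategy != baseline, ], base, by = "draw")
  out <- data.frame(draw = m$draw, strategy = m$strategy,
                    delta_cost = m$cost - m$cost0,
                    delta_qaly = m$qaly - m$qaly0)
  out[order(out$strategy, out$draw), ]
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the fraction of draws in which each
#' strategy has the maximal net monetary benefit. Ties within a draw are
#' split equally between the tied strategies, so fractions sum to 1 at
#' every threshold.
#'
#' @param psa a `psa_result` from [run_psa()].
#' @param wtp_grid willingness-to-pay grid (default 0 to 100,000 in steps
#'   of 1,000).
#' @return data frame `wtp`, `strategy`, `fraction`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 1000)) {
  strat <- unique(psa$strategy)
  draws <- sort(unique(psa$draw))
  cost <- matrix(NA_real_, length(draws), length(strat),
                 dimnames = list(NULL, strat))
  qaly <- cost
  for (s in strat) {
    sub <- psa[psa$strategy == s, ]
    sub <- sub[match(draws, sub$draw), ]
    cost[, s] <- sub$cost
    qaly[, s] <- sub$qaly
  }
  rows <- lapply(wtp_grid, function(l) {
    benefit <- qaly * l - cost
    best <- benefit == apply(benefit, 1, max)
    wins <- best / rowSums(best)  # equal split on ties
    data.frame(wtp = l, strategy = strat, fraction = colMeans(wins))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
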