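#' Convert an annual rate to a per-cycle transition probability
#'
#' Standard constant-hazard conversion `p = 1 - exp(-rate * cycle_length)`.
#'
#' @param annual_rate per-year hazard (>= 0).
#' @param cycle_length cycle length in years.
#' @return transition probability in [0, 1).
#' @export
#' @examples
#' rate_to_probability(0.021807, 0.5)  # 0.010844
rate_to_probability <- function(annual_rate, cycle_length = 0.5) {
  if (any(annual_rate < 0)) {
    stop("rate_to_probability(): rate must be non-negative", call. = FALSE)
  }
  1 - exp(-annual_rate * cycle_length)
}

#' Inverse of [rate_to_probability()]
#' @param p per-cycle probability in [0, 1).
#' @param cycle_length cycle length in years.
#' @return annual rate.
#' @export
probability_to_rate <- function(p, cycle_length = 0.5) {
  if (any(p < 0 | p >= 1)) {
    stop("probability_to_rate(): p must be in [0, 1)", call. = FALSE)
  }
  -log(1 - p) / cycle_length
}

#' Per-cycle discount factor
#'
#' Discrete discounting at an annual rate: `(1 + r)^(-t * cycle_length)` for
#' cycle index `t`.
#'
#' @param cycle_index integer cycle index (0 = first cycle).
#' @param annual_rate annual discount rate (e.g. 0.05).
#' @param cycle_length cycle length in years.
#' @return discount factor(s).
#' @export
discount_factor <- function(cycle_index, annual_rate = 0.05, cycle_length = 0.5) {
  if (annual_rate <= -1) {
    stop("discount_factor(): annual_rate must exceed -1", call. = FALSE)
  }
  (1 + annual_rate)^(-cycle_index * cycle_length)
}

#' Health states of the dysplasia-management model
#'
#' The cohort tracks low-grade dysplasia by its origin (index endoscopy vs
#' developed during surveillance) because ablation policies discriminate on
#' it, non-dysplastic surveillance through interval-tagged tunnel states
#' (6-month confirmation, 12-month, then 2-yearly recall), high-grade
#' dysplasia, early (T1a) and advanced esophageal adenocarcinoma, the
#' post-ablation states, and two absorbing death states.
#'
#' @return data frame with columns `name`, `absorbing`, `accrues_utility`.
#' @export
health_states <- function() {
  nm <- c("LGD_index", "LGD_surv",
          "NDBE_surv6m_index", "NDBE_surv12m_index", "NDBE_surv24m_index",
          "NDBE_surv6m_surv", "NDBE_surv12m_surv", "NDBE_surv24m_surv",
          "HGD", "EAC_T1a", "EAC_advanced", "post_RFA", "post_EMR_RFA",
          "cancer_death", "other_death")
  data.frame(
    name = nm,
    absorbing = nm %in% c("cancer_death", "other_death"),
    accrues_utility = !nm %in% c("cancer_death", "other_death")
  )
}

#' Management strategies compared by the model
#'
#' All four ablate high-grade dysplasia and treat cancer identically; they
#' differ only in whether radiofrequency ablation is offered at the
#' low-grade-dysplasia stage, and to whom.
#'
#' @return character vector of strategy names.
#' @export
strategies <- function() {
  c("surveillance_all_LGD", "RFA_index_LGD", "RFA_surveillance_LGD", "RFA_all_LGD")
}

# LGD states ablated under each strategy
.ablation_targets <- function(strategy) {
  switch(strategy,
    surveillance_all_LGD = character(),
    RFA_index_LGD        = "LGD_index",
    RFA_surveillance_LGD = "LGD_surv",
    RFA_all_LGD          = c("LGD_index", "LGD_surv"),
    stop("unknown strategy: ", strategy, call. = FALSE)
  )
}

#' Construct a model specification
#'
#' Bundles states, cycle grid, discounting, willingness-to-pay, the named
#' parameter list and the starting distribution into a validated
#' `model_spec` object. Most users load the shipped parameter file via
#' [load_model_spec()] / [default_model_spec()] instead of calling this
#' directly.
#'
#' @param params named list of annual rates, per-procedure probabilities,
#'   costs and utilities (see the shipped `model_params.yaml` for the full
#'   schema).
#' @param cycle_length cycle length in years (default 0.5).
#' @param horizon time horizon in years (default 35; must be a multiple of
#'   `cycle_length`).
#' @param discount_rate annual discount rate applied to costs and QALYs.
#' @param wtp willingness-to-pay threshold (currency per QALY).
#' @param start_distribution named probabilities over states; defaults to
#'   the base-case mix of 52% LGD at index and 48% LGD under surveillance.
#' @param placeholders character vector of parameter names whose values are
#'   documented placeholders awaiting published sources.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(params,
                       cycle_length = 0.5,
                       horizon = 35,
                       discount_rate = 0.05,
                       wtp = 50000,
                       start_distribution = c(LGD_index = 0.52, LGD_surv = 0.48),
                       placeholders = character()) {
  states <- health_states()
  if (cycle_length <= 0) stop("model_spec(): cycle_length must be positive", call. = FALSE)
  n_cycles <- horizon / cycle_length
  if (abs(n_cycles - round(n_cycles)) > 1e-9) {
    stop("model_spec(): horizon must be a multiple of cycle_length", call. = FALSE)
  }
  start <- stats::setNames(numeric(nrow(states)), states$name)
  if (!all(names(start_distribution) %in% states$name)) {
    stop("model_spec(): start_distribution names unknown states: ",
         paste(setdiff(names(start_distribution), states$name), collapse = ", "),
         call. = FALSE)
  }
  start[names(start_distribution)] <- start_distribution
  if (abs(sum(start) - 1) > 1e-9 || any(start < 0)) {
    stop("model_spec(): start_distribution must be non-negative and sum to 1",
         call. = FALSE)
  }
  required <- .required_params()
  missing_p <- setdiff(required, names(params))
  if (length(missing_p)) {
    stop("model_spec(): missing parameters: ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  obj <- structure(
    list(states = states, params = params, cycle_length = cycle_length,
         horizon = horizon, n_cycles = as.integer(round(n_cycles)),
         discount_rate = discount_rate, wtp = wtp,
         start_distribution = start, placeholders = placeholders),
    class = "model_spec"
  )
  obj
}

.required_params <- function() {
  c(# annual rates
    "rate_lgd_prog_index", "rate_lgd_prog_surv", "rate_lgd_revert",
    "rate_nd_recur", "rate_nd_prog", "rate_hgd_to_eac", "rate_postrfa_recur",
    "rate_postrfa_prog", "rate_postemr_recur", "rate_postemr_prog",
    "rate_eac_t1a_progress", "rate_eac_t1a_death",
    "rate_eac_adv_death", "rate_mortality_other",
    # per-cycle / per-procedure probabilities
    "p_rfa_success", "p_hgd_rfa", "p_t1a_treat", "p_rfa_complication",
    "frac_prog_to_eac", "frac_eac_t1a",
    # costs
    "cost_endoscopy", "cost_rfa", "cost_rfa_complication", "cost_emr",
    "cost_eac_advanced_care", "cost_eac_advanced_cycle",
    # per-year utilities and per-event disutilities
    "u_ndbe", "u_lgd", "u_hgd", "u_eac_t1a", "u_eac_advanced",
    "u_post_rfa", "u_post_emr_rfa", "du_rfa", "du_emr")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "model_spec: %d states, %g-year cycles over %g years (%d cycles), %g%% discounting, WTP %s/QALY\n",
    nrow(x$states), x$cycle_length, x$horizon, x$n_cycles,
    100 * x$discount_rate, format(x$wtp, big.mark = ",")
  ))
  if (length(x$placeholders)) {
    cat("placeholder parameters:", paste(x$placeholders, collapse = ", "), "\n")
  }
  invisible(x)
}

# Effective per-cycle RFA procedure cost including expected complication cost
.rfa_event_cost <- function(p) {
  p$cost_rfa + p$p_rfa_complication * p$cost_rfa_complication
}

#' Build the per-strategy transition and payoff structure
#'
#' Translates the named parameter list into a row-stochastic transition
#' matrix, per-cycle state costs and utilities, and per-transition event
#' costs/disutilities, with the low-grade-dysplasia rows rewired to
#' radiofrequency ablation where the strategy triggers it. Under an
#' ablation trigger, every patient occupying a triggered LGD state is
#' treated that cycle: the successful fraction moves to the post-ablation
#' state and the remainder stays for retreatment, both arcs carrying the
#' procedure cost and disutility. High-grade dysplasia and cancer handling
#' is identical across strategies.
#'
#' @param spec a [model_spec()].
#' @param strategy one of [strategies()].
#' @param renormalize when `TRUE`, a transition row whose outflows exceed 1
#'   (possible under extreme sampled parameters) is rescaled to sum to 1
#'   instead of erroring; affected rows are recorded in the
#'   `renormalized_rows` attribute of the result for auditing.
#' @return list of class `strategy_model` with elements `strategy`, `states`,
#'   `P` (transition matrix), `state_costs`, `state_utilities` (per year),
#'   `event_cost`, `event_disutility` (matrices over transitions),
#'   `cycle_length`, `n_cycles`, `discount_rate`, `start`.
#' @export
build_strategy_model <- function(spec, strategy = strategies(), renormalize = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(spec, "model_spec"))
  p <- spec$params
  cl <- spec$cycle_length
  st <- spec$states$name
  n <- length(st)
  P <- matrix(0, n, n, dimnames = list(st, st))
  ec <- matrix(0, n, n, dimnames = list(st, st))  # event costs on transitions
  ed <- matrix(0, n, n, dimnames = list(st, st))  # event disutilities

  p_om   <- rate_to_probability(p$rate_mortality_other, cl)
  ablate <- .ablation_targets(strategy)

  # split of a progression flow into HGD / EAC_T1a / EAC_advanced
  prog_split <- function(q) {
    c(HGD = q * (1 - p$frac_prog_to_eac),
      EAC_T1a = q * p$frac_prog_to_eac * p$frac_eac_t1a,
      EAC_advanced = q * p$frac_prog_to_eac * (1 - p$frac_eac_t1a))
  }

  renormalized <- character()
  fill_row <- function(state, flows) {
    total <- sum(flows)
    if (total > 1 + 1e-12) {
      if (!renormalize) {
        stop("transition row for state '", state, "' exceeds 1 (sum = ",
             format(total), ")", call. = FALSE)
      }
      flows <- flows / total
      total <- 1
      renormalized <<- c(renormalized, state)
    }
    P[state, names(flows)] <<- P[state, names(flows)] + flows
    P[state, state] <<- P[state, state] + (1 - total)
  }

  # --- LGD rows (per origin) ---
  for (origin in c("index", "surv")) {
    s <- paste0("LGD_", origin)
    if (s %in% ablate) {
      surv_frac <- 1 - p_om
      flows <- c(other_death = p_om, post_RFA = surv_frac * p$p_rfa_success)
      fill_row(s, flows)
      # procedure payoff on both success and failed-retreat arcs
      ec[s, "post_RFA"] <- .rfa_event_cost(p); ed[s, "post_RFA"] <- p$du_rfa
      ec[s, s] <- .rfa_event_cost(p);          ed[s, s] <- p$du_rfa
    } else {
      q_prog <- rate_to_probability(p[[paste0("rate_lgd_prog_", origin)]], cl)
      q_rev  <- rate_to_probability(p$rate_lgd_revert, cl)
      flows <- c(prog_split(q_prog),
                 stats::setNames(q_rev, paste0("NDBE_surv6m_", origin)),
                 other_death = p_om)
      fill_row(s, flows)
    }
  }

  # --- non-dysplastic tunnel rows ---
  q_rec  <- rate_to_probability(p$rate_nd_recur, cl)
  q_ndpr <- rate_to_probability(p$rate_nd_prog, cl)
  for (origin in c("index", "surv")) {
    lgd <- paste0("LGD_", origin)
    s6  <- paste0("NDBE_surv6m_", origin)
    s12 <- paste0("NDBE_surv12m_", origin)
    s24 <- paste0("NDBE_surv24m_", origin)
    base <- c(prog_split(q_ndpr), other_death = p_om)
    base[lgd] <- q_rec
    adv6 <- base;  adv6[s12] <- 1 - sum(base)   # tunnel advance
    fill_row(s6, adv6)
    adv12 <- base; adv12[s24] <- 1 - sum(base)
    fill_row(s12, adv12)
    fill_row(s24, base)                          # 2-yearly recall, stay
  }

  # --- HGD: detected and ablated under every strategy ---
  q_he <- rate_to_probability(p$rate_hgd_to_eac, cl)
  flows <- c(EAC_T1a = q_he * p$frac_eac_t1a,
             EAC_advanced = q_he * (1 - p$frac_eac_t1a),
             post_RFA = (1 - q_he - p_om) * p$p_hgd_rfa,
             other_death = p_om)
  fill_row("HGD", flows)
  ec["HGD", "post_RFA"] <- .rfa_event_cost(p); ed["HGD", "post_RFA"] <- p$du_rfa

  # --- EAC T1a: endoscopic resection + ablation ---
  q_t1p <- rate_to_probability(p$rate_eac_t1a_progress, cl)
  q_t1d <- rate_to_probability(p$rate_eac_t1a_death, cl)
  flows <- c(EAC_advanced = q_t1p, cancer_death = q_t1d, other_death = p_om,
             post_EMR_RFA = (1 - q_t1p - q_t1d - p_om) * p$p_t1a_treat)
  fill_row("EAC_T1a", flows)
  ec["EAC_T1a", "post_EMR_RFA"] <- p$cost_emr + .rfa_event_cost(p)
  ed["EAC_T1a", "post_EMR_RFA"] <- p$du_emr + p$du_rfa

  # --- advanced EAC: stage-specific care as an entry payoff bundle ---
  q_ad <- rate_to_probability(p$rate_eac_adv_death, cl)
  fill_row("EAC_advanced", c(cancer_death = q_ad, other_death = p_om))
  ec[setdiff(st, "EAC_advanced"), "EAC_advanced"] <-
    ec[setdiff(st, "EAC_advanced"), "EAC_advanced"] + p$cost_eac_advanced_care

  # --- post-ablation states: recurrent metaplasia/dysplasia is retreated
  # under all strategies (expected retreatment payoff on the self-loop);
  # a small residual flow progresses to HGD despite eradication ---
  q_rr <- rate_to_probability(p$rate_postrfa_recur, cl)
  fill_row("post_RFA", c(HGD = rate_to_probability(p$rate_postrfa_prog, cl),
                         other_death = p_om))
  ec["post_RFA", "post_RFA"] <- q_rr * .rfa_event_cost(p)
  ed["post_RFA", "post_RFA"] <- q_rr * p$du_rfa
  q_er <- rate_to_probability(p$rate_postemr_recur, cl)
  fill_row("post_EMR_RFA", c(HGD = rate_to_probability(p$rate_postemr_prog, cl),
                             other_death = p_om))
  ec["post_EMR_RFA", "post_EMR_RFA"] <- q_er * .rfa_event_cost(p)
  ed["post_EMR_RFA", "post_EMR_RFA"] <- q_er * p$du_rfa

  # --- absorbing states ---
  P["cancer_death", "cancer_death"] <- 1
  P["other_death", "other_death"] <- 1
  # no advanced-care bundle on the absorbing self-loops
  ec["cancer_death", ] <- 0; ec["other_death", ] <- 0

  # per-cycle state costs: surveillance endoscopy scaled by recall interval
  sc <- stats::setNames(numeric(n), st)
  sc[c("LGD_index", "LGD_surv")] <- p$cost_endoscopy            # 6-monthly
  sc[paste0("NDBE_surv6m_", c("index", "surv"))]  <- p$cost_endoscopy
  sc[paste0("NDBE_surv12m_", c("index", "surv"))] <- p$cost_endoscopy / 2
  sc[paste0("NDBE_surv24m_", c("index", "surv"))] <- p$cost_endoscopy / 4
  sc["HGD"] <- p$cost_endoscopy
  sc[c("post_RFA", "post_EMR_RFA")] <- p$cost_endoscopy / 2     # annual recall
  sc["EAC_advanced"] <- p$cost_eac_advanced_cycle
  if (length(ablate)) sc[ablate] <- p$cost_endoscopy            # treatment visit

  # per-year utilities
  su <- stats::setNames(numeric(n), st)
  su[c("LGD_index", "LGD_surv")] <- p$u_lgd
  su[grep("^NDBE", st)] <- p$u_ndbe
  su["HGD"] <- p$u_hgd
  su["EAC_T1a"] <- p$u_eac_t1a
  su["EAC_advanced"] <- p$u_eac_advanced
  su["post_RFA"] <- p$u_post_rfa
  su["post_EMR_RFA"] <- p$u_post_emr_rfa

  structure(
    list(strategy = strategy, states = st, P = P,
         state_costs = sc, state_utilities = su,
         event_cost = ec, event_disutility = ed,
         cycle_length = cl, n_cycles = spec$n_cycles,
         discount_rate = spec$discount_rate,
         start = spec$start_distribution),
    class = "strategy_model",
    renormalized_rows = unique(renormalized)
  )
}

#' Propagate a cohort through a transition matrix
#'
#' Low-level engine: `occupancy[t + 1, ] = occupancy[t, ] %*% P`. Validates
#' row-stochasticity and names the offending row otherwise.
#'
#' @param P row-stochastic transition matrix (optionally a function of the
#'   0-based cycle index returning one).
#' @param start starting occupancy vector (sums to 1).
#' @param n_cycles number of cycles to run.
#' @return matrix of size `(n_cycles + 1) x n_states`, class `cohort_trace`.
#' @export
markov_trace <- function(P, start, n_cycles) {
  get_P <- if (is.function(P)) P else function(t) P
  P0 <- get_P(0L)
  n <- nrow(P0)
  check_P <- function(M) {
    bad <- which(abs(rowSums(M) - 1) > 1e-9 | apply(M, 1, min) < -1e-12)
    if (length(bad)) {
      nm <- if (!is.null(rownames(M))) rownames(M)[bad] else bad
      stop("transition matrix is not row-stochastic in row(s): ",
           paste(nm, collapse = ", "), call. = FALSE)
    }
  }
  check_P(P0)
  if (abs(sum(start) - 1) > 1e-9 || any(start < 0)) {
    stop("markov_trace(): start must be a probability vector", call. = FALSE)
  }
  trace <- matrix(0, n_cycles + 1, n,
                  dimnames = list(NULL, colnames(P0)))
  trace[1, ] <- start
  for (t in seq_len(n_cycles)) {
    M <- if (t == 1L) P0 else { Mt <- get_P(t - 1L); check_P(Mt); Mt }
    trace[t + 1, ] <- trace[t, ] %*% M
  }
  class(trace) <- c("cohort_trace", class(trace))
  trace
}

#' Run the cohort model for one strategy
#'
#' @param model a `strategy_model` from [build_strategy_model()], or a
#'   `model_spec` together with `strategy`.
#' @param strategy strategy name, used when `model` is a `model_spec`.
#' @return `cohort_trace` occupancy matrix.
#' @export
run_cohort <- function(model, strategy = NULL) {
  if (inherits(model, "model_spec")) {
    model <- build_strategy_model(model, strategy)
  }
  stopifnot(inherits(model, "strategy_model"))
  markov_trace(model$P, model$start, model$n_cycles)
}

#' Accumulate economic outcomes over a cohort trace
#'
#' Per cycle `t` (0-based), with occupancy `x_t` taken at the start of the
#' cycle and transition flow `F_t = diag(x_t) P`:
#' cost accrues `d_t (x_t . state_costs + sum(F_t * event_cost))` and QALYs
#' accrue `d_t (cycle_length * x_t . state_utilities - sum(F_t *
#' event_disutility))`, with `d_t` the per-cycle discount factor. No
#' half-cycle correction is applied. Cumulative cancer incidence is the
#' total flow into the cancer states from outside them.
#'
#' @param trace a `cohort_trace` from [run_cohort()].
#' @param model the `strategy_model` that produced it.
#' @return list of class `econ_outcome`: `discounted_cost`,
#'   `discounted_qaly`, `undiscounted_cost`, `undiscounted_qaly`,
#'   `cumulative_eac_incidence`.
#' @export
accumulate_outcomes <- function(trace, model) {
  stopifnot(inherits(model, "strategy_model"))
  n_cycles <- nrow(trace) - 1L
  st <- model$states
  if (ncol(trace) != length(st)) {
    stop("accumulate_outcomes(): trace/model dimension mismatch", call. = FALSE)
  }
  eac_states <- intersect(c("EAC_T1a", "EAC_advanced"), st)
  non_eac <- setdiff(st, eac_states)
  disc <- discount_factor(0:(n_cycles - 1), model$discount_rate, model$cycle_length)
  dc <- uc <- dq <- uq <- eac_in <- 0
  for (t in seq_len(n_cycles)) {
    x <- trace[t, ]
    flow <- x * model$P  # diag(x) %*% P, row-scaled
    c_t <- sum(x * model$state_costs) + sum(flow * model$event_cost)
    q_t <- model$cycle_length * sum(x * model$state_utilities) -
      sum(flow * model$event_disutility)
    dc <- dc + disc[t] * c_t; uc <- uc + c_t
    dq <- dq + disc[t] * q_t; uq <- uq + q_t
    if (length(eac_states)) {
      eac_in <- eac_in + sum(flow[non_eac, eac_states, drop = FALSE])
    }
  }
  structure(
    list(discounted_cost = dc, discounted_qaly = dq,
         undiscounted_cost = uc, undiscounted_qaly = uq,
         cumulative_eac_incidence = eac_in),
    class = "econ_outcome"
  )
}

#' @export
print.econ_outcome <- function(x, ...) {
  cat(sprintf(
    "cost %s (undisc. %s), QALY %.3f (undisc. %.3f), cumulative EAC incidence %.1f%%\n",
    format(round(x$discounted_cost), big.mark = ","),
    format(round(x$undiscounted_cost), big.mark = ","),
    x$discounted_qaly, x$undiscounted_qaly,
    100 * x$cumulative_eac_incidence
  ))
  invisible(x)
}

#' Run one strategy end-to-end
#'
#' @param spec a [model_spec()].
#' @param strategy one of [strategies()].
#' @return list with `strategy`, `trace` and `outcome`.
#' @export
run_strategy <- function(spec, strategy) {
  model <- build_strategy_model(spec, strategy)
  trace <- run_cohort(model)
  list(strategy = strategy, trace = trace,
       outcome = accumulate_outcomes(trace, model))
}

#' Run and tabulate all four strategies
#'
#' @param spec a [model_spec()].
#' @param discounted report discounted (default) or undiscounted streams.
#' @return data frame with columns `strategy`, `cost`, `qaly`,
#'   `eac_incidence` (plus undiscounted columns), one row per strategy.
#' @export
run_all_strategies <- function(spec, discounted = TRUE) {
  rows <- lapply(strategies(), function(s) {
    o <- run_strategy(spec, s)$outcome
    data.frame(strategy = s,
               cost = if (discounted) o$discounted_cost else o$undiscounted_cost,
               qaly = if (discounted) o$discounted_qaly else o$undiscounted_qaly,
               cost_undiscounted = o$undiscounted_cost,
               qaly_undiscounted = o$undiscounted_qaly,
               eac_incidence = o$cumulative_eac_incidence)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Individual-level microsimulation of a transition matrix
#'
#' First-order Monte-Carlo counterpart of [markov_trace()], used as an
#' independent cross-check of the cohort engine: each simulated individual
#' walks the chain by sampling a successor state each cycle.
#'
#' @param P row-stochastic transition matrix.
#' @param start starting occupancy vector.
#' @param n_cycles number of cycles.
#' @param n_individuals number of simulated individuals.
#' @param seed RNG seed.
#' @return occupancy-fraction matrix of size `(n_cycles + 1) x n_states`.
#' @export
microsimulate <- function(P, start, n_cycles, n_individuals = 1e5, seed = 1L) {
  set.seed(seed)
  n <- nrow(P)
  state <- sample.int(n, n_individuals, replace = TRUE, prob = start)
  occ <- matrix(0, n_cycles + 1, n, dimnames = list(NULL, colnames(P)))
  occ[1, ] <- tabulate(state, n) / n_individuals
  for (t in seq_len(n_cycles)) {
    prev <- state  # snapshot: every individual moves exactly once per cycle
    for (s in seq_len(n)) {
      idx <- which(prev == s)
      if (length(idx)) {
        state[idx] <- sample.int(n, length(idx), replace = TRUE, prob = P[s, ])
      }
    }
    occ[t + 1, ] <- tabulate(state, n) / n_individuals
  }
  occ
}
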