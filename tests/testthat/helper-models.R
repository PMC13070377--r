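# Toy models used across test files.

# alive/dead chain: constant per-cycle death probability
two_state_P <- function(p_die = 0.1) {
  matrix(c(1 - p_die, p_die, 0, 1), 2, 2, byrow = TRUE,
         dimnames = list(c("alive", "dead"), c("alive", "dead")))
}

# well -> sick -> dead with recovery; generic 4-state chain for oracle checks
four_state_P <- function() {
  st <- c("well", "sick", "very_sick", "dead")
  P <- matrix(0, 4, 4, dimnames = list(st, st))
  P["well", ]      <- c(0.85, 0.10, 0.02, 0.03)
  P["sick", ]      <- c(0.15, 0.60, 0.20, 0.05)
  P["very_sick", ] <- c(0.00, 0.10, 0.70, 0.20)
  P["dead", ]      <- c(0, 0, 0, 1)
  P
}

# hand-built strategy_model around an arbitrary transition matrix
toy_model <- function(P, utilities, costs = rep(0, nrow(P)),
                      n_cycles = 20L, cycle_length = 0.5,
                      discount_rate = 0, start = NULL,
                      event_cost = NULL, event_disutility = NULL) {
  n <- nrow(P)
  if (is.null(start)) start <- c(1, rep(0, n - 1))
  structure(
    list(strategy = "toy", states = rownames(P), P = P,
         state_costs = costs, state_utilities = utilities,
         event_cost = if (is.null(event_cost)) matrix(0, n, n) else event_cost,
         event_disutility = if (is.null(event_disutility)) matrix(0, n, n)
                            else event_disutility,
         cycle_length = cycle_length, n_cycles = n_cycles,
         discount_rate = discount_rate,
         start = stats::setNames(start, rownames(P))),
    class = "strategy_model")
}

# a small strategy set with a hand-checkable frontier
toy_results <- function() {
  data.frame(
    strategy = c("A", "B", "C", "D"),
    cost = c(1000, 2000, 4000, 3500),
    qaly = c(10, 10.5, 11, 10.4)
  )
}

# compact spec for sensitivity tests: the shipped model on a short horizon
short_spec <- function(horizon = 10) {
  spec <- default_model_spec()
  spec$horizon <- horizon
  spec$n_cycles <- as.integer(horizon / spec$cycle_length)
  spec
}
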