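#' Calibration targets for the LGD progression model
#'
#' Observed quantities the transition probabilities must reproduce: the two
#' per-group progression rates (per 100 person-years, LGD at entry and LGD
#' during surveillance) and the three LGD-course proportions (reverted to
#' non-dysplastic, back-and-forth, persistent) of the 187-patient LGD
#' cohort followed for 1341 person-years.
#'
#' @return data frame with columns `name`, `observed`, `scale`
#'   (`per_100py` or `proportion`), `weight`; attributes `n_patients`,
#'   `person_years` and `n_cycles` describe the simulated cohort.
#' @export
default_targets <- function() {
  out <- data.frame(
    name = c("rate_entry", "rate_surv", "reverted", "back_and_forth", "persistent"),
    observed = c(1.0, 2.2, 0.690, 0.198, 0.112),
    scale = c("per_100py", "per_100py", "proportion", "proportion", "proportion"),
    weight = 1
  )
  attr(out, "n_patients") <- 187L
  attr(out, "person_years") <- 1341
  # mean follow-up of the LGD cohort, on the 6-month cycle grid
  attr(out, "n_cycles") <- as.integer(round(2 * 1341 / 187))
  out
}

# History-tracking LGD chain: LGD never reverted (L0), reverted and never
# recurred (N1), LGD after recurrence (BL), non-dysplastic after recurrence
# (BN), progressed (absorbing), dead (absorbing). Course categories are read
# off the occupancy directly; a memoryless chain without these copies could
# not distinguish "reverted" from "back-and-forth".
.lgd_chain <- function(p_prog, p_revert, p_recur, p_nd_prog, p_mort) {
  st <- c("L0", "N1", "BL", "BN", "PROG", "DEAD")
  P <- matrix(0, 6, 6, dimnames = list(st, st))
  P["L0", c("PROG", "N1", "DEAD")] <- c(p_prog, p_revert, p_mort)
  P["N1", c("BL", "PROG", "DEAD")] <- c(p_recur, p_nd_prog, p_mort)
  P["BL", c("PROG", "BN", "DEAD")] <- c(p_prog, p_revert, p_mort)
  P["BN", c("BL", "PROG", "DEAD")] <- c(p_recur, p_nd_prog, p_mort)
  diag(P) <- diag(P) + 1 - rowSums(P)
  P["PROG", "PROG"] <- 1
  P["DEAD", "DEAD"] <- 1
  P
}

#' Model outputs matched against the calibration targets
#'
#' Runs a Markov cohort from an all-LGD start through the history-tracking
#' LGD chain for the observed mean follow-up, separately per LGD-origin
#' group, and converts the results onto the target scales: cumulative
#' progression flow divided by model person-time (per 100 person-years) per
#' group, and pooled course-category fractions among surviving
#' non-progressed patients at the end of follow-up.
#'
#' @param params named per-cycle probabilities: `p_prog_index`,
#'   `p_prog_surv`, `p_revert`, `p_recur`.
#' @param n_cycles follow-up duration in cycles (default from
#'   [default_targets()]).
#' @param cycle_length cycle length in years.
#' @param p_nd_prog per-cycle progression probability after reversion
#'   (default: the non-dysplastic cohort hazard on the 6-month grid).
#' @param p_mort per-cycle other-cause mortality.
#' @param group_weights weights for pooling course fractions across the two
#'   LGD-origin groups (default the observed 97/90 split).
#' @return named numeric vector: `rate_entry`, `rate_surv`, `reverted`,
#'   `back_and_forth`, `persistent`.
#' @export
model_outputs_for_calibration <- function(params,
                                          n_cycles = attr(default_targets(), "n_cycles"),
                                          cycle_length = 0.5,
                                          p_nd_prog = rate_to_probability(0.006457, 0.5),
                                          p_mort = rate_to_probability(0.011, 0.5),
                                          group_weights = c(97, 90)) {
  req <- c("p_prog_index", "p_prog_surv", "p_revert", "p_recur")
  if (!all(req %in% names(params))) {
    stop("model_outputs_for_calibration(): params must contain ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(unlist(params[req]) < 0 | unlist(params[req]) > 1)) {
    stop("model_outputs_for_calibration(): probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  start <- c(L0 = 1, N1 = 0, BL = 0, BN = 0, PROG = 0, DEAD = 0)
  alive <- c("L0", "N1", "BL", "BN")
  run_group <- function(p_prog) {
    P <- .lgd_chain(p_prog, params$p_revert, params$p_recur, p_nd_prog, p_mort)
    tr <- markov_trace(P, start, n_cycles)
    events <- unname(tr[n_cycles + 1, "PROG"])
    py <- cycle_length * sum(tr[seq_len(n_cycles), alive])
    end <- tr[n_cycles + 1, ]
    list(rate = 100 * events / py,
         course = c(reverted = unname(end["N1"]),
                    back_and_forth = unname(end["BL"] + end["BN"]),
                    persistent = unname(end["L0"])))
  }
  g1 <- run_group(params$p_prog_index)
  g2 <- run_group(params$p_prog_surv)
  w <- group_weights / sum(group_weights)
  course <- w[1] * g1$course + w[2] * g2$course
  course <- course / sum(course)
  c(rate_entry = g1$rate, rate_surv = g2$rate, course)
}

#' Default seven-stage calibration plan
#'
#' Stages are ordered from best- to least-identified: each progression
#' probability alone against its own rate target, then the reversion and
#' recurrence probabilities against the course proportions, then joint
#' refinements, ending with a joint polish of all parameters against all
#' targets. Each stage is a list with `params` (names freed) and `targets`
#' (names matched).
#'
#' @return list of seven stages.
#' @export
default_stage_plan <- function() {
  list(
    list(params = "p_prog_index", targets = "rate_entry"),
    list(params = "p_prog_surv",  targets = "rate_surv"),
    list(params = "p_revert",     targets = "reverted"),
    list(params = "p_recur",      targets = "back_and_forth"),
    list(params = c("p_prog_index", "p_prog_surv"),
         targets = c("rate_entry", "rate_surv")),
    list(params = c("p_revert", "p_recur"),
         targets = c("reverted", "back_and_forth", "persistent")),
    list(params = c("p_prog_index", "p_prog_surv", "p_revert", "p_recur"),
         targets = c("rate_entry", "rate_surv", "reverted", "back_and_forth",
                     "persistent"))
  )
}

# weighted squared relative deviation between model outputs and targets;
# infeasible parameter probes (e.g. row sums exceeding 1) score Inf
.calib_objective <- function(outputs, targets, which_targets = targets$name) {
  if (is.null(outputs) || anyNA(outputs)) return(Inf)
  sub <- targets[targets$name %in% which_targets, , drop = FALSE]
  dev <- (outputs[sub$name] - sub$observed) / sub$observed
  sum(sub$weight * dev^2)
}

.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(x) 1 / (1 + exp(-x))

#' Staged calibration of transition probabilities
#'
#' Per stage, minimizes the weighted squared relative deviation between the
#' model outputs and that stage's targets over the freed parameters
#' (bounded to (0, 1) via a logit transform; single-parameter stages use
#' golden-section search), holding the others fixed; the stage cycle is
#' iterated until the overall objective improves by less than `tolerance`.
#' The objective is non-increasing across stages by construction (each
#' stage keeps its incumbent if no improvement is found).
#'
#' @param targets data frame as returned by [default_targets()].
#' @param initial_params named list of starting per-cycle probabilities.
#' @param stage_plan list of stages (see [default_stage_plan()]).
#' @param tolerance stop when an outer iteration improves the overall
#'   objective by less than this (default 1e-8).
#' @param conv_tol `converged` additionally requires the final objective
#'   (weighted squared relative deviation) below this, so that a run
#'   stalled against a feasibility boundary by an unattainable target is
#'   reported as not converged rather than silently accepted.
#' @param max_iter maximum outer iterations over the stage cycle.
#' @param seed RNG seed (the default forward model is deterministic; the
#'   seed is set for reproducibility of any stochastic `output_fn`).
#' @param output_fn function mapping a named parameter list to named model
#'   outputs; defaults to [model_outputs_for_calibration()] on the cycle
#'   count implied by `targets`.
#' @return list of class `calibration_result`: `fitted_params`,
#'   `objective_value`, `stage_log` (data frame), `converged`, `iterations`,
#'   `model_outputs`.
#' @export
calibrate <- function(targets = default_targets(),
                      initial_params = list(p_prog_index = 0.005,
                                            p_prog_surv = 0.01,
                                            p_revert = 0.2,
                                            p_recur = 0.05),
                      stage_plan = default_stage_plan(),
                      tolerance = 1e-8,
                      conv_tol = 1e-6,
                      max_iter = 50L,
                      seed = 1L,
                      output_fn = NULL) {
  set.seed(seed)
  if (is.null(output_fn)) {
    n_cycles <- attr(targets, "n_cycles")
    if (is.null(n_cycles)) n_cycles <- attr(default_targets(), "n_cycles")
    output_fn <- function(par) model_outputs_for_calibration(par, n_cycles = n_cycles)
  }
  par <- initial_params
  eps <- 1e-9
  safe_output <- function(p) tryCatch(output_fn(p), error = function(e) NULL)
  obj_all <- function(p) .calib_objective(safe_output(p), targets)
  current <- obj_all(par)
  stage_log <- list()
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    obj_before_iter <- current
    for (si in seq_along(stage_plan)) {
      stage <- stage_plan[[si]]
      free <- stage$params
      stage_obj <- function(vals) {
        trial <- par
        trial[free] <- as.list(pmin(pmax(vals, eps), 1 - eps))
        v <- .calib_objective(safe_output(trial), targets, stage$targets)
        if (!is.finite(v)) 1e12 else v  # finite penalty keeps optimizers stable
      }
      before <- stage_obj(unlist(par[free]))
      if (length(free) == 1L) {
        # the feasible region can be a narrow sliver of (0, 1) (row sums must
        # stay below 1), so bracket by a coarse logit-space scan before the
        # local search
        grid <- .inv_logit(seq(-14, 6, length.out = 81))
        vals <- vapply(grid, stage_obj, numeric(1))
        i <- which.min(vals)
        lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
        opt <- stats::optimize(function(v) stage_obj(v), c(lo, hi), tol = 1e-12)
        cand <- opt$minimum; cand_val <- opt$objective
      } else {
        opt <- stats::optim(.logit(unlist(par[free])),
                            function(z) stage_obj(.inv_logit(z)),
                            method = "Nelder-Mead",
                            control = list(maxit = 500, reltol = 1e-12))
        cand <- .inv_logit(opt$par); cand_val <- opt$value
      }
      if (cand_val < before) {  # keep the incumbent otherwise
        par[free] <- as.list(pmin(pmax(cand, eps), 1 - eps))
      }
      after <- min(cand_val, before)
      stage_log[[length(stage_log) + 1L]] <- data.frame(
        iteration = iter, stage = si,
        params_freed = paste(free, collapse = "+"),
        objective_before = before, objective_after = after)
    }
    current <- obj_all(par)
    if (obj_before_iter - current < tolerance) {
      converged <- TRUE
      break
    }
  }
  fitted <- unlist(par)
  # a parameter is saturated when it sits at the box bound or when a small
  # upward step leaves the feasible region (row sums would exceed 1)
  at_bound <- any(fitted <= eps * 10 | fitted >= 1 - eps * 10) ||
    any(vapply(names(par), function(nm) {
      probe <- par
      probe[[nm]] <- min(1 - eps, probe[[nm]] * 1.05)
      is.null(safe_output(probe))
    }, logical(1)))
  structure(
    list(fitted_params = par,
         objective_value = current,
         stage_log = do.call(rbind, stage_log),
         converged = converged && current < conv_tol,
         boundary_saturated = at_bound,
         iterations = iter,
         model_outputs = safe_output(par)),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration: objective %.3e after %d iteration(s), %s\n",
              x$objective_value, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  print(unlist(x$fitted_params))
  invisible(x)
}

#' Write calibrated probabilities into a model specification
#'
#' Converts the fitted per-cycle probabilities back to annual rates on the
#' spec's cycle grid and stores them in the corresponding parameter slots.
#'
#' @param spec a [model_spec()].
#' @param fit a `calibration_result` (or named probability list).
#' @return the updated `model_spec`.
#' @export
set_calibrated_params <- function(spec, fit) {
  stopifnot(inherits(spec, "model_spec"))
  par <- if (inherits(fit, "calibration_result")) fit$fitted_params else fit
  cl <- spec$cycle_length
  spec$params$rate_lgd_prog_index <- probability_to_rate(par$p_prog_index, cl)
  spec$params$rate_lgd_prog_surv  <- probability_to_rate(par$p_prog_surv, cl)
  spec$params$rate_lgd_revert     <- probability_to_rate(par$p_revert, cl)
  spec$params$rate_nd_recur       <- probability_to_rate(par$p_recur, cl)
  spec
}
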