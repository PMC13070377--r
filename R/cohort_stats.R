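#' Round half-up
#'
#' Rounds to `digits` decimals with ties going away from zero, matching the
#' reporting convention used for published surveillance tables (base R's
#' `round()` uses banker's rounding, which turns 15.55 into 15.5).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(0.25, 1)  # 0.3, not 0.2
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Crude progression proportion
#'
#' Percentage of patients who progressed, reported to one decimal as in
#' surveillance summary tables.
#'
#' @param events number of progression events (HGD/EAC).
#' @param n number of patients at risk.
#' @return percentage, rounded half-up to one decimal.
#' @export
#' @examples
#' crude_proportion(46, 914)  # 5.0
crude_proportion <- function(events, n) {
  if (length(n) != 1L || is.na(n) || n <= 0) {
    stop("crude_proportion(): 'n' must be a single positive count", call. = FALSE)
  }
  if (any(is.na(events)) || any(events < 0) || any(events > n)) {
    stop("crude_proportion(): 'events' must lie in [0, n]", call. = FALSE)
  }
  round_half_up(100 * events / n, 1)
}

#' Person-time incidence rate with exact Poisson confidence interval
#'
#' Point estimate is `100 * events / person_years`. The confidence interval
#' uses the exact (Garwood) Poisson bounds built from chi-square quantiles:
#' lower = qchisq(alpha/2, 2k)/2, upper = qchisq(1 - alpha/2, 2k + 2)/2, each
#' scaled by 100/person-years; the lower bound is 0 when there are no events.
#' These bounds reproduce published per-100-person-year intervals exactly,
#' where the log-normal approximation does not.
#'
#' @param events event count (k >= 0).
#' @param person_years person-time denominator (> 0).
#' @param alpha two-sided significance level (default 0.05).
#' @return object of class `rate_estimate`: list with `rate_per_100py`,
#'   `ci_low`, `ci_high`, `alpha`, `events`, `person_years`.
#' @export
#' @examples
#' person_time_rate(14, 642)  # 2.18 (1.19-3.66) per 100 person-years
person_time_rate <- function(events, person_years, alpha = 0.05) {
  if (length(person_years) != 1L || is.na(person_years) || person_years <= 0) {
    stop("person_time_rate(): 'person_years' must be positive", call. = FALSE)
  }
  if (length(events) != 1L || is.na(events) || events < 0) {
    stop("person_time_rate(): 'events' must be a non-negative count", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) {
    stop("person_time_rate(): 'alpha' must be in (0, 1)", call. = FALSE)
  }
  k <- events
  lower <- if (k == 0) 0 else stats::qchisq(alpha / 2, 2 * k) / 2
  upper <- stats::qchisq(1 - alpha / 2, 2 * k + 2) / 2
  structure(
    list(
      rate_per_100py = 100 * k / person_years,
      ci_low         = 100 * lower / person_years,
      ci_high        = 100 * upper / person_years,
      alpha          = alpha,
      events         = k,
      person_years   = person_years
    ),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "%.1f per 100 person-years (%d%% CI %.1f-%.1f; %d events / %.0f py)\n",
    round_half_up(x$rate_per_100py, 1), round((1 - x$alpha) * 100),
    round_half_up(x$ci_low, 1), round_half_up(x$ci_high, 1),
    x$events, x$person_years
  ))
  invisible(x)
}

#' Incidence rate ratio with exact conditional confidence interval
#'
#' Ratio of two person-time incidence rates. Conditional on the total event
#' count, the events in the comparison group are binomial; an exact
#' Clopper-Pearson interval for that binomial proportion is transformed to
#' the rate-ratio scale via IRR = p/(1-p) * PY0/PY1. With zero events in the
#' reference group the upper bound is infinite (flagged, not an error).
#'
#' @param events1,py1 events and person-years in the comparison group.
#' @param events0,py0 events and person-years in the reference group.
#' @param alpha two-sided significance level (default 0.05).
#' @return object of class `irr_estimate`: list with `irr`, `ci_low`,
#'   `ci_high`, `alpha`, and the input counts.
#' @export
#' @examples
#' incidence_rate_ratio(14, 642, 25, 3872)  # IRR 3.4 (1.6-6.8)
incidence_rate_ratio <- function(events1, py1, events0, py0, alpha = 0.05) {
  if (py1 <= 0 || py0 <= 0) {
    stop("incidence_rate_ratio(): person-years must be positive in both groups",
         call. = FALSE)
  }
  if (events1 < 0 || events0 < 0) {
    stop("incidence_rate_ratio(): event counts must be non-negative", call. = FALSE)
  }
  k1 <- events1; k0 <- events0
  n <- k1 + k0
  irr <- if (k0 == 0) {
    if (k1 == 0) NaN else Inf
  } else {
    (k1 / py1) / (k0 / py0)
  }
  # Clopper-Pearson bounds for p = k1 / n, then odds transform
  p_low  <- if (k1 == 0) 0 else stats::qbeta(alpha / 2, k1, n - k1 + 1)
  p_high <- if (k1 == n) 1 else stats::qbeta(1 - alpha / 2, k1 + 1, n - k1)
  scale <- py0 / py1
  structure(
    list(
      irr     = irr,
      ci_low  = p_low / (1 - p_low) * scale,
      ci_high = if (p_high >= 1) Inf else p_high / (1 - p_high) * scale,
      alpha   = alpha,
      events1 = k1, py1 = py1, events0 = k0, py0 = py0,
      reference_zero_events = (k0 == 0)
    ),
    class = "irr_estimate"
  )
}

#' @export
print.irr_estimate <- function(x, ...) {
  cat(sprintf(
    "IRR %.1f (%d%% CI %.1f-%s)\n",
    round_half_up(x$irr, 1), round((1 - x$alpha) * 100),
    round_half_up(x$ci_low, 1),
    if (is.finite(x$ci_high)) sprintf("%.1f", round_half_up(x$ci_high, 1)) else "Inf"
  ))
  invisible(x)
}

#' Group labels used throughout the package
#'
#' `ND` (non-dysplastic throughout), `LGD_entry` (low-grade dysplasia at the
#' index endoscopy) and `LGD_surv` (low-grade dysplasia developing during
#' surveillance).
#'
#' @return character vector of the three canonical labels.
#' @export
cohort_groups <- function() c("ND", "LGD_entry", "LGD_surv")

#' Summarise a patient-level surveillance cohort
#'
#' Sums patients, progression events and person-years per group and overall.
#'
#' @param table data frame with columns `patient_id`, `group`,
#'   `person_years`, `event` (0/1) and optionally `event_type`.
#' @return data frame with one row per group plus a pooled `All` row, columns
#'   `group`, `n`, `events`, `person_years`.
#' @export
cohort_summary <- function(table) {
  required <- c("group", "person_years", "event")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stop("cohort_summary(): missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(table) == 0) {
    return(data.frame(group = character(), n = integer(),
                      events = integer(), person_years = numeric()))
  }
  bad <- which(!table$group %in% cohort_groups())
  if (length(bad)) {
    stop("cohort_summary(): unknown group label in rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  if (any(table$person_years <= 0)) {
    stop("cohort_summary(): person_years must be positive for every record",
         call. = FALSE)
  }
  groups <- intersect(cohort_groups(), unique(table$group))
  per_group <- do.call(rbind, lapply(groups, function(g) {
    sub <- table[table$group == g, , drop = FALSE]
    data.frame(group = g, n = nrow(sub), events = sum(sub$event),
               person_years = sum(sub$person_years))
  }))
  pooled <- data.frame(group = "All", n = nrow(table),
                       events = sum(table$event),
                       person_years = sum(table$person_years))
  out <- rbind(per_group, pooled)
  rownames(out) <- NULL
  out
}

#' Progression-rate table for a surveillance cohort
#'
#' Per-group person-time incidence rates with exact Poisson intervals and
#' incidence rate ratios against a reference group, in one table mirroring
#' the standard surveillance-report layout.
#'
#' @param table patient-level cohort data frame (see [cohort_summary()]), or
#'   a pre-aggregated data frame of group counts with columns `group`, `n`,
#'   `events`, `person_years`.
#' @param alpha two-sided significance level.
#' @param reference group label used as the IRR denominator (default `"ND"`).
#' @return data frame with columns `group`, `n`, `events`, `person_years`,
#'   `rate_per_100py`, `ci_low`, `ci_high`, `irr`, `irr_low`, `irr_high`
#'   (IRR columns are `NA` for the pooled row and 1 for the reference).
#' @export
#' @examples
#' progression_rates(fixture_table4())
progression_rates <- function(table, alpha = 0.05, reference = "ND") {
  counts <- if (all(c("n", "events", "person_years") %in% names(table)) &&
                !"patient_id" %in% names(table)) {
    table
  } else {
    cohort_summary(table)
  }
  if (!reference %in% counts$group) {
    stop("progression_rates(): reference group '", reference,
         "' not present in the table", call. = FALSE)
  }
  ref <- counts[counts$group == reference, ]
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    ci <- person_time_rate(counts$events[i], counts$person_years[i], alpha)
    row <- data.frame(
      group = counts$group[i], n = counts$n[i], events = counts$events[i],
      person_years = counts$person_years[i],
      rate_per_100py = ci$rate_per_100py,
      ci_low = ci$ci_low, ci_high = ci$ci_high,
      irr = NA_real_, irr_low = NA_real_, irr_high = NA_real_
    )
    if (counts$group[i] != "All") {
      rr <- incidence_rate_ratio(counts$events[i], counts$person_years[i],
                                 ref$events, ref$person_years, alpha)
      row$irr <- rr$irr; row$irr_low <- rr$ci_low; row$irr_high <- rr$ci_high
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a cohort CSV
#'
#' Expects header `patient_id,group,person_years,event,event_type` with
#' `event` in \{0, 1\} and `event_type` in \{HGD, EAC, NA\}.
#'
#' @param path file path.
#' @return validated data frame.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "group", "person_years", "event")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("read_cohort(): missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(tab$event %in% c(0L, 1L))) {
    stop("read_cohort(): 'event' must be 0 or 1", call. = FALSE)
  }
  if ("event_type" %in% names(tab)) {
    mism <- xor(tab$event == 1L, tab$event_type %in% c("HGD", "EAC"))
    if (any(mism, na.rm = TRUE)) {
      stop("read_cohort(): event_type must be HGD/EAC exactly when event = 1",
           call. = FALSE)
    }
  }
  tab
}
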