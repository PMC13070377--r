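#' Incremental cost-effectiveness ratio with dominance handling
#'
#' @param delta_cost incremental cost versus the comparator.
#' @param delta_qaly incremental QALYs versus the comparator.
#' @return the ratio `delta_cost / delta_qaly` when `delta_qaly > 0` and
#'   `delta_cost > 0`; the character label `"dominated"` (more costly, no
#'   QALY gain), `"dominant"` (QALY gain at no extra cost, i.e.
#'   cost-saving), or `"equivalent"` (both deltas zero). A cheaper but less
#'   effective option returns its (positive) south-west ratio.
#' @export
#' @examples
#' icer(15207, -0.208)  # "dominated"
#' icer(6626, 0.248)    # 26717.74
icer <- function(delta_cost, delta_qaly) {
  if (delta_cost == 0 && delta_qaly == 0) return("equivalent")
  if (delta_qaly > 0 && delta_cost <= 0) return("dominant")
  if (delta_qaly <= 0 && delta_cost > 0) return("dominated")
  if (delta_qaly == 0) return("dominant")  # cheaper, equally effective
  delta_cost / delta_qaly
}

#' Net monetary benefit
#'
#' `qaly * wtp - cost` at willingness-to-pay `wtp`.
#'
#' @param cost total cost.
#' @param qaly total QALYs.
#' @param wtp willingness-to-pay threshold (currency per QALY).
#' @return net monetary benefit.
#' @export
#' @examples
#' nmb(46884, 24.048, 50000)  # 1155516
nmb <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) stop("nmb(): wtp must be non-negative", call. = FALSE)
  qaly * wtp - cost
}

#' Compare strategies against a baseline
#'
#' Pairwise incremental costs, QALYs, ICERs and net monetary benefit of
#' every strategy against one baseline, the presentation used in published
#' strategy tables.
#'
#' @param results data frame with columns `strategy`, `cost`, `qaly` (e.g.
#'   from [run_all_strategies()]).
#' @param wtp willingness-to-pay threshold.
#' @param baseline strategy name used as comparator (default the
#'   surveillance-only strategy).
#' @return data frame with columns `strategy`, `cost`, `qaly`, `delta_cost`,
#'   `delta_qaly`, `icer` (character: a number or dominance label), `nmb`,
#'   `cost_effective` (NMB-optimal flag at `wtp`).
#' @export
compare_to_baseline <- function(results, wtp = 50000,
                                baseline = "surveillance_all_LGD") {
  if (anyDuplicated(results$strategy)) {
    stop("compare_to_baseline(): duplicate strategy names", call. = FALSE)
  }
  if (!baseline %in% results$strategy) {
    stop("compare_to_baseline(): baseline '", baseline, "' not in results",
         call. = FALSE)
  }
  base <- results[results$strategy == baseline, ]
  out <- results[, c("strategy", "cost", "qaly")]
  out$delta_cost <- out$cost - base$cost
  out$delta_qaly <- out$qaly - base$qaly
  out$icer <- vapply(seq_len(nrow(out)), function(i) {
    if (out$strategy[i] == baseline) return("reference")
    v <- icer(out$delta_cost[i], out$delta_qaly[i])
    if (is.numeric(v)) format(v, digits = 10) else v
  }, character(1))
  out$nmb <- nmb(out$cost, out$qaly, wtp)
  out$cost_effective <- out$nmb == max(out$nmb)
  out
}

#' Efficiency frontier with dominance pruning
#'
#' Sorts strategies by cost, removes strictly dominated strategies (more
#' costly and no more effective than another) and extendedly dominated ones
#' (whose sequential ICER exceeds that of the next frontier step), computes
#' sequential ICERs along the frontier, and flags the cost-effective choice
#' at the willingness-to-pay threshold.
#'
#' @param results data frame with `strategy`, `cost`, `qaly`.
#' @param wtp willingness-to-pay threshold.
#' @return data frame with one row per strategy: `strategy`, `cost`, `qaly`,
#'   `status` (`reference`, numeric-ICER rows as `frontier`, `dominated` or
#'   `extendedly_dominated`), `icer` (sequential, `NA` off-frontier),
#'   `nmb`, `cost_effective`.
#' @export
efficiency_frontier <- function(results, wtp = 50000) {
  if (nrow(results) < 2) {
    stop("efficiency_frontier(): need at least two strategies", call. = FALSE)
  }
  if (anyDuplicated(results$strategy)) {
    stop("efficiency_frontier(): duplicate strategy names", call. = FALSE)
  }
  res <- results[order(results$cost, results$qaly), ]
  res$status <- NA_character_
  res$icer <- NA_real_
  # strict dominance: any other strategy no more costly and at least as
  # effective (and better on one margin)
  for (i in seq_len(nrow(res))) {
    dominated <- any(
      (res$cost <= res$cost[i] & res$qaly > res$qaly[i]) |
      (res$cost < res$cost[i] & res$qaly >= res$qaly[i])
    )
    if (dominated) res$status[i] <- "dominated"
  }
  # extended dominance on the survivors: prune until sequential ICERs increase
  repeat {
    idx <- which(is.na(res$status))
    if (length(idx) < 3) break
    ic <- diff(res$cost[idx]) / diff(res$qaly[idx])
    bad <- which(diff(ic) < 0)  # ICER to reach i+1 exceeds ICER of next step
    if (!length(bad)) break
    res$status[idx[bad[1] + 1L]] <- "extendedly_dominated"
  }
  idx <- which(is.na(res$status))
  res$status[idx[1]] <- "reference"
  if (length(idx) > 1) {
    res$status[idx[-1]] <- "frontier"
    res$icer[idx[-1]] <- diff(res$cost[idx]) / diff(res$qaly[idx])
  }
  res$nmb <- nmb(res$cost, res$qaly, wtp)
  res$cost_effective <- res$nmb == max(res$nmb)
  rownames(res) <- NULL
  res
}
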