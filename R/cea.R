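# Strategy comparison: ICERs, dominance, frontier, net monetary benefit.

DAYS_PER_YEAR <- 365.25
ICER_EFFECT_TOL <- 1e-9  # |dQALY| below this is treated as equal effect

#' Incremental comparison of two strategy results
#'
#' Deltas are comparator minus reference. The ICER is numeric when the
#' effect difference is meaningful; otherwise the comparison is flagged
#' `dominant` (comparator no dearer and no less effective, not both equal),
#' `dominated` (the reverse) or `equal`.
#'
#' @param reference,comparator [evaluate_strategy()] results for the same
#'   population and settings.
#' @return Object of class `cea_comparison`: list with `reference`,
#'   `comparator`, `delta_cost`, `delta_qalys`, `delta_life_years`,
#'   `delta_life_days` (365.25 days/year), `icer` (numeric or `NA`) and
#'   `flag` in `c("icer", "dominant", "dominated", "equal")`.
#' @export
icer <- function(reference, comparator) {
  stopifnot(inherits(reference, "strategy_result"),
            inherits(comparator, "strategy_result"))
  if (!identical(reference$population, comparator$population)) {
    stop("cannot compare results from different populations (",
         reference$population, " vs ", comparator$population, ")",
         call. = FALSE)
  }
  dc <- comparator$discounted_cost - reference$discounted_cost
  de <- comparator$discounted_qalys - reference$discounted_qalys
  dly <- comparator$life_years - reference$life_years
  zero_e <- abs(de) < ICER_EFFECT_TOL
  zero_c <- abs(dc) < 1e-9
  if (zero_e && zero_c) {
    flag <- "equal"; ratio <- NA_real_
  } else if (dc <= 0 && (de > 0 || (zero_e && dc < 0))) {
    flag <- "dominant"; ratio <- NA_real_
  } else if (dc >= 0 && (de < 0 || (zero_e && dc > 0))) {
    flag <- "dominated"; ratio <- NA_real_
  } else {
    flag <- "icer"; ratio <- dc / de
  }
  structure(
    list(reference = reference$strategy, comparator = comparator$strategy,
         population = reference$population,
         delta_cost = dc, delta_qalys = de,
         delta_life_years = dly, delta_life_days = dly * DAYS_PER_YEAR,
         icer = ratio, flag = flag),
    class = "cea_comparison"
  )
}

#' @export
print.cea_comparison <- function(x, ...) {
  val <- if (x$flag == "icer") sprintf("%.2f USD/QALY", x$icer) else x$flag
  cat(sprintf("<cea_comparison> %s vs %s: dC %.2f, dQALY %.5f -> %s\n",
              x$comparator, x$reference, x$delta_cost, x$delta_qalys, val))
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp * QALYs - cost` for a strategy result (or for explicit cost/QALY
#' values).
#'
#' @param result A `strategy_result`, or a numeric discounted cost when
#'   `qalys` is supplied.
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @param qalys Optional QALYs when `result` is a numeric cost.
#' @return NMB in USD.
#' @export
nmb <- function(result, wtp, qalys = NULL) {
  if (wtp <= 0) stop("`wtp` must be positive", call. = FALSE)
  if (inherits(result, "strategy_result")) {
    return(wtp * result$discounted_qalys - result$discounted_cost)
  }
  if (is.null(qalys)) stop("supply `qalys` with a numeric cost", call. = FALSE)
  wtp * qalys - result
}

#' Is the comparator acceptable at a willingness-to-pay threshold?
#'
#' Equivalent to the incremental NMB rule `wtp * dQALY - dCost >= 0`:
#' dominant comparisons are accepted, dominated ones rejected, and a numeric
#' ICER is compared against `wtp` from the side its quadrant implies (more
#' effective and dearer: ICER <= wtp; cheaper and less effective:
#' ICER >= wtp).
#'
#' @param comparison An [icer()] result.
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @return `TRUE` or `FALSE`.
#' @export
wtp_verdict <- function(comparison, wtp) {
  stopifnot(inherits(comparison, "cea_comparison"))
  if (wtp <= 0) stop("`wtp` must be positive", call. = FALSE)
  switch(comparison$flag,
    equal = TRUE,
    dominant = TRUE,
    dominated = FALSE,
    icer = if (comparison$delta_qalys > 0) comparison$icer <= wtp
           else comparison$icer >= wtp
  )
}

#' Cost-effectiveness frontier
#'
#' Orders strategies by cost, removes strictly dominated ones (dearer, no
#' more effective) and extended-dominated ones (whose incremental ICER
#' exceeds that of a later, more effective option), leaving strictly
#' increasing ICERs along the frontier.
#'
#' @param results List of `strategy_result` objects (>= 2).
#' @return Data frame `strategy, cost, qalys, icer_vs_previous` in frontier
#'   order (`icer_vs_previous` is `NA` for the cheapest strategy).
#' @export
frontier <- function(results) {
  stopifnot(is.list(results), length(results) >= 2)
  tab <- data.frame(
    strategy = vapply(results, `[[`, character(1), "strategy"),
    cost = vapply(results, `[[`, numeric(1), "discounted_cost"),
    qalys = vapply(results, `[[`, numeric(1), "discounted_qalys"),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$cost, tab$qalys), ]
  # strict dominance: anything with a cheaper-or-equal, more effective rival
  keep <- vapply(seq_len(nrow(tab)), function(i) {
    !any(tab$cost <= tab$cost[i] & tab$qalys > tab$qalys[i] + ICER_EFFECT_TOL)
  }, logical(1))
  tab <- tab[keep, ]
  # extended dominance: prune until sequential ICERs are non-decreasing
  repeat {
    if (nrow(tab) < 3) break
    icers <- diff(tab$cost) / diff(tab$qalys)
    drop <- which(diff(icers) < -1e-12)
    if (!length(drop)) break
    tab <- tab[-(drop[1] + 1L), ]
  }
  tab$icer_vs_previous <- c(NA_real_, diff(tab$cost) / diff(tab$qalys))
  rownames(tab) <- NULL
  tab
}

#' Base-case comparison table for all three strategies
#'
#' Evaluates every strategy and reports discounted costs, life expectancy
#' and QALYs, plus incremental life-days, QALY-days and ICERs of the
#' universal strategy against both alternatives and of the selected strategy
#' against no testing.
#'
#' @param params A [parameter_set()].
#' @param settings A [model_settings()]; defaults to the set's settings.
#' @return List with `results` (per-strategy data frame) and `comparisons`
#'   (data frame of pairwise deltas and ICERs).
#' @export
compare_strategies <- function(params, settings = params$settings) {
  res <- lapply(strategies(), evaluate_strategy, params = params,
                settings = settings)
  names(res) <- strategies()
  results <- data.frame(
    strategy = strategies(),
    cost = vapply(res, `[[`, numeric(1), "discounted_cost"),
    life_years = vapply(res, `[[`, numeric(1), "life_years"),
    qalys = vapply(res, `[[`, numeric(1), "discounted_qalys"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  pairs <- list(
    c("NO_TEST", "SELECTED_TEST"),
    c("NO_TEST", "UNIVERSAL_TEST"),
    c("SELECTED_TEST", "UNIVERSAL_TEST")
  )
  comparisons <- do.call(rbind, lapply(pairs, function(pr) {
    cmp <- icer(res[[pr[1]]], res[[pr[2]]])
    data.frame(reference = cmp$reference, comparator = cmp$comparator,
               delta_cost = cmp$delta_cost, delta_qalys = cmp$delta_qalys,
               delta_life_days = cmp$delta_life_days,
               delta_qaly_days = cmp$delta_qalys * DAYS_PER_YEAR,
               icer = cmp$icer, flag = cmp$flag, stringsAsFactors = FALSE)
  }))
  list(results = results, comparisons = comparisons,
       strategy_results = res)
}
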