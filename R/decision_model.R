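# Decision tree: expand a (strategy, population) pair into weighted pathways.
#
# The cohort is stratified by family history (FH), germline BRCA carrier
# status, detection, and — for carriers — high-risk status. The testing
# strategy only controls who is tested, and the test is treated as perfect:
#   NO_TEST        nobody tested
#   SELECTED_TEST  FH-positive patients tested
#   UNIVERSAL_TEST everybody tested
# Detected carriers receive risk-reducing operations; detected high-risk
# carriers additionally receive one year of adjuvant olaparib. Any carrier who
# did not receive adjuvant olaparib receives one year of olaparib on entering
# recurrence (undetected carriers are tested at that point as well).

#' Testing strategies
#'
#' @return Character vector of the three strategy codes.
#' @export
strategies <- function() c("NO_TEST", "SELECTED_TEST", "UNIVERSAL_TEST")

#' Expand a strategy into weighted decision-tree pathways
#'
#' @param strategy One of [strategies()].
#' @param params A [parameter_set()] complete for its population.
#' @return Data frame with one row per decision-tree leaf: `leaf_id`,
#'   `weight`, the booleans `family_history`, `carrier`, `tested`,
#'   `detected`, `high_risk`, `rro`, `adjuvant_olaparib`,
#'   `olaparib_at_recurrence`, and the `upfront_cost` (USD at cycle 0:
#'   test + counselling + RRO + adjuvant olaparib as applicable). Weights sum
#'   to one.
#' @export
build_pathways <- function(strategy, params) {
  strategy <- match.arg(strategy, strategies())
  stopifnot(inherits(params, "parameter_set"))
  p_fh <- get_param(params, "prob_family_history")
  p_c_fh <- get_param(params, "prob_brca_given_fh")
  p_c_nofh <- get_param(params, "prob_brca_given_no_fh")
  p_hr <- get_param(params, "prob_high_risk")
  for (p in c(p_fh, p_c_fh, p_c_nofh, p_hr)) {
    if (is.na(p) || p < 0 || p > 1) {
      stop("decision-tree branch probabilities must be in [0, 1]",
           call. = FALSE)
    }
  }
  cost_test <- get_param(params, "cost_brca_test")
  cost_counsel <- get_param(params, "cost_genetic_counselling")
  cost_rro <- get_param(params, "cost_rro")
  cost_adjuvant <- get_param(params, "cost_olaparib_adjuvant")

  rows <- list()
  for (fh in c(TRUE, FALSE)) {
    w_fh <- if (fh) p_fh else 1 - p_fh
    p_carrier <- if (fh) p_c_fh else p_c_nofh
    tested <- switch(strategy,
                     NO_TEST = FALSE,
                     SELECTED_TEST = fh,
                     UNIVERSAL_TEST = TRUE)
    # carrier leaves, split by high-risk status
    for (hr in c(TRUE, FALSE)) {
      w <- w_fh * p_carrier * (if (hr) p_hr else 1 - p_hr)
      detected <- tested  # perfect test: detected <=> tested carrier
      adjuvant <- detected && hr
      rows[[length(rows) + 1L]] <- data.frame(
        family_history = fh, carrier = TRUE, tested = tested,
        detected = detected, high_risk = hr,
        rro = detected, adjuvant_olaparib = adjuvant,
        olaparib_at_recurrence = !adjuvant,
        weight = w,
        upfront_cost = tested * (cost_test + cost_counsel) +
          detected * cost_rro + adjuvant * cost_adjuvant
      )
    }
    # non-carrier leaf
    rows[[length(rows) + 1L]] <- data.frame(
      family_history = fh, carrier = FALSE, tested = tested,
      detected = FALSE, high_risk = FALSE,
      rro = FALSE, adjuvant_olaparib = FALSE,
      olaparib_at_recurrence = FALSE,
      weight = w_fh * (1 - p_carrier),
      upfront_cost = tested * (cost_test + cost_counsel)
    )
  }
  out <- do.call(rbind, rows)
  out <- cbind(strategy = strategy, leaf_id = seq_len(nrow(out)), out)
  total <- sum(out$weight)
  if (abs(total - 1) > 1e-12) {
    stop("pathway weights sum to ", format(total, digits = 15),
         ", not 1", call. = FALSE)
  }
  out
}

#' Fraction of the cohort whose mutation is detected
#'
#' Total weight of pathways with `detected = TRUE`; equals the overall
#' carrier prevalence under universal testing and zero under no testing.
#'
#' @inheritParams build_pathways
#' @return Probability.
#' @export
detected_fraction <- function(strategy, params) {
  pw <- build_pathways(strategy, params)
  sum(pw$weight[pw$detected])
}

#' Overall carrier prevalence implied by the decision-tree branches
#'
#' @param params A [parameter_set()].
#' @return `p(FH)·p(carrier|FH) + p(¬FH)·p(carrier|¬FH)`.
#' @export
carrier_prevalence <- function(params) {
  p_fh <- get_param(params, "prob_family_history")
  p_fh * get_param(params, "prob_brca_given_fh") +
    (1 - p_fh) * get_param(params, "prob_brca_given_no_fh")
}
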