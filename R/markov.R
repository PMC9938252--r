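# Three-state Markov cohort engine: disease-free (DF), recurrence, death.
# Death is absorbing and recovery from recurrence is impossible. Relative
# effects act on the recurrence hazard (rate scale), rewards are accumulated
# with a trapezoidal half-cycle correction and discounted at
# 1/(1+r)^t with cycle-0 rewards undiscounted.

HEALTH_STATES <- c("DISEASE_FREE", "RECURRENCE", "DEATH")

# One-row data frame from build_pathways() -> plain list.
as_pathway <- function(pathway) {
  if (is.data.frame(pathway)) pathway <- as.list(pathway[1L, ])
  needed <- c("carrier", "tested", "detected", "high_risk", "rro",
              "adjuvant_olaparib", "olaparib_at_recurrence", "upfront_cost")
  missing <- setdiff(needed, names(pathway))
  if (length(missing)) {
    stop("pathway is missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(pathway$leaf_id)) pathway$leaf_id <- NA_integer_
  pathway
}

# Annual DF -> recurrence probability for a pathway at a given cycle
# (cycle = 1 is the first model year). Relative effects multiply the hazard.
recurrence_probability <- function(pathway, cycle, params) {
  pathway <- as_pathway(pathway)
  p_base <- merge_recurrence(
    get_param(params, "prob_recurrence_locoregional"),
    get_param(params, "prob_recurrence_second_primary"),
    get_param(params, "prob_recurrence_distant")
  )
  rr <- 1
  if (isTRUE(pathway$carrier)) {
    if (!isTRUE(pathway$detected)) {
      rr <- rr * get_param(params, "rr_recurrence_undetected_carrier")
    }
    if (isTRUE(pathway$rro)) {
      rr <- rr * get_param(params, "rr_recurrence_rro")
    }
    if (isTRUE(pathway$adjuvant_olaparib)) {
      rr <- rr * if (cycle == 1L) {
        get_param(params, "rr_recurrence_olaparib")
      } else {
        get_param(params, "rr_recurrence_olaparib_longterm")
      }
    }
  }
  apply_relative_risk(p_base, rr)
}

#' Annual transition matrix for one pathway and cycle
#'
#' Rows and columns are ordered disease-free, recurrence, death. The
#' recurrence hazard carries the pathway's relative effects (undetected-carrier
#' excess risk, risk-reducing surgery, adjuvant olaparib during its active
#' year and a long-term effect thereafter), applied on the rate scale.
#'
#' @param pathway One row of [build_pathways()] output (or an equivalent list).
#' @param cycle Cycle index, 1-based (cycle 1 spans years 0 to 1).
#' @param params A [parameter_set()].
#' @return 3x3 row-stochastic matrix.
#' @export
build_transition_matrix <- function(pathway, cycle, params) {
  pathway <- as_pathway(pathway)
  p_rec <- recurrence_probability(pathway, cycle, params)
  p_df_death <- get_param(params, "prob_death_disease_free")
  p_rec_death <- get_param(params, "prob_death_recurrence")
  probs <- c(p_rec, p_df_death, p_rec_death)
  if (any(probs < 0) || any(probs > 1) || p_rec + p_df_death > 1) {
    stop("invalid transition probabilities for pathway ", pathway$leaf_id,
         " at cycle ", cycle, ": p(rec)=", signif(p_rec, 6),
         ", p(DF death)=", signif(p_df_death, 6),
         ", p(rec death)=", signif(p_rec_death, 6), call. = FALSE)
  }
  m <- matrix(c(
    1 - p_rec - p_df_death, p_rec,           p_df_death,
    0,                      1 - p_rec_death, p_rec_death,
    0,                      0,               1
  ), nrow = 3, byrow = TRUE, dimnames = list(HEALTH_STATES, HEALTH_STATES))
  m
}

#' Run the cohort model for one pathway
#'
#' Propagates the full cohort through the annual transition matrices:
#' `occupancy(t+1) = occupancy(t) %*% M(t+1)`.
#'
#' @inheritParams build_transition_matrix
#' @param settings A [model_settings()]; defaults to the set's settings.
#' @return Object of class `markov_trace`: list with `occupancy`
#'   (`(horizon+1) x 3` matrix, row `t+1` is the state distribution at time
#'   `t` years) and `p_recurrence` (per-cycle DF->recurrence probability,
#'   used for first-passage accounting).
#' @export
run_cohort <- function(pathway, params, settings = params$settings) {
  pathway <- as_pathway(pathway)
  h <- settings$horizon
  occ <- matrix(0, nrow = h + 1L, ncol = 3L,
                dimnames = list(NULL, HEALTH_STATES))
  occ[1L, ] <- c(1, 0, 0)
  p_rec <- numeric(h)
  for (t in seq_len(h)) {
    m <- build_transition_matrix(pathway, t, params)
    occ[t + 1L, ] <- occ[t, ] %*% m
    p_rec[t] <- m[1L, 2L]
  }
  rs <- rowSums(occ)
  if (any(abs(rs - 1) > 1e-10)) {
    stop("occupancy rows do not sum to 1 (max deviation ",
         max(abs(rs - 1)), ")", call. = FALSE)
  }
  structure(list(occupancy = occ, p_recurrence = p_rec, pathway = pathway),
            class = "markov_trace")
}

#' Accumulate costs, QALYs and life-years for one pathway
#'
#' Applies the trapezoidal half-cycle correction (the reward of cycle `t`
#' uses the average of the occupancies at `t` and `t+1`), discounts cycle `t`
#' by `1/(1+r)^t` (cycle 0 undiscounted), adds the pathway's upfront cost at
#' cycle 0, and charges recurrence-entry costs (one year of olaparib, plus
#' the test for carriers undetected at baseline) to the new entrants of each
#' cycle. Carriers receiving olaparib at recurrence also carry a persistent
#' recurrence-utility increment.
#'
#' @param trace A [run_cohort()] result.
#' @inheritParams run_cohort
#' @return List with `discounted_cost`, `discounted_qalys`, `life_years`
#'   (undiscounted), `discounted_life_years` and `upfront_cost`.
#' @export
accumulate_pathway <- function(trace, params, settings = params$settings,
                               pathway = trace$pathway) {
  stopifnot(inherits(trace, "markov_trace"))
  pathway <- as_pathway(pathway)
  occ <- trace$occupancy
  h <- settings$horizon
  cl <- settings$cycle_length
  r <- settings$discount_rate

  u_df <- get_param(params, "utility_disease_free")
  u_rec <- get_param(params, "utility_recurrence")
  if (isTRUE(pathway$olaparib_at_recurrence)) {
    u_rec <- u_rec + get_param(params, "utility_olaparib_recurrence_increment")
  }
  if (u_df < 0 || u_df > 1 || u_rec < 0 || u_rec > 1) {
    stop("state utility outside [0, 1] after stacking increments (DF=",
         signif(u_df, 4), ", recurrence=", signif(u_rec, 4), ")",
         call. = FALSE)
  }
  utilities <- c(u_df, u_rec, 0)
  state_costs <- c(get_param(params, "cost_disease_free_annual"),
                   get_param(params, "cost_recurrence_annual"), 0)
  entry_cost <- 0
  if (isTRUE(pathway$olaparib_at_recurrence)) {
    entry_cost <- get_param(params, "cost_olaparib_recurrence")
    if (isTRUE(pathway$carrier) && !isTRUE(pathway$tested)) {
      entry_cost <- entry_cost + get_param(params, "cost_brca_test")
    }
  }

  t_idx <- seq_len(h)                         # cycles 1..h, start at t-1 years
  eff <- (occ[t_idx, , drop = FALSE] + occ[t_idx + 1L, , drop = FALSE]) / 2
  df <- 1 / (1 + r)^(t_idx - 1L)
  entrants <- occ[t_idx, 1L] * trace$p_recurrence

  cycle_cost <- as.vector(eff %*% state_costs) * cl + entrants * entry_cost
  cycle_qaly <- as.vector(eff %*% utilities) * cl
  alive <- (eff[, 1L] + eff[, 2L]) * cl

  list(
    discounted_cost = pathway$upfront_cost + sum(cycle_cost * df),
    discounted_qalys = sum(cycle_qaly * df),
    life_years = sum(alive),
    discounted_life_years = sum(alive * df),
    upfront_cost = pathway$upfront_cost
  )
}

#' Evaluate one strategy: weighted average over its pathways
#'
#' @inheritParams build_pathways
#' @param settings A [model_settings()]; defaults to the set's settings.
#' @return Object of class `strategy_result`: list with `strategy`,
#'   `population`, `discounted_cost`, `discounted_qalys`, `life_years`,
#'   `discounted_life_years` and a per-pathway breakdown data frame.
#' @export
evaluate_strategy <- function(strategy, params, settings = params$settings) {
  pw <- build_pathways(strategy, params)
  per <- lapply(seq_len(nrow(pw)), function(i) {
    trace <- run_cohort(pw[i, ], params, settings)
    accumulate_pathway(trace, params, settings)
  })
  breakdown <- cbind(
    pw[, c("leaf_id", "weight", "family_history", "carrier", "detected",
           "high_risk", "adjuvant_olaparib", "olaparib_at_recurrence")],
    do.call(rbind, lapply(per, as.data.frame))
  )
  wavg <- function(col) sum(pw$weight * vapply(per, `[[`, numeric(1), col))
  structure(
    list(strategy = strategy, population = settings$population,
         discounted_cost = wavg("discounted_cost"),
         discounted_qalys = wavg("discounted_qalys"),
         life_years = wavg("life_years"),
         discounted_life_years = wavg("discounted_life_years"),
         pathways = breakdown),
    class = "strategy_result"
  )
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> %s / %s: cost %.2f USD, %.4f QALYs, %.4f LY\n",
              x$strategy, x$population, x$discounted_cost,
              x$discounted_qalys, x$life_years))
  invisible(x)
}

#' Per-cycle surviving fraction of the cohort under a strategy
#'
#' Weight-averaged `1 - death occupancy` at each cycle boundary; differences
#' between strategies give the avoided-death fractions.
#'
#' @inheritParams evaluate_strategy
#' @return Numeric vector of length `horizon + 1` (cycle 0 is 1).
#' @export
survival_curve <- function(strategy, params, settings = params$settings) {
  pw <- build_pathways(strategy, params)
  surv <- numeric(settings$horizon + 1L)
  for (i in seq_len(nrow(pw))) {
    occ <- run_cohort(pw[i, ], params, settings)$occupancy
    surv <- surv + pw$weight[i] * (1 - occ[, 3L])
  }
  surv
}

#' Export a trace as a per-cycle data frame
#'
#' @param trace A [run_cohort()] result.
#' @return Data frame `cycle, p_df, p_rec, p_death`.
#' @export
trace_as_data_frame <- function(trace) {
  stopifnot(inherits(trace, "markov_trace"))
  occ <- trace$occupancy
  data.frame(cycle = seq_len(nrow(occ)) - 1L,
             p_df = occ[, 1L], p_rec = occ[, 2L], p_death = occ[, 3L])
}
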