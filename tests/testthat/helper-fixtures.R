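# Shared fixtures: all built in code at test time.

anchored_params <- local({
  cache <- list()
  function(population = "TNBC_CN") {
    if (is.null(cache[[population]])) {
      cache[[population]] <<-
        generate_parameter_table(synthetic_scenario(population))
    }
    cache[[population]]
  }
})

# A single-row parameter table entry for direct fit_distribution tests.
param_row_fixture <- function(name = "x", category = "probability",
                              base = 0.2, low = 0.1, high = 0.3,
                              distribution = "beta", bound_type = "ci") {
  data.frame(name = name, category = category, population = "ALL",
             base = base, low = low, high = high,
             distribution = distribution, source_note = "",
             bound_type = bound_type, stringsAsFactors = FALSE)
}

# A hand-built parameter set with explicit transition inputs, for engine
# oracles. All branch probabilities collapse the tree to a single effective
# pathway when carrier prevalence is 0.
engine_params <- function(p_loco = 0, p_second = 0, p_distant = 0,
                          p_df_death = 0, p_rec_death = 0,
                          u_df = 0.85, u_rec = 0.51, u_inc = 0.075,
                          c_df = 0, c_rec = 0, c_ola_rec = 0,
                          population = "TNBC_CN", discount_rate = 0.03,
                          horizon = 20L, prevalence = 0) {
  row <- function(name, category, base, dist) {
    data.frame(name = name, category = category, population = "ALL",
               base = base, low = base, high = base, distribution = dist,
               source_note = "fixture", bound_type = NA_character_,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(
    row("prob_family_history", "probability", 0.2, "fixed"),
    row("prob_brca_given_fh", "probability", prevalence, "fixed"),
    row("prob_brca_given_no_fh", "probability", prevalence, "fixed"),
    row("prob_high_risk", "probability", 0.5, "fixed"),
    row("prob_recurrence_locoregional", "probability", p_loco, "fixed"),
    row("prob_recurrence_second_primary", "probability", p_second, "fixed"),
    row("prob_recurrence_distant", "probability", p_distant, "fixed"),
    row("prob_death_disease_free", "probability", p_df_death, "fixed"),
    row("prob_death_recurrence", "probability", p_rec_death, "fixed"),
    row("rr_recurrence_olaparib", "relative_effect", 1, "fixed"),
    row("rr_recurrence_olaparib_longterm", "relative_effect", 1, "fixed"),
    row("rr_recurrence_rro", "relative_effect", 1, "fixed"),
    row("rr_recurrence_undetected_carrier", "relative_effect", 1, "fixed"),
    row("cost_brca_test", "cost", 0, "fixed"),
    row("cost_genetic_counselling", "cost", 0, "fixed"),
    row("cost_rro", "cost", 0, "fixed"),
    row("cost_olaparib_adjuvant", "cost", 0, "fixed"),
    row("cost_olaparib_recurrence", "cost", c_ola_rec, "fixed"),
    row("cost_disease_free_annual", "cost", c_df, "fixed"),
    row("cost_recurrence_annual", "cost", c_rec, "fixed"),
    row("utility_disease_free", "utility", u_df, "fixed"),
    row("utility_recurrence", "utility", u_rec, "fixed"),
    row("utility_olaparib_recurrence_increment", "utility", u_inc, "fixed")
  )
  parameter_set(tab, model_settings(population, horizon = horizon,
                                    discount_rate = discount_rate))
}

# A bare non-carrier pathway for direct engine calls.
simple_pathway <- function(carrier = FALSE, tested = FALSE, detected = FALSE,
                           high_risk = FALSE, rro = detected,
                           adjuvant_olaparib = FALSE,
                           olaparib_at_recurrence = carrier && !adjuvant_olaparib,
                           upfront_cost = 0) {
  list(leaf_id = 1L, weight = 1, family_history = FALSE, carrier = carrier,
       tested = tested, detected = detected, high_risk = high_risk,
       rro = rro, adjuvant_olaparib = adjuvant_olaparib,
       olaparib_at_recurrence = olaparib_at_recurrence,
       upfront_cost = upfront_cost)
}

# Minimal strategy_result stand-in for CEA algebra tests.
fake_result <- function(cost, qalys, strategy = "NO_TEST",
                        life_years = qalys, population = "TNBC_CN") {
  structure(list(strategy = strategy, population = population,
                 discounted_cost = cost, discounted_qalys = qalys,
                 life_years = life_years, discounted_life_years = life_years,
                 pathways = NULL),
            class = "strategy_result")
}
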