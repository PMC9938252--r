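# Synthetic parameter table: one place for every shipped input value.
#
# Values marked pinned = TRUE are the main-text constants of the modelled
# study design (utilities 0.85 / 0.51 / +0.075, carrier prevalence 0.10 in
# TNBC and 0.097 in HER2-negative disease, and the family-history anchor
# that makes selected testing detect 4.30% of the TNBC cohort and 3.36% of
# the HER2-negative cohort). Everything else is a documented plausible
# placeholder ("placeholder - supplement value unknown"): swapping in real
# supplement values is a file edit, not a code change.

PLACEHOLDER_NOTE <- "placeholder - supplement value unknown"

synthetic_rows <- function() {
  row <- function(name, category, population, base, low, high, distribution,
                  bound_type, pinned, note) {
    data.frame(name = name, category = category, population = population,
               base = base, low = low, high = high,
               distribution = distribution, source_note = note,
               bound_type = bound_type, pinned = pinned,
               stringsAsFactors = FALSE)
  }
  rows <- list(
    # --- utilities (shared across populations), main-text values ----------
    row("utility_disease_free", "utility", "ALL", 0.85, 0.765, 0.935,
        "beta", "fallback", TRUE, "disease-free utility, main text"),
    row("utility_recurrence", "utility", "ALL", 0.51, 0.459, 0.561,
        "beta", "fallback", TRUE, "recurrence utility, main text"),
    row("utility_olaparib_recurrence_increment", "utility", "ALL",
        0.075, 0.0675, 0.0825, "beta", "fallback", TRUE,
        "recurrence utility increment on olaparib, main text"),
    # --- relative effects on the recurrence hazard (shared) ---------------
    row("rr_recurrence_olaparib", "relative_effect", "ALL",
        0.58, 0.41, 0.82, "lognormal", "ci", FALSE,
        paste0(PLACEHOLDER_NOTE, "; adjuvant-trial-like iDFS hazard ratio")),
    row("rr_recurrence_olaparib_longterm", "relative_effect", "ALL",
        0.75, 0.60, 0.94, "lognormal", "ci", FALSE,
        paste0(PLACEHOLDER_NOTE, "; durable post-treatment effect")),
    row("rr_recurrence_rro", "relative_effect", "ALL",
        0.60, 0.45, 0.80, "lognormal", "ci", FALSE,
        paste0(PLACEHOLDER_NOTE, "; risk-reducing surgery effect")),
    row("rr_recurrence_undetected_carrier", "relative_effect", "ALL",
        1.20, 1.08, 1.32, "lognormal", "fallback", FALSE,
        paste0(PLACEHOLDER_NOTE, "; excess risk, undetected carriers"))
  )
  # --- disease-level probabilities (same in both countries) ---------------
  prob <- function(name, pops, base, low, high, pinned, note) {
    lapply(pops, function(p) row(name, "probability", p, base, low, high,
                                 "beta", "ci", pinned, note))
  }
  tn <- c("TNBC_CN", "TNBC_US")
  h2 <- c("HER2NEG_CN", "HER2NEG_US")
  rows <- c(rows,
    prob("prob_family_history", tn, 0.20, 0.16, 0.24, TRUE,
         "family-history branch anchor"),
    prob("prob_brca_given_fh", tn, 0.215, 0.172, 0.258, TRUE,
         "anchors selected-testing detection at 4.30% of the cohort"),
    prob("prob_brca_given_no_fh", tn, 0.07125, 0.057, 0.0855, TRUE,
         "derived: keeps marginal carrier prevalence at 0.10"),
    prob("prob_high_risk", tn, 0.60, 0.48, 0.72, FALSE, PLACEHOLDER_NOTE),
    prob("prob_recurrence_locoregional", tn, 0.020, 0.016, 0.024, FALSE,
         PLACEHOLDER_NOTE),
    prob("prob_recurrence_second_primary", tn, 0.010, 0.008, 0.012, FALSE,
         PLACEHOLDER_NOTE),
    prob("prob_recurrence_distant", tn, 0.050, 0.040, 0.060, FALSE,
         PLACEHOLDER_NOTE),
    prob("prob_death_disease_free", tn, 0.005, 0.004, 0.006, FALSE,
         paste0(PLACEHOLDER_NOTE, "; annual, from 5-year trial mortality")),
    prob("prob_death_recurrence", tn, 0.25, 0.20, 0.30, FALSE,
         PLACEHOLDER_NOTE),
    prob("prob_family_history", h2, 0.20, 0.16, 0.24, TRUE,
         "family-history branch anchor"),
    prob("prob_brca_given_fh", h2, 0.168, 0.134, 0.202, TRUE,
         "anchors selected-testing detection at 3.36% of the cohort"),
    prob("prob_brca_given_no_fh", h2, 0.07925, 0.0634, 0.0951, TRUE,
         "derived: keeps marginal carrier prevalence at 0.097"),
    prob("prob_high_risk", h2, 0.50, 0.40, 0.60, FALSE, PLACEHOLDER_NOTE),
    prob("prob_recurrence_locoregional", h2, 0.015, 0.012, 0.018, FALSE,
         PLACEHOLDER_NOTE),
    prob("prob_recurrence_second_primary", h2, 0.008, 0.0064, 0.0096, FALSE,
         PLACEHOLDER_NOTE),
    prob("prob_recurrence_distant", h2, 0.035, 0.028, 0.042, FALSE,
         PLACEHOLDER_NOTE),
    prob("prob_death_disease_free", h2, 0.004, 0.0032, 0.0048, FALSE,
         paste0(PLACEHOLDER_NOTE, "; annual, from 5-year trial mortality")),
    prob("prob_death_recurrence", h2, 0.18, 0.144, 0.216, FALSE,
         PLACEHOLDER_NOTE)
  )
  # --- costs, 2021 USD, country-level --------------------------------------
  cost <- function(name, pops, base, note = PLACEHOLDER_NOTE) {
    lapply(pops, function(p) row(name, "cost", p, base, 0.8 * base,
                                 1.2 * base, "gamma", "ci", FALSE, note))
  }
  cn <- c("TNBC_CN", "HER2NEG_CN")
  us <- c("TNBC_US", "HER2NEG_US")
  rows <- c(rows,
    cost("cost_brca_test", cn, 300), cost("cost_brca_test", us, 1500),
    cost("cost_genetic_counselling", cn, 50),
    cost("cost_genetic_counselling", us, 250),
    cost("cost_rro", cn, 6000), cost("cost_rro", us, 25000),
    cost("cost_olaparib_adjuvant", cn, 22000,
         paste0(PLACEHOLDER_NOTE, "; one year of adjuvant olaparib")),
    cost("cost_olaparib_adjuvant", us, 160000,
         paste0(PLACEHOLDER_NOTE, "; one year of adjuvant olaparib")),
    cost("cost_olaparib_recurrence", cn, 22000,
         paste0(PLACEHOLDER_NOTE, "; one year of olaparib at recurrence")),
    cost("cost_olaparib_recurrence", us, 160000,
         paste0(PLACEHOLDER_NOTE, "; one year of olaparib at recurrence")),
    cost("cost_disease_free_annual", cn, 600),
    cost("cost_disease_free_annual", us, 2500),
    cost("cost_recurrence_annual", cn, 12000),
    cost("cost_recurrence_annual", us, 60000)
  )
  flat <- list()
  for (r in rows) flat <- c(flat, if (is.data.frame(r)) list(r) else r)
  do.call(rbind, flat)
}
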