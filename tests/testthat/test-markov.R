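# Cohort engine: transition matrices, occupancy propagation, rewards.

test_that("transition matrices are row-stochastic with an absorbing death state", {
  ps <- anchored_params("TNBC_CN")
  pw <- build_pathways("UNIVERSAL_TEST", ps)
  for (i in seq_len(nrow(pw))) {
    for (cycle in c(1L, 2L, 20L)) {
      m <- build_transition_matrix(pw[i, ], cycle, ps)
      expect_equal(unname(rowSums(m)), c(1, 1, 1), tolerance = 1e-12)
      expect_true(all(m >= 0 & m <= 1))
      expect_equal(unname(m[3, ]), c(0, 0, 1))  # death absorbing
      expect_equal(m[2, 1], 0)                  # no recovery
    }
  }
})

test_that("relative effects act on the rate scale", {
  # halving the recurrence hazard: p -> 1 - (1 - p)^0.5
  p_base <- merge_recurrence(0.02, 0.01, 0.05)
  ps <- engine_params(p_loco = 0.02, p_second = 0.01, p_distant = 0.05,
                      prevalence = 1)
  ps <- set_param_base(ps, "rr_recurrence_olaparib", 0.5)
  pw <- simple_pathway(carrier = TRUE, tested = TRUE, detected = TRUE,
                       high_risk = TRUE, rro = FALSE, adjuvant_olaparib = TRUE,
                       olaparib_at_recurrence = FALSE)
  pw$rro <- FALSE
  m <- build_transition_matrix(pw, 1L, ps)
  expect_equal(m[1, 2], 1 - (1 - p_base)^0.5, tolerance = 1e-12)
  expect_equal(m[1, 2], 0.0399531, tolerance = 1e-6)
  # long-term effect takes over after the adjuvant year
  ps <- set_param_base(ps, "rr_recurrence_olaparib_longterm", 0.8)
  m2 <- build_transition_matrix(pw, 2L, ps)
  expect_equal(m2[1, 2], 1 - (1 - p_base)^0.8, tolerance = 1e-12)
})

test_that("degenerate matrices behave: zero transitions and certain death", {
  ps0 <- engine_params()
  m <- build_transition_matrix(simple_pathway(), 1L, ps0)
  expect_equal(unname(m[1, ]), c(1, 0, 0))
  tr <- run_cohort(simple_pathway(), ps0)
  expect_true(all(tr$occupancy[, 1] == 1))
  ps1 <- engine_params(p_df_death = 1)
  tr1 <- run_cohort(simple_pathway(), ps1)
  expect_equal(unname(tr1$occupancy[1, ]), c(1, 0, 0))
  expect_true(all(tr1$occupancy[-1, 3] == 1))
})

test_that("two-cycle occupancy matches path enumeration", {
  # p(DF->REC) = 0.5, p(REC->DEATH) = 0.5, no other exits. The four two-step
  # paths: DF>DF>DF 0.25, DF>DF>REC 0.25, DF>REC>REC 0.25, DF>REC>DEATH 0.25.
  ps <- engine_params(p_loco = 0.5, p_rec_death = 0.5)
  tr <- run_cohort(simple_pathway(), ps)
  expect_equal(unname(tr$occupancy[2, ]), c(0.5, 0.5, 0), tolerance = 1e-14)
  expect_equal(unname(tr$occupancy[3, ]), c(0.25, 0.5, 0.25),
               tolerance = 1e-14)
})

test_that("occupancy conserves mass and death is monotone", {
  ps <- anchored_params("HER2NEG_CN")
  pw <- build_pathways("SELECTED_TEST", ps)
  for (i in seq_len(nrow(pw))) {
    occ <- run_cohort(pw[i, ], ps)$occupancy
    expect_equal(rowSums(occ), rep(1, nrow(occ)), tolerance = 1e-10)
    expect_true(all(diff(occ[, 3]) >= -1e-14))
    expect_equal(unname(occ[1, ]), c(1, 0, 0))
  }
})

test_that("a constant disease-free trace accumulates 20 x utility QALYs", {
  ps <- engine_params(u_df = 0.85, discount_rate = 0)
  tr <- run_cohort(simple_pathway(), ps)
  acc <- accumulate_pathway(tr, ps)
  expect_equal(acc$discounted_qalys, 17, tolerance = 1e-12)
  expect_equal(acc$life_years, 20, tolerance = 1e-12)
  ps1 <- engine_params(u_df = 1, discount_rate = 0)
  acc1 <- accumulate_pathway(run_cohort(simple_pathway(), ps1), ps1)
  expect_equal(acc1$discounted_qalys, 20, tolerance = 1e-12)
})

test_that("cycle-0 rewards are undiscounted (discount convention)", {
  ps <- engine_params(c_df = 100, horizon = 1L, discount_rate = 0.03)
  acc <- accumulate_pathway(run_cohort(simple_pathway(), ps), ps)
  expect_equal(acc$discounted_cost, 100, tolerance = 1e-12)
  # with two cycles the second is discounted once
  ps2 <- engine_params(c_df = 100, horizon = 2L, discount_rate = 0.03)
  acc2 <- accumulate_pathway(run_cohort(simple_pathway(), ps2), ps2)
  expect_equal(acc2$discounted_cost, 100 + 100 / 1.03, tolerance = 1e-12)
})

test_that("zero discounting equals the undiscounted accumulation exactly", {
  ps <- engine_params(p_loco = 0.05, p_df_death = 0.01, p_rec_death = 0.2,
                      c_df = 500, c_rec = 8000, discount_rate = 0)
  acc <- accumulate_pathway(run_cohort(simple_pathway(), ps), ps)
  expect_equal(acc$discounted_life_years, acc$life_years, tolerance = 1e-12)
})

test_that("constant-hazard QALYs match the geometric-series closed form", {
  q <- 0.07
  r <- 0.03
  u <- 0.85
  h <- 20
  ps <- engine_params(p_df_death = q, u_df = u, discount_rate = r)
  acc <- accumulate_pathway(run_cohort(simple_pathway(), ps), ps)
  # trapezoid on survival (1-q)^t, discount factor (1+r)^-t
  t <- 0:(h - 1)
  closed <- sum(((1 - q)^t + (1 - q)^(t + 1)) / 2 * u / (1 + r)^t)
  expect_equal(acc$discounted_qalys, closed, tolerance = 1e-10)
})

test_that("raising any recurrence probability never increases QALYs", {
  ps <- anchored_params("TNBC_CN")
  base <- evaluate_strategy("UNIVERSAL_TEST", ps)$discounted_qalys
  for (nm in c("prob_recurrence_locoregional", "prob_recurrence_distant",
               "prob_recurrence_second_primary")) {
    for (bump in c(0.01, 0.05)) {
      ps2 <- set_param_base(ps, nm, get_param(ps, nm) + bump)
      expect_lte(evaluate_strategy("UNIVERSAL_TEST", ps2)$discounted_qalys,
                 base + 1e-12)
    }
  }
})

test_that("a mixture of identical pathways equals the single-pathway result", {
  ps <- engine_params(p_loco = 0.05, p_rec_death = 0.2, c_df = 100,
                      c_rec = 5000)
  single <- accumulate_pathway(run_cohort(simple_pathway(), ps), ps)
  # prevalence 0 collapses every leaf to the standard-treatment profile
  for (s in strategies()) {
    res <- evaluate_strategy(s, ps)
    expect_equal(res$discounted_cost, single$discounted_cost,
                 tolerance = 1e-10)
    expect_equal(res$discounted_qalys, single$discounted_qalys,
                 tolerance = 1e-10)
  }
})

test_that("testing without consequences leaves strategies identical", {
  ps <- generate_parameter_table(
    synthetic_scenario("TNBC_CN", realism = "degenerate",
                       variant = "no_benefit"))
  res <- lapply(strategies(), evaluate_strategy, params = ps)
  costs <- vapply(res, `[[`, numeric(1), "discounted_cost")
  qalys <- vapply(res, `[[`, numeric(1), "discounted_qalys")
  expect_equal(unname(diff(range(costs))), 0, tolerance = 1e-9)
  expect_equal(unname(diff(range(qalys))), 0, tolerance = 1e-12)
})

test_that("survival curves start at 1 and difference to zero for identical inputs", {
  ps <- anchored_params("TNBC_CN")
  for (s in strategies()) {
    surv <- survival_curve(s, ps)
    expect_equal(surv[1], 1)
    expect_true(all(diff(surv) <= 1e-14))
  }
  ps0 <- generate_parameter_table(
    synthetic_scenario("TNBC_CN", realism = "degenerate",
                       variant = "no_benefit"))
  d <- survival_curve("UNIVERSAL_TEST", ps0) - survival_curve("NO_TEST", ps0)
  expect_equal(d, rep(0, ps0$settings$horizon + 1), tolerance = 1e-14)
})

test_that("utility stacking beyond [0, 1] is reported, not silently clamped", {
  ps <- engine_params(u_rec = 0.96, u_inc = 0.075, p_loco = 0.1,
                      prevalence = 1)
  pw <- simple_pathway(carrier = TRUE, olaparib_at_recurrence = TRUE)
  tr <- run_cohort(pw, ps)
  expect_error(accumulate_pathway(tr, ps), "utility outside")
})

test_that("invalid transition rows name the pathway and cycle", {
  ps <- engine_params(p_loco = 0.9, p_df_death = 0.5)
  expect_error(run_cohort(simple_pathway(), ps), "cycle 1")
})
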