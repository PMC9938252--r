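# Tornado (one-way DSA) and probabilistic sensitivity analysis.

test_that("degenerate parameters produce zero tornado range, sorted last", {
  ps <- anchored_params("TNBC_CN")
  tor <- one_way_dsa(ps)
  expect_setequal(tor$parameter, required_parameters())
  expect_true(all(diff(tor$range[!is.na(tor$range)]) <= 1e-9))
  # a parameter that neither compared strategy's pathways use: make one
  ps0 <- generate_parameter_table(
    synthetic_scenario("TNBC_CN", realism = "degenerate",
                       variant = "all_fixed"))
  tor0 <- one_way_dsa(ps0)
  expect_true(all(tor0$range == 0))
})

test_that("tornado range is exactly zero for a parameter no pathway uses", {
  # zero prevalence: no carrier pathways, so olaparib and RRO parameters are
  # never exercised by either strategy
  ps <- engine_params(p_loco = 0.05, p_rec_death = 0.2, c_df = 100,
                      c_rec = 5000)
  idx <- ps$parameters$name %in% c("cost_olaparib_adjuvant", "cost_rro")
  ps$parameters$low[idx] <- 0
  ps$parameters$high[idx] <- 2 * ps$parameters$base[idx] + 10
  tor <- one_way_dsa(ps)
  expect_equal(tor$range[tor$parameter == "cost_olaparib_adjuvant"], 0)
  expect_equal(tor$range[tor$parameter == "cost_rro"], 0)
})

test_that("cost-only variation matches the direct accounting oracle", {
  # adjuvant olaparib cost enters only at cycle 0 of adjuvant pathways, so
  # d(incremental NMB)/d(cost) = -(adjuvant weight difference)
  ps <- anchored_params("TNBC_CN")
  row <- ps$parameters[ps$parameters$name == "cost_olaparib_adjuvant" &
                         ps$parameters$population == "TNBC_CN", ]
  tor <- one_way_dsa(ps)
  entry <- tor[tor$parameter == "cost_olaparib_adjuvant", ]
  w_adj <- function(strategy) {
    pw <- build_pathways(strategy, ps)
    sum(pw$weight[pw$adjuvant_olaparib])
  }
  dw <- w_adj("UNIVERSAL_TEST") - w_adj("SELECTED_TEST")
  expect_equal(entry$nmb_at_high - entry$nmb_at_low,
               -dw * (row$high - row$low), tolerance = 1e-6)
})

test_that("an all-fixed table makes every PSA draw the base case", {
  ps <- generate_parameter_table(
    synthetic_scenario("TNBC_CN", realism = "degenerate",
                       variant = "all_fixed"))
  samples <- run_psa(ps, n_draws = 5, seed = 3)
  base <- compare_strategies(ps)$results
  for (s in strategies()) {
    sub <- samples[samples$strategy == s, ]
    expect_equal(sub$cost, rep(base$cost[base$strategy == s], 5),
                 tolerance = 1e-9)
    expect_equal(sub$qalys, rep(base$qalys[base$strategy == s], 5),
                 tolerance = 1e-12)
  }
})

test_that("PSA is reproducible from its seed", {
  ps <- anchored_params("TNBC_CN")
  s1 <- run_psa(ps, n_draws = 10, seed = 42)
  s2 <- run_psa(ps, n_draws = 10, seed = 42)
  expect_equal(s1, s2)
  s3 <- run_psa(ps, n_draws = 10, seed = 43)
  expect_false(isTRUE(all.equal(s1$cost, s3$cost)))
})

test_that("sampled parameter means recover base values within 3 SE", {
  ps <- anchored_params("TNBC_CN")
  samples <- run_psa(ps, n_draws = 1000, seed = 5)
  draws <- attr(samples, "samples")
  # disease-free utility: mean 0.85, SD 0.085 (10% rule)
  m <- mean(draws[, "utility_disease_free"])
  expect_lt(abs(m - 0.85), 3 * 0.085 / sqrt(1000))
  # recurrence utility: 5% rule
  m <- mean(draws[, "utility_recurrence"])
  expect_lt(abs(m - 0.51), 3 * 0.0255 / sqrt(1000))
  # a gamma-distributed cost
  row <- ps$parameters[ps$parameters$name == "cost_olaparib_adjuvant" &
                         ps$parameters$population == "TNBC_CN", ]
  sd_cost <- (row$high - row$low) / 3.92
  m <- mean(draws[, "cost_olaparib_adjuvant"])
  expect_lt(abs(m - row$base), 3 * sd_cost / sqrt(1000))
})

test_that("CEAC probabilities sum to one and respect the WTP limits", {
  ps <- anchored_params("TNBC_CN")
  samples <- run_psa(ps, n_draws = 200, seed = 9)
  curve <- ceac(samples, wtp_grid = seq(0, 150000, 15000))
  sums <- as.numeric(tapply(curve$probability, curve$wtp, sum))
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-12)
  m <- attr(samples, "samples")
  # wtp = 0: the cheapest strategy per draw wins
  cost_w <- matrix(samples$cost, ncol = 3, byrow = TRUE,
                   dimnames = list(NULL, samples$strategy[1:3]))
  cheapest <- colMeans(cost_w <= apply(cost_w, 1, min) + 1e-9)
  at0 <- curve[curve$wtp == 0, ]
  for (s in strategies()) {
    expect_equal(at0$probability[at0$strategy == s], unname(cheapest[s]),
                 tolerance = 1e-12)
  }
  # very large wtp: the highest-QALY strategy per draw wins
  qaly_w <- matrix(samples$qalys, ncol = 3, byrow = TRUE,
                   dimnames = list(NULL, samples$strategy[1:3]))
  best_q <- names(which.max(colMeans(qaly_w)))
  big <- ceac(samples, wtp_grid = 1e9)
  expect_gt(big$probability[big$strategy == best_q], 0.95)
})

test_that("CEAC collapses to the base-case step function as SDs -> 0", {
  ps <- anchored_params("TNBC_CN")
  tab <- ps$parameters
  # shrink every range to a +/- 1.96e-6 CI around base
  tab$low <- tab$base - 1.96e-6
  tab$high <- tab$base + 1.96e-6
  tab$low <- pmax(tab$low, 0)
  tab$bound_type <- "ci"
  ps_tiny <- parameter_set(tab, ps$settings)
  samples <- run_psa(ps_tiny, n_draws = 50, seed = 21)
  # per-strategy means converge to base case
  base <- compare_strategies(ps)$results
  for (s in strategies()) {
    expect_equal(mean(samples$cost[samples$strategy == s]),
                 base$cost[base$strategy == s], tolerance = 1e-3)
  }
  # CEAC equals the deterministic argmax-NMB step function on a grid
  curve <- ceac(samples, wtp_grid = seq(0, 60000, 6000))
  res <- compare_strategies(ps)$strategy_results
  for (w in unique(curve$wtp)) {
    nmbs <- vapply(res, nmb, numeric(1), wtp = max(w, 1))
    winner <- names(which.max(nmbs))
    sub <- curve[curve$wtp == w, ]
    expect_equal(sub$probability[sub$strategy == winner], 1,
                 tolerance = 0.05)
  }
})

test_that("the CE plane is consistent with pairwise CEAC for two strategies", {
  ps <- anchored_params("TNBC_CN")
  samples <- run_psa(ps, n_draws = 200, seed = 31)
  two <- samples[samples$strategy != "NO_TEST", ]
  plane <- ce_plane(samples, reference = "SELECTED_TEST")
  pts <- plane[plane$strategy == "UNIVERSAL_TEST", ]
  wtp <- 31500
  below_ray <- mean(wtp * pts$delta_qalys - pts$delta_cost >= 0)
  curve <- ceac(two, wtp_grid = wtp)
  expect_equal(below_ray,
               curve$probability[curve$strategy == "UNIVERSAL_TEST"],
               tolerance = 1e-12)
  # reference vs itself: all points at the origin
  self <- ce_plane(samples, reference = "UNIVERSAL_TEST")
  expect_true(all(abs(self$delta_cost[self$strategy == "UNIVERSAL_TEST"]) == 0) ||
                !"UNIVERSAL_TEST" %in% self$strategy)
})
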