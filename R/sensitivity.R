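# Deterministic (tornado) and probabilistic sensitivity analysis.

#' Default willingness-to-pay grid for acceptability curves
#'
#' 0 to 150,000 USD/QALY in 1,500-USD steps, covering both country
#' thresholds.
#'
#' @return Numeric vector.
#' @export
default_wtp_grid <- function() seq(0, 150000, by = 1500)

# Effective parameter rows for the set's population (population overrides ALL).
effective_rows <- function(ps) {
  p <- ps$parameters
  nms <- available_names(ps)
  do.call(rbind, lapply(nms, function(n) param_row(ps, n)))
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-evaluates the incremental net monetary benefit of
#' `comparator` vs `reference` at the population WTP with each parameter set
#' to its low and high bound in turn (all other parameters at base).
#'
#' @param params A [parameter_set()].
#' @param settings A [model_settings()]; defaults to the set's settings.
#' @param reference,comparator Strategy codes; default selected vs universal.
#' @param wtp Willingness-to-pay; defaults to the settings threshold.
#' @return Data frame sorted by descending `range`:
#'   `parameter, base_value, low, high, nmb_at_low, nmb_at_high, range,
#'   flagged` (`flagged` marks bounds that broke model validity; their NMB is
#'   `NA` but the row is kept).
#' @export
one_way_dsa <- function(params, settings = params$settings,
                        reference = "SELECTED_TEST",
                        comparator = "UNIVERSAL_TEST",
                        wtp = settings$wtp) {
  reference <- match.arg(reference, strategies())
  comparator <- match.arg(comparator, strategies())
  inc_nmb <- function(ps) {
    a <- evaluate_strategy(reference, ps, settings)
    b <- evaluate_strategy(comparator, ps, settings)
    nmb(b, wtp) - nmb(a, wtp)
  }
  base_nmb <- inc_nmb(params)
  rows <- effective_rows(params)
  out <- lapply(seq_len(nrow(rows)), function(i) {
    row <- rows[i, ]
    at <- function(value) {
      tryCatch(inc_nmb(set_param_base(params, row$name, value)),
               error = function(e) NA_real_)
    }
    lo <- at(row$low)
    hi <- at(row$high)
    data.frame(parameter = row$name, base_value = row$base,
               low = row$low, high = row$high,
               nmb_at_low = lo, nmb_at_high = hi,
               range = if (is.na(lo) || is.na(hi)) NA_real_ else abs(hi - lo),
               flagged = is.na(lo) || is.na(hi),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$range, na.last = TRUE), ]
  rownames(out) <- NULL
  attr(out, "base_nmb") <- base_nmb
  attr(out, "wtp") <- wtp
  attr(out, "comparison") <- c(reference = reference, comparator = comparator)
  out
}

#' Probabilistic sensitivity analysis (Monte-Carlo)
#'
#' Draws every non-fixed parameter independently from its fitted
#' distribution ([fit_distribution()]), evaluates all three strategies for
#' each joint draw, and records per-draw costs and QALYs. Draws that break
#' model validity (e.g. sampled probabilities making a transition row exceed
#' one) are redrawn; a redraw rate above 1% triggers a warning.
#'
#' @param params A [parameter_set()].
#' @param settings A [model_settings()]; defaults to the set's settings.
#' @param n_draws Number of Monte-Carlo draws (default from settings).
#' @param seed Integer RNG seed (default from settings).
#' @return Data frame `draw, strategy, cost, qalys` with attributes
#'   `samples` (draw x parameter matrix of sampled values), `seed` and
#'   `redraws`.
#' @export
run_psa <- function(params, settings = params$settings,
                    n_draws = settings$psa_draws,
                    seed = settings$rng_seed) {
  rows <- effective_rows(params)
  dists <- lapply(seq_len(nrow(rows)), function(i) fit_distribution(rows[i, ]))
  names(dists) <- rows$name
  set.seed(seed)
  n_par <- length(dists)
  samples <- matrix(NA_real_, nrow = n_draws, ncol = n_par,
                    dimnames = list(NULL, rows$name))
  recs <- vector("list", n_draws * 3L)
  redraws <- 0L
  for (d in seq_len(n_draws)) {
    repeat {
      drawn <- vapply(dists, function(ds) sample_distribution(ds, 1L),
                      numeric(1))
      ps_d <- params
      ps_d$values[names(drawn)] <- drawn
      res <- tryCatch(
        lapply(strategies(), evaluate_strategy, params = ps_d,
               settings = settings),
        error = function(e) NULL
      )
      if (!is.null(res)) break
      redraws <- redraws + 1L
      if (redraws > 100L * n_draws) {
        stop("PSA cannot find feasible draws; check parameter bounds",
             call. = FALSE)
      }
    }
    samples[d, ] <- drawn
    for (k in seq_along(res)) {
      recs[[(d - 1L) * 3L + k]] <- data.frame(
        draw = d, strategy = res[[k]]$strategy,
        cost = res[[k]]$discounted_cost,
        qalys = res[[k]]$discounted_qalys, stringsAsFactors = FALSE)
    }
  }
  if (redraws > 0.01 * n_draws) {
    warning(redraws, " redraws for ", n_draws,
            " PSA draws (>1%); parameter distributions may be too wide",
            call. = FALSE)
  }
  out <- do.call(rbind, recs)
  attr(out, "samples") <- samples
  attr(out, "seed") <- seed
  attr(out, "redraws") <- redraws
  out
}

# Wide cost/qalys matrices (draw x strategy) from a PSA sample frame.
psa_matrices <- function(samples) {
  strats <- sort(unique(samples$strategy))
  draws <- sort(unique(samples$draw))
  shape <- function(col) {
    m <- matrix(NA_real_, nrow = length(draws), ncol = length(strats),
                dimnames = list(NULL, strats))
    for (s in strats) {
      sub <- samples[samples$strategy == s, ]
      m[match(sub$draw, draws), s] <- sub[[col]]
    }
    m
  }
  list(cost = shape("cost"), qalys = shape("qalys"), strategies = strats)
}

#' Cost-effectiveness acceptability curves
#'
#' For each WTP value, the probability that each strategy attains the
#' maximum net monetary benefit across the PSA draws (ties split evenly).
#'
#' @param samples A [run_psa()] result.
#' @param wtp_grid WTP values, USD/QALY.
#' @return Data frame `wtp, strategy, probability`; probabilities sum to one
#'   at every grid point.
#' @export
ceac <- function(samples, wtp_grid = default_wtp_grid()) {
  stopifnot(nrow(samples) >= 1)
  m <- psa_matrices(samples)
  out <- lapply(wtp_grid, function(w) {
    benefit <- w * m$qalys - m$cost
    best <- benefit >= apply(benefit, 1L, max) - 1e-9
    credit <- best / rowSums(best)
    data.frame(wtp = w, strategy = m$strategies,
               probability = colMeans(credit), stringsAsFactors = FALSE,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Incremental cost-effectiveness plane point cloud
#'
#' Per-draw incremental QALYs and costs of every strategy against a
#' reference.
#'
#' @param samples A [run_psa()] result.
#' @param reference Reference strategy code.
#' @return Data frame `draw, strategy, delta_qalys, delta_cost` (the
#'   reference itself is omitted).
#' @export
ce_plane <- function(samples, reference = "NO_TEST") {
  reference <- match.arg(reference, strategies())
  m <- psa_matrices(samples)
  if (!reference %in% m$strategies) {
    stop("reference strategy not present in the samples", call. = FALSE)
  }
  others <- setdiff(m$strategies, reference)
  out <- lapply(others, function(s) {
    data.frame(draw = seq_len(nrow(m$cost)), strategy = s,
               delta_qalys = m$qalys[, s] - m$qalys[, reference],
               delta_cost = m$cost[, s] - m$cost[, reference],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
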