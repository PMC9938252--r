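# Parameter table: schema, validation, IO and PSA distribution fitting.

PARAM_CATEGORIES <- c("probability", "rate", "cost", "utility", "disutility",
                      "relative_effect")
POPULATIONS <- c("TNBC_CN", "TNBC_US", "HER2NEG_CN", "HER2NEG_US")
PARAM_COLUMNS <- c("name", "category", "population", "base", "low", "high",
                   "distribution", "source_note")
DIST_FAMILIES <- c("beta", "gamma", "lognormal", "fixed")

# Default PSA family per category; "fixed" is always a legal override.
CATEGORY_DISTRIBUTION <- c(
  probability = "beta", utility = "beta", disutility = "beta",
  cost = "gamma", rate = "gamma", relative_effect = "lognormal"
)

#' Parameter names the decision model requires
#'
#' Every model run needs, for its population, a value for each of these
#' (either a population-specific row or an `ALL` row).
#'
#' @return Character vector of required parameter names.
#' @export
required_parameters <- function() {
  c(
    # decision-tree branch probabilities
    "prob_family_history", "prob_brca_given_fh", "prob_brca_given_no_fh",
    "prob_high_risk",
    # annual transition probabilities
    "prob_recurrence_locoregional", "prob_recurrence_second_primary",
    "prob_recurrence_distant", "prob_death_disease_free",
    "prob_death_recurrence",
    # relative effects on the recurrence hazard
    "rr_recurrence_olaparib", "rr_recurrence_olaparib_longterm",
    "rr_recurrence_rro", "rr_recurrence_undetected_carrier",
    # costs (2021 USD)
    "cost_brca_test", "cost_genetic_counselling", "cost_rro",
    "cost_olaparib_adjuvant", "cost_olaparib_recurrence",
    "cost_disease_free_annual", "cost_recurrence_annual",
    # utilities
    "utility_disease_free", "utility_recurrence",
    "utility_olaparib_recurrence_increment"
  )
}

#' Model settings
#'
#' Run-level settings of the cohort model. Defaults are the base-case design:
#' 1-year cycles, 20-year horizon, 3% annual discounting, cohort entry at age
#' 40, and willingness-to-pay thresholds of 31,500 USD/QALY for the Chinese
#' populations and 100,000 USD/QALY for the US populations.
#'
#' @param population One of `"TNBC_CN"`, `"TNBC_US"`, `"HER2NEG_CN"`,
#'   `"HER2NEG_US"`.
#' @param cycle_length Cycle length in years.
#' @param horizon Number of cycles.
#' @param discount_rate Annual discount rate in `[0, 1)`.
#' @param start_age Cohort age at model entry, years.
#' @param wtp Willingness-to-pay threshold, USD/QALY; defaults by country.
#' @param psa_draws Number of Monte-Carlo draws for the PSA.
#' @param rng_seed Integer seed recorded with stochastic outputs.
#' @return A list of class `model_settings`.
#' @export
model_settings <- function(population,
                           cycle_length = 1,
                           horizon = 20L,
                           discount_rate = 0.03,
                           start_age = 40,
                           wtp = NULL,
                           psa_draws = 1000L,
                           rng_seed = 1L) {
  population <- match.arg(population, POPULATIONS)
  if (is.null(wtp)) {
    wtp <- if (grepl("_CN$", population)) 31500 else 100000
  }
  stopifnot(horizon >= 1, cycle_length > 0, psa_draws >= 1)
  if (discount_rate < 0 || discount_rate >= 1) {
    stop("`discount_rate` must be in [0, 1)", call. = FALSE)
  }
  if (wtp <= 0) stop("`wtp` must be positive", call. = FALSE)
  structure(
    list(population = population, cycle_length = cycle_length,
         horizon = as.integer(horizon), discount_rate = discount_rate,
         start_age = start_age, wtp = wtp,
         psa_draws = as.integer(psa_draws), rng_seed = as.integer(rng_seed)),
    class = "model_settings"
  )
}

#' Construct a validated parameter set
#'
#' @param parameters Data frame with columns
#'   `name, category, population, base, low, high, distribution, source_note`
#'   and optionally `bound_type` (`"ci"` for a reported 95% CI, `"fallback"`
#'   for a base ∓10% range).
#' @param settings A [model_settings()] object.
#' @param check_complete Require all [required_parameters()] to be present
#'   for `settings$population`.
#' @return Object of class `parameter_set`: list with elements `parameters`
#'   (data frame) and `settings`.
#' @export
parameter_set <- function(parameters, settings, check_complete = TRUE) {
  stopifnot(inherits(settings, "model_settings"), is.data.frame(parameters))
  parameters <- as.data.frame(parameters, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PARAM_COLUMNS, names(parameters))
  if (length(missing_cols)) {
    stop("parameter table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"bound_type" %in% names(parameters)) parameters$bound_type <- NA_character_
  rownames(parameters) <- NULL
  validate_parameter_rows(parameters)
  ps <- structure(list(parameters = parameters, settings = settings),
                  class = "parameter_set")
  if (check_complete) {
    missing <- setdiff(required_parameters(), available_names(ps))
    if (length(missing)) {
      stop("parameter set incomplete for population ", settings$population,
           "; missing: ", paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  ps$values <- effective_values(ps)
  ps
}

# Named vector of effective base values (population rows override ALL);
# cached on the parameter_set so the engines avoid data-frame lookups.
effective_values <- function(ps) {
  nms <- available_names(ps)
  vapply(nms, function(n) param_row(ps, n)$base, numeric(1))
}

available_names <- function(ps) {
  p <- ps$parameters
  unique(p$name[p$population %in% c("ALL", ps$settings$population)])
}

validate_parameter_rows <- function(parameters) {
  bad <- function(cond, msg, rows) {
    if (any(cond)) {
      stop(msg, " (rows: ",
           paste(utils::head(which(cond), 5), collapse = ", "), "; names: ",
           paste(utils::head(parameters$name[cond], 5), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  bad(!parameters$category %in% PARAM_CATEGORIES, "unknown parameter category")
  bad(!parameters$population %in% c(POPULATIONS, "ALL"),
      "unknown population code")
  bad(!parameters$distribution %in% DIST_FAMILIES, "unknown distribution family")
  num <- c("base", "low", "high")
  for (col in num) {
    if (!is.numeric(parameters[[col]])) {
      stop("column `", col, "` must be numeric", call. = FALSE)
    }
    bad(!is.finite(parameters[[col]]), paste0("non-finite `", col, "`"))
  }
  bad(parameters$low > parameters$base | parameters$base > parameters$high,
      "bounds must satisfy low <= base <= high")
  is_prob <- parameters$category == "probability"
  bad(is_prob & (parameters$low < 0 | parameters$high > 1),
      "probability bounds must lie in [0, 1]")
  is_util <- parameters$category %in% c("utility", "disutility")
  bad(is_util & (parameters$low < 0 | parameters$high > 1),
      "utility bounds must lie in [0, 1]")
  bad(parameters$category == "cost" & parameters$low < 0,
      "cost bounds must be non-negative")
  # family must match category unless explicitly fixed
  expect <- unname(CATEGORY_DISTRIBUTION[parameters$category])
  bad(parameters$distribution != "fixed" & parameters$distribution != expect,
      "distribution family does not match category rule")
  dup <- duplicated(parameters[c("name", "population")])
  bad(dup, "duplicate (name, population) row")
  invisible(TRUE)
}

# The effective row for `name`: population-specific overrides ALL.
param_row <- function(ps, name) {
  p <- ps$parameters
  hit <- p[p$name == name & p$population == ps$settings$population, ]
  if (nrow(hit) == 0L) hit <- p[p$name == name & p$population == "ALL", ]
  if (nrow(hit) == 0L) {
    stop("parameter `", name, "` not found for population ",
         ps$settings$population, call. = FALSE)
  }
  hit[1L, ]
}

#' Look up a parameter's base value
#'
#' Population-specific rows override `ALL` rows.
#'
#' @param ps A [parameter_set()].
#' @param name Parameter name.
#' @return Base value (scalar).
#' @export
get_param <- function(ps, name) {
  v <- ps$values
  if (!is.null(v)) {
    hit <- v[name]
    if (!is.na(hit)) return(unname(hit))
  }
  param_row(ps, name)$base
}

#' Replace a parameter's base value
#'
#' Used by the sensitivity analyses: replaces `base` in the effective row for
#' the set's population (bounds are left untouched).
#'
#' @inheritParams get_param
#' @param value New base value.
#' @return A modified `parameter_set`.
#' @export
set_param_base <- function(ps, name, value) {
  p <- ps$parameters
  idx <- which(p$name == name & p$population == ps$settings$population)
  if (length(idx) == 0L) idx <- which(p$name == name & p$population == "ALL")
  if (length(idx) == 0L) {
    stop("parameter `", name, "` not found", call. = FALSE)
  }
  ps$parameters$base[idx[1L]] <- value
  if (!is.null(ps$values) && name %in% names(ps$values)) {
    # only update the cache if this row is the effective one
    eff <- param_row(ps, name)
    ps$values[[name]] <- eff$base
  }
  ps
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> ", nrow(x$parameters), " rows, population ",
      x$settings$population, ", horizon ", x$settings$horizon,
      " cycles, WTP ", format(x$settings$wtp, big.mark = ","),
      " USD/QALY\n", sep = "")
  invisible(x)
}

#' Read a parameter table from CSV
#'
#' The CSV must have a header `name,category,population,base,low,high,`
#' `distribution,source_note` (an optional `bound_type` column is honoured).
#' Model settings are taken from `settings`, from a JSON/YAML file via
#' `settings_path`, or default to [model_settings()] for the population.
#'
#' @param path Path to the parameter CSV.
#' @param population Population code the run is for.
#' @param settings Optional [model_settings()]; overrides `settings_path`.
#' @param settings_path Optional path to a YAML or JSON settings block.
#' @return A validated [parameter_set()].
#' @export
load_parameters <- function(path, population, settings = NULL,
                            settings_path = NULL) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  for (col in c("base", "low", "high")) {
    if (col %in% names(raw) && !is.numeric(raw[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[col]]))))
      stop("non-numeric `", col, "` at data line(s) ",
           paste(utils::head(bad, 5), collapse = ", "), " of ", path,
           call. = FALSE)
    }
  }
  if (is.null(settings)) {
    settings <- if (!is.null(settings_path)) {
      read_settings(settings_path, population)
    } else {
      model_settings(population)
    }
  }
  parameter_set(raw, settings)
}

#' Write a parameter set to CSV (and its settings to YAML)
#'
#' @param ps A [parameter_set()].
#' @param path Output CSV path.
#' @param settings_path Optional YAML path for the settings block.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(ps, path, settings_path = NULL) {
  stopifnot(inherits(ps, "parameter_set"))
  utils::write.csv(ps$parameters, path, row.names = FALSE, quote = TRUE)
  if (!is.null(settings_path)) {
    yaml::write_yaml(unclass(ps$settings), settings_path)
  }
  invisible(path)
}

#' Read model settings from a YAML or JSON file
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @param population Population code (used for defaults of missing fields).
#' @return A [model_settings()] object.
#' @export
read_settings <- function(path, population) {
  if (!file.exists(path)) stop("settings file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- model_settings(population)
  keep <- intersect(names(vals),
                    c("cycle_length", "horizon", "discount_rate", "start_age",
                      "wtp", "psa_draws", "rng_seed"))
  args <- utils::modifyList(
    unclass(defaults)[c("cycle_length", "horizon", "discount_rate",
                        "start_age", "wtp", "psa_draws", "rng_seed")],
    vals[keep]
  )
  do.call(model_settings, c(list(population = population), args))
}

# ---- PSA distribution fitting -----------------------------------------------

# SD for PSA sampling. A reported 95% CI gives (high-low)/3.92. Bounds that
# are just the +/-10% deterministic range fall back to the utility overrides
# (10% of base for the disease-free utility, 5% for recurrence-state
# utilities) or 10% of base otherwise.
param_sd <- function(row) {
  if (row$distribution == "fixed") return(0)
  if (row$low == row$high) return(0)
  bt <- row$bound_type
  if (is.null(bt) || is.na(bt) || !nzchar(bt)) {
    fallback_bounds <-
      isTRUE(all.equal(row$low, 0.9 * row$base, tolerance = 1e-6)) &&
      isTRUE(all.equal(row$high, 1.1 * row$base, tolerance = 1e-6))
    bt <- if (fallback_bounds) "fallback" else "ci"
  }
  if (bt == "ci") return((row$high - row$low) / 3.92)
  if (row$category %in% c("utility", "disutility")) {
    if (grepl("recurrence", row$name)) return(0.05 * row$base)
    return(0.10 * row$base)
  }
  0.10 * row$base
}

#' Fit a PSA sampling distribution to a parameter
#'
#' Method-of-moments fit of the family implied by the parameter's category:
#' beta for probabilities and utilities, gamma for costs and rates,
#' log-normal for relative effects. The SD comes from the 95% CI
#' (`(high - low)/3.92`) or, for ±10% fallback ranges, from the 10%/5%
#' utility overrides (10% of base otherwise).
#'
#' @param row A single parameter row (one-row data frame or list with fields
#'   `name, category, base, low, high, distribution`, optionally
#'   `bound_type`), e.g. from a [parameter_set()]'s `parameters`.
#' @return Object of class `psa_distribution`: list with `family`, the two
#'   shape parameters, and the implied `mean` and `sd`.
#' @export
fit_distribution <- function(row) {
  if (is.data.frame(row)) row <- as.list(row[1L, ])
  if (is.null(row$bound_type)) row$bound_type <- NA_character_
  m <- row$base
  s <- param_sd(row)
  family <- row$distribution
  make <- function(family, p1, p2, mean, sd) {
    structure(list(family = family, par1 = p1, par2 = p2,
                   mean = mean, sd = sd, name = row$name),
              class = "psa_distribution")
  }
  if (family == "fixed" || s == 0) {
    return(make("fixed", m, NA_real_, m, 0))
  }
  v <- s^2
  if (family == "beta") {
    if (m <= 0 || m >= 1 || v >= m * (1 - m)) {
      warning("beta fit infeasible for `", row$name,
              "` (mean ", signif(m, 4), ", sd ", signif(s, 4),
              "); falling back to a fixed point mass", call. = FALSE)
      return(make("fixed", m, NA_real_, m, 0))
    }
    alpha <- m * ((m * (1 - m)) / v - 1)
    beta <- alpha * (1 - m) / m
    return(make("beta", alpha, beta, m, s))
  }
  if (family == "gamma") {
    if (m <= 0) {
      warning("gamma fit needs a positive mean for `", row$name,
              "`; falling back to fixed", call. = FALSE)
      return(make("fixed", m, NA_real_, m, 0))
    }
    return(make("gamma", m^2 / v, v / m, m, s)) # shape, scale
  }
  if (family == "lognormal") {
    if (m <= 0) {
      warning("log-normal fit needs a positive mean for `", row$name,
              "`; falling back to fixed", call. = FALSE)
      return(make("fixed", m, NA_real_, m, 0))
    }
    sigma2 <- log(1 + v / m^2)
    mu <- log(m) - sigma2 / 2
    return(make("lognormal", mu, sqrt(sigma2), m, s))
  }
  stop("unknown distribution family: ", family, call. = FALSE)
}

#' Draw samples from a fitted PSA distribution
#'
#' @param dist A `psa_distribution` from [fit_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_distribution <- function(dist, n) {
  stopifnot(inherits(dist, "psa_distribution"))
  switch(dist$family,
    fixed = rep(dist$par1, n),
    beta = stats::rbeta(n, dist$par1, dist$par2),
    gamma = stats::rgamma(n, shape = dist$par1, scale = dist$par2),
    lognormal = stats::rlnorm(n, meanlog = dist$par1, sdlog = dist$par2),
    stop("unknown family", call. = FALSE)
  )
}

#' Analytic mean and SD of a fitted distribution
#'
#' @param dist A `psa_distribution`.
#' @return Named numeric vector `c(mean, sd)`.
#' @export
distribution_moments <- function(dist) {
  stopifnot(inherits(dist, "psa_distribution"))
  switch(dist$family,
    fixed = c(mean = dist$par1, sd = 0),
    beta = {
      a <- dist$par1; b <- dist$par2
      c(mean = a / (a + b),
        sd = sqrt(a * b / ((a + b)^2 * (a + b + 1))))
    },
    gamma = c(mean = dist$par1 * dist$par2,
              sd = sqrt(dist$par1) * dist$par2),
    lognormal = {
      m <- exp(dist$par1 + dist$par2^2 / 2)
      c(mean = m, sd = m * sqrt(exp(dist$par2^2) - 1))
    }
  )
}
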