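# Parameter table, model settings and life table: loading and validation.

PARAM_GROUPS <- c("progression", "death", "compliance", "accuracy",
                  "cost_screening", "cost_treatment", "utility")
PARAM_FAMILIES <- c("beta", "gamma", "fixed")

# Canonical parameter set of the bundled configuration; load_model() reports
# missing or unexpected names against this list unless check_names = FALSE.
CANONICAL_PARAMETERS <- c(
  "p_no_cancer_to_precancer", "p_precancer_to_I", "p_I_to_II", "p_II_to_III",
  "p_III_to_IV", "p_precancer_regression", "hr_treatment_progression",
  "p_precancer_cure", "p_ltfu_to_I",
  "p_death_I", "p_death_II", "p_death_III", "p_death_IV",
  "hr_no_treatment_death",
  "c_mse", "c_vetdn", "c_vetdt", "c_veos_precancer", "c_screen_cancer",
  "c_biopsy_screening",
  "selfref_no_cancer", "selfref_precancer", "selfref_early", "selfref_late",
  "c_biopsy_noscreening",
  "tc_precancer", "tc_I", "tc_II", "tc_III", "tc_IV",
  "sens_mse", "spec_mse", "sens_vetdn", "spec_vetdn", "sens_vetdt",
  "spec_vetdt", "sens_veos", "sens_gd", "spec_gd", "sens_veos_ns",
  "cost_management", "cost_mse", "cost_vetdn", "cost_vetdt", "cost_gd",
  "cost_veos", "cost_biopsy",
  "transport_vetdn", "transport_vetdt", "transport_veos",
  "prod_vetdn", "prod_vetdt", "prod_veos",
  "ct_med_precancer", "ct_med_I", "ct_med_II", "ct_med_III", "ct_med_IV",
  "ct_nonmed_precancer", "ct_nonmed_I", "ct_nonmed_II", "ct_nonmed_III",
  "ct_nonmed_IV",
  "u_precancer", "u_early", "u_late"
)

# Groups whose parameters are probabilities (support [0, 1]) even when fixed.
PROBABILITY_GROUPS <- c("compliance", "accuracy", "utility")
# Fixed parameters that are hazard ratios, not probabilities.
HAZARD_RATIO_PARAMS <- c("hr_treatment_progression", "hr_no_treatment_death")

#' Build a parameter table
#'
#' Assembles and validates a table of model parameters, each with a mean, an
#' optional standard error, a sampling-distribution family and a thematic
#' group.  Probabilities and utilities carry Beta distributions, costs carry
#' Gamma distributions, and parameters reported without a standard error are
#' `fixed`: held at their mean in probabilistic sensitivity analysis.
#'
#' @param df Data frame with columns `name`, `mean`, `se` (NA when absent),
#'   `family`, `group` and optionally `source`.
#' @return The validated data frame with class `os_parameter_table`.
#' @export
parameter_table <- function(df) {
  req <- c("name", "mean", "family", "group")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("parameter table lacks columns: ", paste(miss, collapse = ", "))
  }
  if (is.null(df$se)) df$se <- NA_real_
  if (is.null(df$source)) df$source <- ""
  df <- df[, c("name", "mean", "se", "family", "group", "source")]
  df$mean <- as.numeric(df$mean)
  df$se <- as.numeric(df$se)
  if (anyDuplicated(df$name)) {
    stop("duplicated parameter names: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  }
  bad <- character()
  for (i in seq_len(nrow(df))) {
    p <- df[i, ]
    ok <- tryCatch({
      validate_parameter_value(p)
      TRUE
    }, error = function(e) {
      bad <<- c(bad, conditionMessage(e))
      FALSE
    })
  }
  if (length(bad)) {
    stop("invalid parameters:\n  ", paste(bad, collapse = "\n  "))
  }
  class(df) <- c("os_parameter_table", "data.frame")
  df
}

validate_parameter_value <- function(p) {
  p <- as.list(p)
  nm <- p$name
  if (!p$family %in% PARAM_FAMILIES) {
    stop(sprintf("%s: unknown family '%s'", nm, p$family))
  }
  if (!p$group %in% PARAM_GROUPS) {
    stop(sprintf("%s: unknown group '%s'", nm, p$group))
  }
  if (!is.finite(p$mean)) stop(sprintf("%s: mean is not finite", nm))
  if (p$family == "beta") {
    if (p$mean <= 0 || p$mean >= 1) {
      stop(sprintf("%s: beta mean %g outside (0, 1)", nm, p$mean))
    }
  }
  if (p$family == "gamma" && p$mean <= 0) {
    stop(sprintf("%s: gamma mean %g not positive", nm, p$mean))
  }
  if (!is.na(p$se)) {
    if (p$se <= 0) stop(sprintf("%s: se %g not positive", nm, p$se))
    if (p$family == "beta" && p$se^2 >= p$mean * (1 - p$mean)) {
      stop(sprintf("%s: se^2 = %g exceeds Beta feasibility bound %g",
                   nm, p$se^2, p$mean * (1 - p$mean)))
    }
    if (p$family == "fixed") {
      stop(sprintf("%s: fixed parameters must not carry an se", nm))
    }
  } else if (p$family != "fixed") {
    stop(sprintf("%s: family '%s' requires an se", nm, p$family))
  }
  # fixed probabilities (compliance, accuracy, utilities) must stay in [0, 1]
  if (p$family == "fixed" && p$group %in% PROBABILITY_GROUPS &&
      !nm %in% HAZARD_RATIO_PARAMS) {
    if (p$mean < 0 || p$mean > 1) {
      stop(sprintf("%s: probability %g outside [0, 1]", nm, p$mean))
    }
  }
  if (p$family == "fixed" && p$group %in% c("progression", "death") &&
      !nm %in% HAZARD_RATIO_PARAMS) {
    if (p$mean < 0 || p$mean > 1) {
      stop(sprintf("%s: probability %g outside [0, 1]", nm, p$mean))
    }
  }
  invisible(TRUE)
}

#' Model settings
#'
#' Global settings of the cohort model: discounting, cycle length, cohort
#' age span, willingness-to-pay threshold and the utility anchors.
#'
#' @param discount_rate Annual discount rate applied to costs and QALYs.
#' @param cycle_length Cycle length in years.
#' @param start_age Cohort entry age in years.
#' @param max_age Age at which the simulation stops.
#' @param wtp_threshold Willingness-to-pay ceiling, THB per QALY.
#' @param healthy_utility Utility of the disease-free state.
#' @param death_utility Utility of death; must be 0.
#' @param currency Currency label (metadata).
#' @param usd_per_thb_2016 2016 exchange-rate metadata; never used in
#'   computation.
#' @return A list with class `os_settings`.
#' @export
os_settings <- function(discount_rate = 0.03, cycle_length = 1,
                        start_age = 40, max_age = 100,
                        wtp_threshold = 160000, healthy_utility = 1,
                        death_utility = 0, currency = "THB",
                        usd_per_thb_2016 = 34.62) {
  s <- list(discount_rate = discount_rate, cycle_length = cycle_length,
            start_age = start_age, max_age = max_age,
            wtp_threshold = wtp_threshold, healthy_utility = healthy_utility,
            death_utility = death_utility, currency = currency,
            usd_per_thb_2016 = usd_per_thb_2016)
  if (s$discount_rate < 0) stop("discount_rate must be >= 0")
  if (s$cycle_length <= 0) stop("cycle_length must be positive")
  if (s$start_age >= s$max_age) stop("start_age must be below max_age")
  if (s$death_utility != 0) stop("death_utility must be 0")
  if (s$healthy_utility < 0 || s$healthy_utility > 1) {
    stop("healthy_utility must lie in [0, 1]")
  }
  class(s) <- "os_settings"
  s
}

#' Load a life table
#'
#' Reads an age-specific annual death-probability table from a two-column
#' CSV (`age`, `qx`) and checks it covers the requested age span.
#'
#' @param path Path to the CSV file.
#' @param start_age,max_age Age span the table must cover.
#' @return Data frame with columns `age` and `qx`, class `os_life_table`.
#' @export
load_life_table <- function(path, start_age = 40, max_age = 100) {
  lt <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(lt))) {
    stop("life table must have columns 'age' and 'qx'")
  }
  lt <- lt[order(lt$age), c("age", "qx")]
  if (any(lt$qx < 0 | lt$qx > 1)) {
    stop("life-table death probabilities must lie in [0, 1]")
  }
  need <- seq(start_age, max_age)
  miss <- setdiff(need, lt$age)
  if (length(miss)) {
    stop("life table missing ages: ", paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ..." else "")
  }
  class(lt) <- c("os_life_table", "data.frame")
  lt
}

# qx lookup closure over a life table
life_table_fn <- function(lt) {
  qx <- lt$qx[match(seq(min(lt$age), max(lt$age)), lt$age)]
  a0 <- min(lt$age)
  function(age) qx[age - a0 + 1]
}

#' Path to the bundled default configuration
#' @return Path of the YAML configuration installed with the package.
#' @export
default_config <- function() {
  system.file("extdata", "default_config.yaml", package = "oralscreen",
              mustWork = TRUE)
}

#' Load a model configuration
#'
#' Reads a hierarchical YAML/JSON configuration with sections `settings`,
#' `options`, `parameters`, `life_table` and `cascades` into a validated
#' model object.  The bundled default transcribes the Thai oral precancer
#' screening programme evaluation: all transition probabilities, cascade
#' compliances and accuracies, 2016 THB costs and time-trade-off utilities.
#'
#' @param path Path to the configuration document; defaults to the bundled
#'   configuration.
#' @param check_names If `TRUE` (default), report parameters missing from or
#'   extra to the canonical set by name.
#' @return A list with components `params` (an `os_parameter_table`),
#'   `settings` (`os_settings`), `options`, `life_table` and `cascades`,
#'   with class `os_model`.
#' @export
load_model <- function(path = default_config(), check_names = TRUE) {
  cfg <- yaml::read_yaml(path)
  req <- c("settings", "parameters", "life_table", "cascades")
  miss <- setdiff(req, names(cfg))
  if (length(miss)) {
    stop("configuration missing sections: ", paste(miss, collapse = ", "))
  }
  req_settings <- c("discount_rate", "cycle_length", "start_age", "max_age",
                    "wtp_threshold")
  miss <- setdiff(req_settings, names(cfg$settings))
  if (length(miss)) {
    stop("settings missing keys: ", paste(miss, collapse = ", "))
  }
  settings <- do.call(os_settings, cfg$settings)

  opts <- cfg$options
  options <- list(
    hr_transform = opts$hr_transform %||% "rate",
    half_cycle_correction = isTRUE(opts$half_cycle_correction),
    ltfu_supplements_progression =
      if (is.null(opts$ltfu_supplements_progression)) TRUE
      else isTRUE(opts$ltfu_supplements_progression),
    precancer_cost_timing = opts$precancer_cost_timing %||% "annual",
    cancer_cost_timing = opts$cancer_cost_timing %||% "once",
    undetected_precancer_utility = opts$undetected_precancer_utility %||% "state",
    regression_timing = opts$regression_timing %||% "annual"
  )
  if (!options$regression_timing %in% c("annual", "at_onset")) {
    stop("options$regression_timing must be 'annual' or 'at_onset'")
  }
  if (!options$undetected_precancer_utility %in% c("state", "healthy")) {
    stop("options$undetected_precancer_utility must be 'state' or 'healthy'")
  }
  if (!options$hr_transform %in% c("rate", "multiplicative")) {
    stop("options$hr_transform must be 'rate' or 'multiplicative'")
  }

  pl <- cfg$parameters
  df <- data.frame(
    name = names(pl),
    mean = vapply(pl, function(x) as.numeric(x$mean), 0),
    se = vapply(pl, function(x) if (is.null(x$se)) NA_real_ else as.numeric(x$se), 0),
    family = vapply(pl, function(x) x$family %||% "fixed", ""),
    group = vapply(pl, function(x) x$group %||% "progression", ""),
    source = vapply(pl, function(x) x$source %||% "", ""),
    stringsAsFactors = FALSE
  )
  params <- parameter_table(df)

  if (check_names) {
    missing <- setdiff(CANONICAL_PARAMETERS, params$name)
    extra <- setdiff(params$name, CANONICAL_PARAMETERS)
    if (length(missing)) {
      stop("configuration missing parameters: ",
           paste(missing, collapse = ", "))
    }
    if (length(extra)) {
      warning("configuration has parameters outside the canonical set: ",
              paste(extra, collapse = ", "))
    }
  }

  lt_spec <- cfg$life_table
  lt <- if (is.character(lt_spec)) {
    lt_path <- if (file.exists(lt_spec)) lt_spec else
      file.path(dirname(path), lt_spec)
    load_life_table(lt_path, settings$start_age, settings$max_age)
  } else {
    df <- data.frame(age = as.integer(names(lt_spec)),
                     qx = as.numeric(unlist(lt_spec)))
    tf <- tempfile(fileext = ".csv")
    utils::write.csv(df, tf, row.names = FALSE)
    on.exit(unlink(tf))
    load_life_table(tf, settings$start_age, settings$max_age)
  }

  model <- list(params = params, settings = settings, options = options,
                life_table = lt, cascades = cfg$cascades)
  class(model) <- "os_model"
  validate_cascade_config(model$cascades)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parameter values as a named vector
#'
#' Extracts the point estimates (means) of every parameter, the vector the
#' deterministic model is evaluated at and the template each probabilistic
#' sensitivity draw perturbs.
#'
#' @param params An `os_parameter_table` or an `os_model`.
#' @return Named numeric vector of parameter means.
#' @export
param_values <- function(params) {
  if (inherits(params, "os_model")) params <- params$params
  stats::setNames(params$mean, params$name)
}

#' @export
print.os_model <- function(x, ...) {
  cat("Oral cancer screening cost-utility model\n")
  cat(sprintf("  %d parameters (%d distributed), ages %d-%d, discount %.1f%%\n",
              nrow(x$params), sum(x$params$family != "fixed"),
              x$settings$start_age, x$settings$max_age,
              100 * x$settings$discount_rate))
  cat(sprintf("  cascades: %s\n", paste(names(x$cascades), collapse = ", ")))
  invisible(x)
}
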