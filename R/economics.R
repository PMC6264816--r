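# Decision outputs: ICER, net monetary benefit, probabilistic sensitivity
# analysis with acceptability curves, one-way (tornado) and two-way
# sensitivity analyses, and programme-scenario comparison.

#' Lifetime discounted cost and QALYs of one strategy arm
#'
#' Runs the cohort for one arm and returns its discounted totals.
#'
#' @param model An `os_model`.
#' @param arm `"screening"` or `"no_screening"`.
#' @param theta Optional named parameter vector.
#' @param cascade_config Optional cascade override (programme scenarios).
#' @return Named vector `c(cost, qaly)`.
#' @export
run_arm <- function(model, arm = "screening", theta = NULL,
                    cascade_config = NULL) {
  accumulate(run_cohort(model, arm, theta = theta,
                        cascade_config = cascade_config))
}

#' Incremental cost-effectiveness ratio
#'
#' Compares an intervention (subscript 1) with a comparator (subscript 0):
#' the ICER is the incremental cost per incremental QALY.  When the
#' intervention is cheaper and more effective it dominates (no ratio is
#' reported); costlier and less effective, it is dominated; with equal
#' QALYs the ratio is undefined.
#'
#' @param cost1,qaly1 Lifetime discounted cost and QALYs of the
#'   intervention.
#' @param cost0,qaly0 Those of the comparator.
#' @return List with `delta_cost`, `delta_qaly`, `icer` (NA when flagged)
#'   and `dominance` (one of `"none"`, `"dominant"`, `"dominated"`,
#'   `"undefined"`).
#' @examples
#' icer(2765, 21.6233, 1403, 21.6189)
#' @export
icer <- function(cost1, qaly1, cost0, qaly0) {
  stopifnot(is.finite(c(cost1, qaly1, cost0, qaly0)))
  dc <- cost1 - cost0
  dq <- qaly1 - qaly0
  dominance <- if (dq == 0) "undefined"
    else if (dc < 0 && dq > 0) "dominant"
    else if (dc > 0 && dq < 0) "dominated"
    else "none"
  list(delta_cost = dc, delta_qaly = dq,
       icer = if (dominance == "none") dc / dq else NA_real_,
       dominance = dominance)
}

#' Net monetary benefit
#'
#' `threshold * qaly - cost`.  For positive incremental QALYs, a positive
#' incremental NMB is equivalent to the ICER lying below the threshold.
#'
#' @param cost Discounted cost (THB).
#' @param qaly Discounted QALYs.
#' @param threshold Willingness to pay, THB per QALY, non-negative.
#' @return NMB in THB.
#' @export
nmb <- function(cost, qaly, threshold) {
  if (any(threshold < 0)) stop("threshold must be non-negative")
  threshold * qaly - cost
}

#' Deterministic base-case comparison
#'
#' Runs both arms at the parameter means and reports lifetime discounted
#' costs, QALYs, increments and the ICER of screening versus no screening.
#'
#' @param model An `os_model`.
#' @param theta Optional named parameter vector.
#' @param cascade_config Optional screening-cascade override.
#' @return List with `screening`, `no_screening` (each `c(cost, qaly)`),
#'   the [icer()] components and the model's `threshold`.
#' @export
run_base_case <- function(model, theta = NULL, cascade_config = NULL) {
  scr <- run_arm(model, "screening", theta, cascade_config)
  ns <- run_arm(model, "no_screening", theta)
  res <- icer(scr[["cost"]], scr[["qaly"]], ns[["cost"]], ns[["qaly"]])
  c(list(screening = scr, no_screening = ns), res,
    list(threshold = model$settings$wtp_threshold))
}

# Sample one parameter vector: distributed parameters drawn from their
# moment-matched distributions, fixed parameters held at their means.
sample_theta <- function(params, theta0) {
  dist <- params[params$family != "fixed", ]
  draws <- vapply(seq_len(nrow(dist)),
                  function(i) sample_parameter(dist[i, ], 1), 0)
  theta0[dist$name] <- draws
  theta0
}

#' Probabilistic sensitivity analysis and acceptability curve
#'
#' Propagates parameter uncertainty through the model: each Monte-Carlo
#' draw samples every distributed parameter independently from its
#' moment-matched Beta or Gamma distribution (fixed parameters stay at
#' their means), re-runs both arms, and records lifetime discounted cost
#' and QALYs.  Draws whose sampled probabilities produce an infeasible
#' transition structure are rejected and redrawn (the count is reported).
#' The cost-effectiveness acceptability curve gives, for each
#' willingness-to-pay value, the fraction of draws in which screening has
#' positive incremental net monetary benefit.
#'
#' @param model An `os_model`.
#' @param n Number of retained draws (default 1000).
#' @param seed Integer seed; the full draw stream is reproducible.
#' @param lambda_grid Willingness-to-pay grid for the acceptability curve
#'   (default 0 to 500,000 THB/QALY in steps of 10,000).
#' @param cascade_config Optional screening-cascade override.
#' @return List with `draws` (data frame of per-draw parameter-free
#'   results), `ceac` (data frame `lambda`, `probability`), `n`, `seed` and
#'   `n_rejected`.
#' @export
run_psa <- function(model, n = 1000, seed = 1,
                    lambda_grid = seq(0, 5e5, by = 1e4),
                    cascade_config = NULL) {
  stopifnot(n >= 1)
  set.seed(seed)
  theta0 <- param_values(model)
  res <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("cost_screening", "qaly_screening",
                                        "cost_no_screening",
                                        "qaly_no_screening")))
  n_rejected <- 0L
  i <- 1L
  while (i <= n) {
    theta <- sample_theta(model$params, theta0)
    out <- tryCatch({
      scr <- run_arm(model, "screening", theta, cascade_config)
      ns <- run_arm(model, "no_screening", theta)
      c(scr[["cost"]], scr[["qaly"]], ns[["cost"]], ns[["qaly"]])
    }, error = function(e) NULL)
    if (is.null(out)) {
      n_rejected <- n_rejected + 1L
      if (n_rejected > 100L * n) stop("PSA rejection rate implausibly high")
      next
    }
    res[i, ] <- out
    i <- i + 1L
  }
  draws <- as.data.frame(res)
  dc <- draws$cost_screening - draws$cost_no_screening
  dq <- draws$qaly_screening - draws$qaly_no_screening
  ceac <- data.frame(
    lambda = lambda_grid,
    probability = vapply(lambda_grid, function(l) mean(l * dq - dc > 0), 0)
  )
  list(draws = draws, ceac = ceac, n = n, seed = seed,
       n_rejected = n_rejected)
}

#' Probability of cost-effectiveness at one threshold
#'
#' @param psa Result of [run_psa()].
#' @param threshold Willingness to pay, THB per QALY.
#' @return Fraction of draws with positive incremental net monetary
#'   benefit.
#' @export
ceac_at <- function(psa, threshold) {
  dc <- psa$draws$cost_screening - psa$draws$cost_no_screening
  dq <- psa$draws$qaly_screening - psa$draws$qaly_no_screening
  mean(threshold * dq - dc > 0)
}

#' One-way sensitivity analysis of a single parameter
#'
#' Re-runs the deterministic model with one parameter set to the bounds of
#' its moment-matched confidence interval (all other parameters at their
#' means) and reports the ICER at each bound.  Fixed parameters can be
#' varied only by supplying explicit `bounds`.
#'
#' @param model An `os_model`.
#' @param parameter Parameter name.
#' @param level Confidence level for the default bounds (default 0.95).
#' @param bounds Optional explicit `c(low, high)` override.
#' @return Data frame with the parameter, its low/high values and
#'   `icer_low`, `icer_high`.
#' @export
one_way <- function(model, parameter, level = 0.95, bounds = NULL) {
  p <- model$params[model$params$name == parameter, ]
  if (!nrow(p)) stop("unknown parameter '", parameter, "'")
  if (is.null(bounds)) {
    bounds <- confidence_bounds(p, level)
  } else if (length(bounds) != 2 || bounds[1] >= bounds[2]) {
    stop("bounds must be c(low, high) with low < high")
  }
  theta0 <- param_values(model)
  icer_at <- function(v) {
    th <- theta0
    th[[parameter]] <- v
    run_base_case(model, theta = th)$icer
  }
  data.frame(parameter = parameter, low = bounds[[1]], high = bounds[[2]],
             icer_low = icer_at(bounds[[1]]), icer_high = icer_at(bounds[[2]]),
             row.names = NULL)
}

#' Tornado analysis over all distributed parameters
#'
#' Runs [one_way()] for every parameter carrying a sampling distribution
#' and sorts the results by the width of the induced ICER range, the
#' ordering of a tornado diagram.
#'
#' @param model An `os_model`.
#' @param level Confidence level of the ranges (default 0.95).
#' @return Data frame of one-way results with a `range` column, widest
#'   first, plus the base-case ICER as attribute `icer_base`.
#' @export
tornado <- function(model, level = 0.95) {
  base <- run_base_case(model)$icer
  dist <- model$params$name[model$params$family != "fixed"]
  rows <- lapply(dist, function(nm) one_way(model, nm, level))
  out <- do.call(rbind, rows)
  out$range <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$range), ]
  rownames(out) <- NULL
  attr(out, "icer_base") <- base
  out
}

#' Two-way sensitivity analysis
#'
#' Evaluates the deterministic ICER while two parameters move together.
#' In `"grid"` mode both parameters sweep a relative grid around their
#' base values (default -20% to +20% in 5% steps).  In `"paired"` mode the
#' sensitivity and specificity of one screening step are set to a common
#' value over `values`, the construction behind accuracy-threshold
#' statements such as "the programme becomes cost-effective once MSE
#' sensitivity and specificity reach 60%"; the crossing of the
#' willingness-to-pay contour is interpolated from the sweep.
#'
#' @param model An `os_model`.
#' @param param_a In grid mode, first parameter name; in paired mode, the
#'   step name (`"mse"`, `"vetdn"`, `"vetdt"`) whose `sens_*`/`spec_*`
#'   parameters are paired.
#' @param param_b Second parameter name (grid mode only).
#' @param mode `"grid"` or `"paired"`.
#' @param rel Relative offsets for grid mode.
#' @param values Common accuracy values for paired mode.
#' @param threshold Willingness-to-pay contour level (defaults to the model
#'   setting).
#' @return Grid mode: list with `surface` (data frame `value_a`, `value_b`,
#'   `icer`) and `contour` (surface rows nearest the threshold).  Paired
#'   mode: list with `sweep` (data frame `value`, `icer`) and `crossing`,
#'   the interpolated common accuracy at which the ICER equals the
#'   threshold (NA if not crossed).
#' @export
two_way <- function(model, param_a, param_b = NULL,
                    mode = c("grid", "paired"),
                    rel = seq(-0.2, 0.2, by = 0.05),
                    values = seq(0.30, 0.95, by = 0.05),
                    threshold = NULL) {
  mode <- match.arg(mode)
  if (is.null(threshold)) threshold <- model$settings$wtp_threshold
  theta0 <- param_values(model)
  if (mode == "grid") {
    if (is.null(param_b)) stop("grid mode needs two parameter names")
    if (!length(rel)) stop("empty grid")
    for (nm in c(param_a, param_b)) {
      if (!nm %in% names(theta0)) stop("unknown parameter '", nm, "'")
    }
    grid <- expand.grid(value_a = theta0[[param_a]] * (1 + rel),
                        value_b = theta0[[param_b]] * (1 + rel))
    grid$icer <- vapply(seq_len(nrow(grid)), function(i) {
      th <- theta0
      th[[param_a]] <- grid$value_a[i]
      th[[param_b]] <- grid$value_b[i]
      run_base_case(model, theta = th)$icer
    }, 0)
    near <- grid[order(abs(grid$icer - threshold)), ]
    list(surface = grid,
         contour = utils::head(near[is.finite(near$icer), ], 5))
  } else {
    sens <- paste0("sens_", param_a)
    spec <- paste0("spec_", param_a)
    for (nm in c(sens, spec)) {
      if (!nm %in% names(theta0)) {
        stop("no paired accuracy parameters for step '", param_a, "'")
      }
    }
    if (!length(values)) stop("empty grid")
    sweep <- data.frame(value = values)
    sweep$icer <- vapply(values, function(v) {
      th <- theta0
      th[[sens]] <- v
      th[[spec]] <- v
      run_base_case(model, theta = th)$icer
    }, 0)
    cross <- NA_real_
    f <- sweep$icer - threshold
    sgn <- which(diff(sign(f)) != 0)
    if (length(sgn)) {
      i <- sgn[1]
      cross <- sweep$value[i] +
        (sweep$value[i + 1] - sweep$value[i]) * (-f[i]) / (f[i + 1] - f[i])
    }
    list(sweep = sweep, crossing = cross, threshold = threshold)
  }
}

#' Compare the four programme scenarios
#'
#' Evaluates the screening programme under scenarios A (full cascade), B
#' (MSE removed), C (MSE and VETDN removed) and D (VETDN removed), each
#' against the common no-screening comparator.
#'
#' @param model An `os_model`.
#' @param theta Optional named parameter vector.
#' @return Data frame with one row per scenario: steps, lifetime cost,
#'   QALYs, increments and ICER versus no screening.
#' @export
run_scenarios <- function(model, theta = NULL) {
  ns <- run_arm(model, "no_screening", theta)
  rows <- lapply(c("A", "B", "C", "D"), function(id) {
    cc <- scenario_cascade(model, id)
    scr <- run_arm(model, "screening", theta, cascade_config = cc)
    r <- icer(scr[["cost"]], scr[["qaly"]], ns[["cost"]], ns[["qaly"]])
    data.frame(scenario = id,
               steps = paste(vapply(cc$steps, function(s) s$name, ""),
                             collapse = "+"),
               cost = scr[["cost"]], qaly = scr[["qaly"]],
               delta_cost = r$delta_cost, delta_qaly = r$delta_qaly,
               icer = r$icer, row.names = NULL)
  })
  do.call(rbind, rows)
}
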