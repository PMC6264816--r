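# Markov cohort engine: disease states expanded by treatment status, yearly
# transition dynamics, cohort trace and discounted accumulation.

CANCER_STAGES <- c("stage_I", "stage_II", "stage_III", "stage_IV")
TREATMENT_STATUS <- c("undetected", "on_treatment", "detected_untreated")

MODEL_STATES <- c(
  "no_cancer",
  paste("precancer", TREATMENT_STATUS, sep = "_"),
  as.vector(t(outer(CANCER_STAGES, TREATMENT_STATUS, paste, sep = "_"))),
  "death"
)

state_index <- function(state) match(state, MODEL_STATES)

#' Hazard-ratio adjustment of a per-cycle probability
#'
#' Converts a per-cycle event probability under one hazard to the
#' probability under a proportionally scaled hazard: with the default
#' rate-based transform, `p' = 1 - (1 - p)^hr`, which keeps probabilities in
#' `[0, 1)` and composes multiplicatively in the hazard ratio.  A
#' multiplicative variant (`p' = min(p * hr, 1)`) is available for
#' calibration comparisons.
#'
#' @param p Per-cycle probability in `[0, 1]`.
#' @param hr Hazard ratio, positive.
#' @param method `"rate"` (default) or `"multiplicative"`.
#' @return Adjusted per-cycle probability.  `p = 1` saturates at 1 for any
#'   hazard ratio.
#' @examples
#' hr_adjust(0.53, 0.5)  # treated progression, about 0.314
#' hr_adjust(0.20, 2)    # untreated death, 0.36
#' @export
hr_adjust <- function(p, hr, method = c("rate", "multiplicative")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (any(hr <= 0)) stop("hazard ratio must be positive")
  if (method == "rate") 1 - (1 - p)^hr else pmin(p * hr, 1)
}

# Internal: assemble the full transition matrix pieces for one arm.
# `det` is a named vector of per-cycle confirmed-detection probabilities by
# health state (from cascade_outcomes).  Returns the age-independent matrix
# plus a filler for the age-dependent rows (no_cancer and precancer, whose
# background mortality comes from the life table).
tm_template <- function(theta, det, options) {
  n <- length(MODEL_STATES)
  M <- matrix(0, n, n, dimnames = list(MODEL_STATES, MODEL_STATES))
  hrm <- options$hr_transform
  g <- function(nm) unname(theta[[nm]])
  idx <- state_index

  p_prog <- c(stage_I = g("p_I_to_II"), stage_II = g("p_II_to_III"),
              stage_III = g("p_III_to_IV"), stage_IV = 0)
  p_die_tr <- c(stage_I = g("p_death_I"), stage_II = g("p_death_II"),
                stage_III = g("p_death_III"), stage_IV = g("p_death_IV"))
  tc <- c(stage_I = g("tc_I"), stage_II = g("tc_II"),
          stage_III = g("tc_III"), stage_IV = g("tc_IV"))
  hr_pr <- g("hr_treatment_progression")
  hr_d <- g("hr_no_treatment_death")

  for (k in seq_along(CANCER_STAGES)) {
    st <- CANCER_STAGES[k]
    nxt <- if (k < 4) CANCER_STAGES[k + 1] else NA
    p_u <- p_prog[[st]]                       # untreated progression
    p_t <- hr_adjust(p_u, hr_pr, hrm)         # on-treatment progression
    q_t <- p_die_tr[[st]]                     # treated death
    q_u <- hr_adjust(q_t, hr_d, hrm)          # untreated death
    d <- det[[st]]
    tck <- tc[[st]]

    # undetected: death, then detection routing, then progression under the
    # post-detection status
    r <- idx(paste0(st, "_undetected"))
    s <- 1 - q_u
    b_tr <- s * d * tck
    b_du <- s * d * (1 - tck)
    b_un <- s * (1 - d)
    M[r, idx("death")] <- q_u
    if (!is.na(nxt)) {
      M[r, idx(paste0(nxt, "_on_treatment"))] <- b_tr * p_t
      M[r, idx(paste0(nxt, "_detected_untreated"))] <- b_du * p_u
      M[r, idx(paste0(nxt, "_undetected"))] <- b_un * p_u
    }
    M[r, idx(paste0(st, "_on_treatment"))] <-
      M[r, idx(paste0(st, "_on_treatment"))] + b_tr * (1 - p_t)
    M[r, idx(paste0(st, "_detected_untreated"))] <- b_du * (1 - p_u)
    M[r, idx(paste0(st, "_undetected"))] <- b_un * (1 - p_u)

    # on treatment: halved progression hazard, treated mortality
    r <- idx(paste0(st, "_on_treatment"))
    M[r, idx("death")] <- q_t
    if (!is.na(nxt)) M[r, idx(paste0(nxt, "_on_treatment"))] <- (1 - q_t) * p_t
    M[r, r] <- (1 - q_t) * (1 - if (is.na(nxt)) 0 else p_t)

    # detected but refused treatment: untreated dynamics, no re-screening
    r <- idx(paste0(st, "_detected_untreated"))
    M[r, idx("death")] <- q_u
    if (!is.na(nxt)) M[r, idx(paste0(nxt, "_detected_untreated"))] <- (1 - q_u) * p_u
    M[r, r] <- (1 - q_u) * (1 - if (is.na(nxt)) 0 else p_u)
  }
  M[idx("death"), idx("death")] <- 1

  # precancer branch probabilities (age-independent part)
  p_inc <- g("p_no_cancer_to_precancer")
  p_pc1 <- g("p_precancer_to_I")
  regr <- g("p_precancer_regression")
  # lesion-level regression: the regressing fraction of incident lesions
  # resolves at onset and never enters the persistent precancer pool,
  # instead of an annual regression probability from the precancer state
  if (identical(options$regression_timing, "at_onset")) {
    p_inc <- p_inc * (1 - regr)
    regr <- 0
  }
  cure <- g("p_precancer_cure")
  ltfu <- g("p_ltfu_to_I")
  p_pc_tr <- hr_adjust(p_pc1, hr_pr, hrm)
  if (!options$ltfu_supplements_progression) p_pc_tr <- 0
  d_pc <- det[["precancer"]]
  tc_pc <- g("tc_precancer")
  if (cure + p_pc_tr + ltfu > 1) {
    stop("precancer on-treatment exits exceed 1 (cure ", cure,
         " + progression ", p_pc_tr, " + loss to follow-up ", ltfu, ")")
  }
  if (p_pc1 + regr > 1) {
    stop("untreated precancer exits exceed 1 (progression ", p_pc1,
         " + regression ", regr, ")")
  }
  if (p_inc < 0 || p_inc > 1) stop("incidence probability outside [0, 1]")

  fill_age <- function(M, qx) {
    idx <- state_index
    s <- 1 - qx
    r <- idx("no_cancer")
    M[r, ] <- 0
    M[r, idx("death")] <- qx
    M[r, idx("precancer_undetected")] <- s * p_inc
    M[r, r] <- s * (1 - p_inc)

    r <- idx("precancer_undetected")
    M[r, ] <- 0
    b_tr <- s * d_pc * tc_pc
    b_du <- s * d_pc * (1 - tc_pc)
    b_un <- s * (1 - d_pc)
    M[r, idx("death")] <- qx
    M[r, idx("no_cancer")] <- b_tr * cure + (b_du + b_un) * regr
    M[r, idx("stage_I_on_treatment")] <- b_tr * p_pc_tr
    M[r, idx("stage_I_undetected")] <- b_tr * ltfu + b_un * p_pc1
    M[r, idx("stage_I_detected_untreated")] <- b_du * p_pc1
    M[r, idx("precancer_on_treatment")] <- b_tr * (1 - cure - p_pc_tr - ltfu)
    M[r, idx("precancer_detected_untreated")] <- b_du * (1 - p_pc1 - regr)
    M[r, r] <- b_un * (1 - p_pc1 - regr)

    r <- idx("precancer_on_treatment")
    M[r, ] <- 0
    M[r, idx("death")] <- qx
    M[r, idx("no_cancer")] <- s * cure
    M[r, idx("stage_I_on_treatment")] <- s * p_pc_tr
    M[r, idx("stage_I_undetected")] <- s * ltfu
    M[r, r] <- s * (1 - cure - p_pc_tr - ltfu)

    r <- idx("precancer_detected_untreated")
    M[r, ] <- 0
    M[r, idx("death")] <- qx
    M[r, idx("no_cancer")] <- s * regr
    M[r, idx("stage_I_detected_untreated")] <- s * p_pc1
    M[r, r] <- s * (1 - p_pc1 - regr)
    M
  }

  list(M = M, fill_age = fill_age)
}

#' Build the transition matrix for one age and arm
#'
#' Assembles the per-cycle transition matrix over the expanded state space
#' (disease state crossed with treatment status, plus death).  The event
#' order within a cycle is: (1) death — background mortality from the life
#' table for no-cancer and precancer, stage-specific all-cause mortality
#' within invasive cancer; (2) confirmed detection with the cascade's
#' per-state probability, routed to treatment by treatment compliance;
#' (3) progression and regression with probabilities matching the
#' post-detection treatment status (hazard-ratio-halved progression on
#' treatment, regression 0.30 untreated, cure 0.58 on treatment, and a 0.01
#' loss-to-follow-up progression from treated precancer to stage I).
#'
#' @param model An `os_model`.
#' @param age Age in years (must be covered by the life table).
#' @param arm `"screening"` or `"no_screening"`.
#' @param theta Optional named parameter vector (defaults to model means).
#' @param det Optional named vector of per-state detection probabilities;
#'   computed from the arm's cascade when omitted.
#' @return Row-stochastic matrix over the model states.
#' @export
build_transition_matrix <- function(model, age, arm = "screening",
                                    theta = NULL, det = NULL) {
  if (is.null(theta)) theta <- param_values(model)
  if (is.null(det)) {
    casc <- build_cascade(model$cascades[[arm]], theta)
    out <- cascade_outcomes(casc)
    det <- stats::setNames(out$p_confirmed, out$state)
  }
  tmpl <- tm_template(theta, det, model$options)
  qx <- life_table_fn(model$life_table)(age)
  if (is.na(qx)) stop("life table does not cover age ", age)
  M <- tmpl$fill_age(tmpl$M, qx)
  check_stochastic(M, age)
  M
}

check_stochastic <- function(M, age = NA) {
  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-10) || any(M < -1e-12)) {
    bad <- MODEL_STATES[which.max(abs(rs - 1))]
    stop("transition matrix not row-stochastic at state '", bad, "'",
         if (!is.na(age)) paste0(" (age ", age, ")") else "")
  }
  invisible(TRUE)
}

#' Run the cohort model for one arm
#'
#' Simulates a closed cohort entering disease-free at the start age and
#' followed in yearly cycles until the maximum age.  Per cycle the trace
#' records state occupancy, screening costs (cascade expected cost times the
#' occupancy of screenable states: disease-free and undetected), treatment
#' costs (stage episode costs charged on entry to treatment, precancer
#' follow-up charged per treated year) and utility-weighted life years.
#'
#' @param model An `os_model`.
#' @param arm `"screening"` or `"no_screening"`.
#' @param theta Optional named parameter vector (defaults to model means).
#' @param cascade_config Optional cascade configuration overriding the arm's
#'   default (used for programme scenarios).
#' @return An `os_trace`: list with `occupancy` (cycles+1 by states matrix),
#'   `ages`, per-cycle `cost_screening`, `cost_treatment`, `qaly`
#'   (undiscounted), and the evaluated `cascade_outcomes`.
#' @export
run_cohort <- function(model, arm = c("screening", "no_screening"),
                       theta = NULL, cascade_config = NULL) {
  arm <- match.arg(arm)
  if (is.null(theta)) theta <- param_values(model)
  st <- model$settings
  if (is.null(cascade_config)) cascade_config <- model$cascades[[arm]]
  casc <- build_cascade(cascade_config, theta)
  cout <- cascade_outcomes(casc)
  det <- stats::setNames(cout$p_confirmed, cout$state)
  scost <- stats::setNames(cout$expected_cost, cout$state)

  tmpl <- tm_template(theta, det, model$options)
  qx_at <- life_table_fn(model$life_table)

  n_cycles <- floor((st$max_age - st$start_age) / st$cycle_length)
  n <- length(MODEL_STATES)
  occ <- matrix(0, n_cycles + 1, n, dimnames = list(NULL, MODEL_STATES))
  occ[1, "no_cancer"] <- 1

  u <- state_utilities(theta, st, model$options)
  screen_cost_vec <- stats::setNames(numeric(n), MODEL_STATES)
  screen_cost_vec["no_cancer"] <- scost[["no_cancer"]]
  screen_cost_vec["precancer_undetected"] <- scost[["precancer"]]
  for (stg in CANCER_STAGES) {
    screen_cost_vec[paste0(stg, "_undetected")] <- scost[[stg]]
  }
  ct_stage <- c(
    stage_I = unname(theta[["ct_med_I"]] + theta[["ct_nonmed_I"]]),
    stage_II = unname(theta[["ct_med_II"]] + theta[["ct_nonmed_II"]]),
    stage_III = unname(theta[["ct_med_III"]] + theta[["ct_nonmed_III"]]),
    stage_IV = unname(theta[["ct_med_IV"]] + theta[["ct_nonmed_IV"]])
  )
  ct_pc <- unname(theta[["ct_med_precancer"]] + theta[["ct_nonmed_precancer"]])
  on_idx <- state_index(paste0(CANCER_STAGES, "_on_treatment"))
  pc_on <- state_index("precancer_on_treatment")

  cost_screening <- cost_treatment <- qaly <- numeric(n_cycles)
  v <- occ[1, ]
  for (t in seq_len(n_cycles)) {
    age <- st$start_age + (t - 1) * st$cycle_length
    M <- tmpl$fill_age(tmpl$M, qx_at(age))
    check_stochastic(M, age)
    w <- as.vector(v %*% M)

    cost_screening[t] <- sum(v * screen_cost_vec)
    inflow_on <- w[on_idx] - v[on_idx] * M[cbind(on_idx, on_idx)]
    ct <- if (model$options$cancer_cost_timing == "once") {
      sum(inflow_on * ct_stage)
    } else {
      sum(w[on_idx] * ct_stage)
    }
    ct <- ct + if (model$options$precancer_cost_timing == "annual") {
      v[pc_on] * ct_pc
    } else {
      (w[pc_on] - v[pc_on] * M[pc_on, pc_on]) * ct_pc
    }
    cost_treatment[t] <- ct
    qaly[t] <- if (model$options$half_cycle_correction) {
      sum((v + w) / 2 * u) * st$cycle_length
    } else {
      sum(v * u) * st$cycle_length
    }
    occ[t + 1, ] <- w
    v <- w
  }
  structure(list(occupancy = occ,
                 ages = st$start_age + (0:n_cycles) * st$cycle_length,
                 cost_screening = cost_screening,
                 cost_treatment = cost_treatment,
                 qaly = qaly, arm = arm, cascade_outcomes = cout,
                 settings = st),
            class = "os_trace")
}

# Utility weight of every model state.  The precancer utility was elicited
# from diagnosed patients; whether an undetected asymptomatic lesion carries
# it or the healthy utility is a configurable structural choice.
state_utilities <- function(theta, settings, options = NULL) {
  u <- stats::setNames(numeric(length(MODEL_STATES)), MODEL_STATES)
  u["no_cancer"] <- settings$healthy_utility
  u[grep("^precancer", MODEL_STATES)] <- theta[["u_precancer"]]
  if (!is.null(options) &&
      identical(options$undetected_precancer_utility, "healthy")) {
    u["precancer_undetected"] <- settings$healthy_utility
  }
  u[grep("^stage_(I|II)_", MODEL_STATES)] <- theta[["u_early"]]
  u[grep("^stage_(III|IV)_", MODEL_STATES)] <- theta[["u_late"]]
  u["death"] <- settings$death_utility
  u
}

#' Discounted totals of a cohort trace
#'
#' Sums the per-cycle cost and QALY streams of a trace with annual
#' discounting: cycle `t` (0-based, the entry cycle undiscounted) is
#' weighted by `1 / (1 + r)^t`.
#'
#' @param trace An `os_trace` from [run_cohort()].
#' @param settings Optional `os_settings` (defaults to those stored in the
#'   trace).
#' @return Named vector `c(cost, qaly)`: lifetime discounted cost (THB) and
#'   QALYs.
#' @export
accumulate <- function(trace, settings = NULL) {
  if (is.null(settings)) settings <- trace$settings
  r <- settings$discount_rate
  tvec <- seq_along(trace$qaly) - 1
  disc <- 1 / (1 + r)^(tvec * settings$cycle_length)
  c(cost = sum((trace$cost_screening + trace$cost_treatment) * disc),
    qaly = sum(trace$qaly * disc))
}

#' Survival curve of a stage-entry subcohort
#'
#' Survival, by years since entry, of the subcohort entering a given cancer
#' stage with a given treatment status.  Because stage dynamics do not
#' depend on age in this model, the curve is independent of when the
#' subcohort entered; it is computed by forward iteration of the
#' cancer-stage transition rows.
#'
#' @param model An `os_model`.
#' @param from_state Entry stage, `"stage_I"` through `"stage_IV"`.
#' @param status Treatment status at entry (default `"on_treatment"`).
#' @param years Number of yearly points after entry.
#' @param arm Arm whose detection probabilities drive later transitions.
#' @param theta Optional parameter vector.
#' @return Numeric vector of length `years + 1`, starting at 1 and
#'   non-increasing.
#' @export
survival_curve <- function(model, from_state, status = "on_treatment",
                           years = 10, arm = "no_screening", theta = NULL) {
  if (!from_state %in% CANCER_STAGES) {
    stop("from_state must be a cancer stage")
  }
  if (is.null(theta)) theta <- param_values(model)
  casc <- build_cascade(model$cascades[[arm]], theta)
  cout <- cascade_outcomes(casc)
  det <- stats::setNames(cout$p_confirmed, cout$state)
  M <- tm_template(theta, det, model$options)$M
  keep <- c(as.vector(t(outer(CANCER_STAGES, TREATMENT_STATUS, paste, sep = "_"))),
            "death")
  M <- M[keep, keep]
  v <- stats::setNames(numeric(length(keep)), keep)
  entry <- paste(from_state, status, sep = "_")
  v[entry] <- 1
  surv <- numeric(years + 1)
  surv[1] <- 1
  for (t in seq_len(years)) {
    v <- as.vector(v %*% M)
    names(v) <- keep
    surv[t + 1] <- 1 - v[["death"]]
  }
  surv
}
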