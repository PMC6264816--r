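# Screening-cascade evaluation: probability of confirmed diagnosis and
# expected cost per person per cycle, for ordered sequences of imperfect,
# imperfectly attended tests followed by biopsy confirmation.

HEALTH_STATES <- c("no_cancer", "precancer",
                   "stage_I", "stage_II", "stage_III", "stage_IV")

# Compliance/accuracy class of a health state within a cascade.
state_class <- function(state) {
  switch(state,
    no_cancer = "no_cancer",
    precancer = "precancer",
    stage_I = , stage_II = "cancer_early",
    stage_III = , stage_IV = "cancer_late",
    stop("unknown health state '", state, "'")
  )
}

validate_cascade_config <- function(cascades) {
  for (arm in names(cascades)) {
    cc <- cascades[[arm]]
    if (is.null(cc$steps) || !length(cc$steps)) {
      stop("cascade '", arm, "' has no steps")
    }
    step_names <- vapply(cc$steps, function(s) s$name, "")
    conf <- cc$confirmation$no_cancer
    if (is.null(conf) || !conf %in% step_names) {
      stop("cascade '", arm, "': confirmation step for no_cancer ('",
           conf %||% "<missing>", "') is not among its steps")
    }
    if (is.null(cc$biopsy$compliance) || is.null(cc$biopsy$cost)) {
      stop("cascade '", arm, "' lacks a biopsy definition")
    }
  }
  invisible(TRUE)
}

# Resolve a config entry that is either a literal number or a parameter name.
resolve_value <- function(x, theta, where) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.character(x)) {
    if (!x %in% names(theta)) {
      stop("cascade references unknown parameter '", x, "' in ", where)
    }
    return(unname(theta[[x]]))
  }
  stop("cannot resolve cascade value in ", where)
}

#' Build a concrete cascade from a configuration and parameter values
#'
#' Resolves every parameter reference in a cascade configuration against a
#' named vector of parameter values, producing the numeric cascade that
#' [evaluate_cascade()] consumes.  Sensitivity for invasive cancer stages is
#' taken as 1 at every step (oral cancer lesions are assumed never to be
#' missed once a person attends).
#'
#' @param cascade_config One entry of the `cascades` configuration section.
#' @param theta Named numeric vector of parameter values, see
#'   [param_values()].
#' @return A list with components `steps`, `biopsy`, `confirmation_index`
#'   and `management_cost`, class `os_cascade`.
#' @export
build_cascade <- function(cascade_config, theta) {
  cc <- cascade_config
  step_names <- vapply(cc$steps, function(s) s$name, "")
  steps <- lapply(cc$steps, function(s) {
    w <- paste0("step '", s$name, "'")
    comp <- s$compliance
    need <- c("no_cancer", "precancer", "cancer_early", "cancer_late")
    miss <- setdiff(need, names(comp))
    if (length(miss)) {
      stop(w, ": missing compliance for state class(es) ",
           paste(miss, collapse = ", "))
    }
    list(
      name = s$name,
      sens_precancer = resolve_value(s$sens_precancer, theta, w),
      sens_cancer = resolve_value(s$sens_cancer %||% 1, theta, w),
      spec = resolve_value(s$spec %||% 1, theta, w),
      compliance = vapply(need, function(k) resolve_value(comp[[k]], theta, w), 0),
      cost = resolve_value(s$cost$direct %||% 0, theta, w) +
        resolve_value(s$cost$transport %||% 0, theta, w) +
        resolve_value(s$cost$productivity %||% 0, theta, w)
    )
  })
  out <- list(
    steps = steps,
    step_names = step_names,
    biopsy = list(
      compliance = resolve_value(cc$biopsy$compliance, theta, "biopsy"),
      cost = resolve_value(cc$biopsy$cost, theta, "biopsy")
    ),
    confirmation_index = match(cc$confirmation$no_cancer, step_names),
    fp_workup = cc$fp_workup %||% "release",
    management_cost = resolve_value(cc$management_cost %||% 0, theta,
                                    "management cost"),
    management_as_fraction = isTRUE(cc$management_as_fraction)
  )
  if (!out$fp_workup %in% c("release", "full")) {
    stop("fp_workup must be 'release' or 'full'")
  }
  for (s in out$steps) {
    vals <- c(s$sens_precancer, s$sens_cancer, s$spec, s$compliance)
    if (any(vals < 0 | vals > 1)) {
      stop("step '", s$name, "': probabilities must lie in [0, 1]")
    }
    if (s$cost < 0) stop("step '", s$name, "': negative cost")
  }
  if (out$biopsy$compliance < 0 || out$biopsy$compliance > 1) {
    stop("biopsy compliance must lie in [0, 1]")
  }
  class(out) <- "os_cascade"
  out
}

#' Evaluate a screening cascade for one health state
#'
#' Walks a person with the given true health state through the ordered
#' cascade.  At each step the person attends with the state-class
#' compliance; attending a step incurs its full cost (fee, transport, lost
#' productivity).  A diseased person (precancer or cancer) continues only on
#' a true-positive result and, after a positive result at every step,
#' reaches biopsy; confirmed diagnosis requires biopsy attendance.  A
#' disease-free person continues on false-positive results and is released
#' at the confirmation step for the no-cancer state, so specificity losses
#' generate cost but never a diagnosis.  Anyone exiting early (non-attendance
#' or a negative result) keeps their state and re-enters the cascade next
#' cycle.
#'
#' @param state Health state: `"no_cancer"`, `"precancer"`, or `"stage_I"`
#'   through `"stage_IV"`.
#' @param cascade An `os_cascade` built by [build_cascade()].
#' @return A list with `p_confirmed` (probability of biopsy-confirmed
#'   diagnosis this cycle), `expected_cost` (THB per person entering the
#'   cascade, management cost included) and `p_any_contact` (probability of
#'   attending the first step).
#' @export
evaluate_cascade <- function(state, cascade) {
  if (!state %in% HEALTH_STATES) stop("unknown health state '", state, "'")
  cls <- state_class(state)
  diseased <- cls != "no_cancer"
  cost <- 0
  p_reach <- 1
  p_any <- cascade$steps[[1]]$compliance[[cls]]
  for (i in seq_along(cascade$steps)) {
    s <- cascade$steps[[i]]
    att <- s$compliance[[cls]]
    cost <- cost + p_reach * att * s$cost
    if (diseased) {
      pos <- if (cls == "precancer") s$sens_precancer else s$sens_cancer
      p_reach <- p_reach * att * pos
    } else {
      if (i == cascade$confirmation_index) {
        if (cascade$fp_workup == "full") {
          # positives at the confirmation step are still referred on: they
          # attend the remaining examinations and a rule-out biopsy before
          # being released without diagnosis
          p_ref <- p_reach * att * (1 - s$spec)
          for (j in seq_along(cascade$steps)[-seq_len(i)]) {
            sj <- cascade$steps[[j]]
            attj <- sj$compliance[[cls]]
            cost <- cost + p_ref * attj * sj$cost
            p_ref <- p_ref * attj
          }
          cost <- cost + p_ref * cascade$biopsy$compliance * cascade$biopsy$cost
        }
        p_reach <- 0
        break
      }
      p_reach <- p_reach * att * (1 - s$spec)
    }
  }
  if (diseased) {
    cost <- cost + p_reach * cascade$biopsy$compliance * cascade$biopsy$cost
    p_confirmed <- p_reach * cascade$biopsy$compliance
  } else {
    p_confirmed <- 0
  }
  # programme management: either a flat amount per person per cycle or a
  # fractional overhead on the screening services delivered
  cost <- cost + if (cascade$management_as_fraction) {
    cascade$management_cost * cost
  } else {
    cascade$management_cost
  }
  list(p_confirmed = p_confirmed, expected_cost = cost, p_any_contact = p_any)
}

#' Evaluate the no-screening (self-referral) pathway for one health state
#'
#' Convenience wrapper over [evaluate_cascade()] for a model's
#' `no_screening` cascade: self-referral to a general dentist acts as the
#' first-step compliance, followed by oral-surgeon examination and biopsy.
#'
#' @param state Health state.
#' @param model An `os_model`, or an already-built `os_cascade` for the
#'   self-referral pathway.
#' @param theta Optional parameter vector (defaults to the model means).
#' @return As [evaluate_cascade()].
#' @export
evaluate_no_screening <- function(state, model, theta = NULL) {
  casc <- if (inherits(model, "os_cascade")) model else {
    if (is.null(theta)) theta <- param_values(model)
    build_cascade(model$cascades$no_screening, theta)
  }
  evaluate_cascade(state, casc)
}

#' Scenario cascades: reduced versions of the base screening programme
#'
#' Returns the screening-cascade configuration of one of the four programme
#' scenarios: A, the full four-step cascade (MSE, VETDN, VETDT, VEOS); B,
#' MSE removed; C, MSE and VETDN removed; D, VETDN removed.  All remaining
#' steps keep their order, accuracies, compliances and costs.
#'
#' @param model An `os_model`.
#' @param scenario_id One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return A cascade configuration (same shape as
#'   `model$cascades$screening`).
#' @export
scenario_cascade <- function(model, scenario_id) {
  removed <- switch(scenario_id,
    A = character(),
    B = "mse",
    C = c("mse", "vetdn"),
    D = "vetdn",
    stop("unknown scenario '", scenario_id, "' (expected A, B, C or D)")
  )
  cc <- model$cascades$screening
  keep <- vapply(cc$steps, function(s) !s$name %in% removed, TRUE)
  cc$steps <- cc$steps[keep]
  validate_cascade_config(list(scenario = cc))
  cc
}

#' Cascade outcomes for every health state
#'
#' Evaluates a cascade for each living health state, the per-cycle
#' detection probabilities and expected screening costs the transition
#' engine consumes.
#'
#' @param cascade An `os_cascade`.
#' @return Data frame with columns `state`, `p_confirmed`, `expected_cost`,
#'   `p_any_contact`.
#' @export
cascade_outcomes <- function(cascade) {
  rows <- lapply(HEALTH_STATES, function(st) {
    o <- evaluate_cascade(st, cascade)
    data.frame(state = st, p_confirmed = o$p_confirmed,
               expected_cost = o$expected_cost,
               p_any_contact = o$p_any_contact)
  })
  do.call(rbind, rows)
}
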