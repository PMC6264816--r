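# Synthetic-data generators: time-trade-off interview responses, patient
# cost records, and perturbed parameter tables for property testing.

#' Utility estimate from time-trade-off responses
#'
#' In the time-trade-off interview a respondent chooses the number of years
#' in full health (0-10) they judge equivalent to living 10 years in the
#' health state; the respondent-level utility is that number divided by 10.
#' Returns the sample mean and its standard error.
#'
#' @param responses Data frame with a `chosen_years` column, or a numeric
#'   vector of chosen years (integers 0-10).
#' @return List with `mean` (in `[0, 1]`), `se` (sample SD / sqrt(n)) and
#'   `n`.
#' @examples
#' tto_utility(c(8, 9, 8, 8, 9))  # mean 0.84
#' @export
tto_utility <- function(responses) {
  x <- if (is.data.frame(responses)) responses$chosen_years else responses
  if (!length(x)) stop("no responses")
  if (any(x < 0 | x > 10)) stop("chosen_years must lie in 0-10")
  u <- x / 10
  list(mean = mean(u),
       se = if (length(u) > 1) stats::sd(u) / sqrt(length(u)) else 0,
       n = length(u))
}

#' Generate synthetic time-trade-off responses
#'
#' Emulates a TTO interview of `n` respondents whose true utility for the
#' state is `true_utility`: each respondent's indifference point is the
#' true utility plus truncated-normal noise on the utility scale, rounded
#' to the nearest whole year out of ten (the questionnaire's granularity).
#' The default noise scale is chosen so that about nine respondents yield a
#' standard error near 0.02, the precision of the precancer utility.
#'
#' @param true_utility True state utility in `[0, 1]`.
#' @param n Number of respondents (at least 1).
#' @param seed Integer seed.
#' @param noise_sd Standard deviation of the respondent-level noise on the
#'   utility scale (default 0.055).
#' @param state Optional state label attached to the output.
#' @return Data frame with `respondent`, `state`, `chosen_years`.
#' @export
generate_tto_responses <- function(true_utility, n, seed = 1,
                                   noise_sd = 0.055, state = "precancer") {
  if (true_utility < 0 || true_utility > 1) {
    stop("true_utility must lie in [0, 1]")
  }
  if (n < 1) stop("n must be at least 1")
  set.seed(seed)
  u <- if (noise_sd == 0) rep(true_utility, n) else {
    # truncated normal on [0, 1] by inverse-CDF
    lo <- stats::pnorm(0, true_utility, noise_sd)
    hi <- stats::pnorm(1, true_utility, noise_sd)
    stats::qnorm(stats::runif(n, lo, hi), true_utility, noise_sd)
  }
  data.frame(respondent = seq_len(n), state = state,
             chosen_years = as.integer(round(10 * u)))
}

#' Generate synthetic patient cost records
#'
#' Emulates interview-collected cost data: `n` gamma-distributed
#' patient-level amounts whose sample mean has, by construction, the stated
#' standard error at the stated `n` (patient-level variance `n * se^2`).
#'
#' @param mean Target mean cost, THB, positive.
#' @param se_of_mean Standard error of the sample mean, positive.
#' @param n Number of patients.
#' @param seed Integer seed.
#' @param state,component Optional labels attached to the records.
#' @return Data frame with `patient`, `state`, `component`, `amount`.
#' @export
generate_cost_records <- function(mean, se_of_mean, n, seed = 1,
                                  state = "precancer",
                                  component = "direct_medical") {
  if (mean <= 0 || se_of_mean <= 0) stop("mean and se_of_mean must be positive")
  if (n < 1) stop("n must be at least 1")
  set.seed(seed)
  sd_patient <- sqrt(n) * se_of_mean
  sh <- gamma_from_moments(mean, sd_patient)
  data.frame(patient = seq_len(n), state = state, component = component,
             amount = stats::rgamma(n, shape = sh$shape, scale = sh$scale))
}

#' Randomly perturb a parameter table
#'
#' Jitters the mean of every distributed parameter uniformly within
#' `+/- scale` of its value, then clips back into the feasible region of
#' its family (for Beta parameters the open interval where the stored
#' standard error still admits moment matching), so the result always
#' passes the parameter-table invariants.  Used for property-based testing
#' of downstream modules.
#'
#' @param params An `os_parameter_table` or `os_model`.
#' @param scale Relative jitter magnitude in `[0, 1)`.
#' @param seed Integer seed.
#' @return A new validated `os_parameter_table`.
#' @export
perturb_parameter_table <- function(params, scale, seed = 1) {
  if (inherits(params, "os_model")) params <- params$params
  if (scale < 0 || scale >= 1) stop("scale must lie in [0, 1)")
  set.seed(seed)
  df <- as.data.frame(params)
  eps <- 1e-6
  for (i in seq_len(nrow(df))) {
    if (df$family[i] == "fixed") next
    m <- df$mean[i] * (1 + stats::runif(1, -scale, scale))
    if (df$family[i] == "beta") {
      # keep se^2 < m (1 - m): clip into the root interval of m^2 - m + se^2
      v <- df$se[i]^2
      disc <- 1 - 4 * v
      lo <- if (disc > 0) (1 - sqrt(disc)) / 2 + eps else 0.5 - eps
      hi <- if (disc > 0) (1 + sqrt(disc)) / 2 - eps else 0.5 + eps
      m <- min(max(m, max(lo, eps)), min(hi, 1 - eps))
    } else {
      m <- max(m, eps)
    }
    df$mean[i] <- m
  }
  parameter_table(df)
}
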