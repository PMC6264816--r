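# Independent oracles used across tests.

# Exhaustive outcome-tree enumeration of a screening cascade: every
# attendance / test-result combination is expanded as an explicit branch and
# the leaf probabilities and path costs are summed.  Independent of the
# sequential-product evaluator in the package (fp_workup = "release" rules).
oracle_cascade <- function(state, cascade) {
  cls <- switch(state,
    no_cancer = "no_cancer", precancer = "precancer",
    stage_I = , stage_II = "cancer_early",
    stage_III = , stage_IV = "cancer_late")
  diseased <- cls != "no_cancer"
  p_confirmed <- 0
  expected_cost <- 0
  recurse <- function(i, prob, cost) {
    if (prob == 0) return()
    if (i > length(cascade$steps)) {
      # reached the end of the examination chain: biopsy for diseased
      if (diseased) {
        cb <- cascade$biopsy$compliance
        # attends biopsy: confirmed
        p_confirmed <<- p_confirmed + prob * cb
        expected_cost <<- expected_cost +
          prob * cb * (cost + cascade$biopsy$cost)
        # skips biopsy: exits unconfirmed
        expected_cost <<- expected_cost + prob * (1 - cb) * cost
      } else {
        expected_cost <<- expected_cost + prob * cost
      }
      return()
    }
    s <- cascade$steps[[i]]
    att <- s$compliance[[cls]]
    # branch: does not attend -> exits with costs so far
    expected_cost <<- expected_cost + prob * (1 - att) * cost
    cost_att <- cost + s$cost
    if (diseased) {
      pos <- if (cls == "precancer") s$sens_precancer else s$sens_cancer
      # attends, negative result -> exit
      expected_cost <<- expected_cost + prob * att * (1 - pos) * cost_att
      # attends, positive -> next step
      recurse(i + 1, prob * att * pos, cost_att)
    } else {
      if (i == cascade$confirmation_index) {
        # attends the confirmation step and is released
        expected_cost <<- expected_cost + prob * att * cost_att
        return()
      }
      # true negative -> released; false positive -> next step
      expected_cost <<- expected_cost + prob * att * s$spec * cost_att
      recurse(i + 1, prob * att * (1 - s$spec), cost_att)
    }
  }
  recurse(1, 1, 0)
  expected_cost <- expected_cost + if (isTRUE(cascade$management_as_fraction)) {
    cascade$management_cost * expected_cost
  } else {
    cascade$management_cost
  }
  list(p_confirmed = p_confirmed, expected_cost = expected_cost)
}

# Random cascade configuration with n_steps steps and literal numeric rates.
random_cascade_config <- function(n_steps) {
  steps <- lapply(seq_len(n_steps), function(i) {
    list(name = paste0("step", i),
         sens_precancer = runif(1, 0.05, 1),
         sens_cancer = runif(1, 0.5, 1),
         spec = runif(1, 0.3, 1),
         compliance = list(no_cancer = runif(1), precancer = runif(1),
                           cancer_early = runif(1), cancer_late = runif(1)),
         cost = list(direct = runif(1, 0, 200), transport = runif(1, 0, 100),
                     productivity = runif(1, 0, 100)))
  })
  list(steps = steps,
       biopsy = list(compliance = runif(1, 0.2, 1), cost = runif(1, 100, 600)),
       confirmation = list(no_cancer = paste0("step", sample.int(n_steps, 1))),
       management_cost = runif(1, 0, 5))
}

# Load the bundled model once for the whole suite.
default_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- load_model()
    m
  }
})
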