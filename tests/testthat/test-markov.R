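test_that("hazard-ratio transform matches its closed form and composes", {
  expect_equal(hr_adjust(0.53, 1), 0.53)
  expect_equal(hr_adjust(0.53, 0.5), 1 - sqrt(0.47), tolerance = 1e-12)
  expect_equal(hr_adjust(0.20, 2), 0.36, tolerance = 1e-12)
  expect_equal(hr_adjust(1, 3), 1)  # saturation
  expect_equal(hr_adjust(0.6, 2, "multiplicative"), 1)  # capped

  set.seed(3)
  for (i in 1:50) {
    p <- runif(1)
    a <- runif(1, 0.1, 3)
    b <- runif(1, 0.1, 3)
    expect_equal(hr_adjust(hr_adjust(p, a), b), hr_adjust(p, a * b),
                 tolerance = 1e-12)
  }
  expect_error(hr_adjust(1.2, 1), "\\[0, 1\\]")
  expect_error(hr_adjust(0.5, -1), "positive")
})

test_that("transition matrices are row-stochastic with absorbing death", {
  m <- default_model()
  for (arm in c("screening", "no_screening")) {
    for (age in c(40, 70, 99)) {
      M <- build_transition_matrix(m, age, arm)
      expect_true(all(abs(rowSums(M) - 1) < 1e-10))
      expect_true(all(M >= -1e-12 & M <= 1 + 1e-12))
      expect_equal(unname(M["death", "death"]), 1)
      expect_true(all(M["death", setdiff(colnames(M), "death")] == 0))
    }
  }
})

test_that("untreated precancer row matches an independent hand assembly", {
  m <- default_model()
  th <- param_values(m)
  age <- 55
  M <- build_transition_matrix(m, age, "no_screening")
  qx <- m$life_table$qx[m$life_table$age == age]
  casc <- build_cascade(m$cascades$no_screening, th)
  d <- evaluate_cascade("precancer", casc)$p_confirmed
  s <- 1 - qx
  tc <- th[["tc_precancer"]]
  cure <- th[["p_precancer_cure"]]
  prog <- th[["p_precancer_to_I"]]
  prog_tr <- 1 - (1 - prog)^th[["hr_treatment_progression"]]
  ltfu <- th[["p_ltfu_to_I"]]
  regr <- th[["p_precancer_regression"]]
  r <- M["precancer_undetected", ]
  expect_equal(unname(r[["death"]]), qx)
  expect_equal(unname(r[["no_cancer"]]),
               s * (d * tc * cure + (d * (1 - tc) + (1 - d)) * regr),
               tolerance = 1e-12)
  expect_equal(unname(r[["stage_I_on_treatment"]]), s * d * tc * prog_tr,
               tolerance = 1e-12)
  expect_equal(unname(r[["stage_I_undetected"]]),
               s * (d * tc * ltfu + (1 - d) * prog), tolerance = 1e-12)
  expect_equal(sum(r), 1, tolerance = 1e-12)
})

test_that("cohort occupancy is conserved and death is monotone", {
  m <- default_model()
  for (arm in c("screening", "no_screening")) {
    tr <- run_cohort(m, arm)
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-9))
    expect_true(all(diff(tr$occupancy[, "death"]) >= -1e-12))
    expect_true(all(tr$occupancy >= -1e-12))
  }
})

test_that("cohort iteration matches an independent matrix-power computation", {
  m <- default_model()
  th <- param_values(m)
  tr <- run_cohort(m, "screening")
  v <- stats::setNames(numeric(length(oralscreen:::MODEL_STATES)),
                       oralscreen:::MODEL_STATES)
  v["no_cancer"] <- 1
  for (t in 1:15) {
    M <- build_transition_matrix(m, 39 + t, "screening", theta = th)
    v <- as.vector(v %*% M)
  }
  expect_equal(unname(tr$occupancy[16, ]), v, tolerance = 1e-12)
})

test_that("with zero incidence QALYs equal discounted life expectancy", {
  m <- default_model()
  th <- param_values(m)
  th[["p_no_cancer_to_precancer"]] <- 0
  res <- run_arm(m, "no_screening", theta = th)
  qx <- m$life_table$qx[match(40:99, m$life_table$age)]
  S <- cumprod(c(1, 1 - qx[1:59]))
  expect_equal(unname(res[["qaly"]]), sum(S / 1.03^(0:59)), tolerance = 1e-9)
})

test_that("discounted accumulation matches hand sums", {
  fake <- structure(list(cost_screening = c(100, 100), cost_treatment = c(0, 0),
                         qaly = c(1, 1),
                         settings = os_settings(discount_rate = 0.03)),
                    class = "os_trace")
  out <- accumulate(fake)
  expect_equal(unname(out[["cost"]]), 100 + 100 / 1.03, tolerance = 1e-12)
  expect_equal(unname(out[["qaly"]]), 1 + 1 / 1.03, tolerance = 1e-12)

  out0 <- accumulate(fake, os_settings(discount_rate = 0))
  expect_equal(unname(out0[["cost"]]), 200)
  expect_equal(unname(out0[["qaly"]]), 2)
})

test_that("screening changes outcomes only through detection", {
  m <- default_model()
  # give both arms the identical cascade: QALYs must coincide exactly
  m$cascades$no_screening <- m$cascades$screening
  scr <- run_arm(m, "screening")
  ns <- run_arm(m, "no_screening")
  expect_equal(unname(scr[["qaly"]]), unname(ns[["qaly"]]), tolerance = 1e-12)
})

test_that("screening arm never loses QALYs under the base configuration", {
  m <- default_model()
  scr <- run_arm(m, "screening")
  ns <- run_arm(m, "no_screening")
  expect_gte(scr[["qaly"]], ns[["qaly"]])
})

test_that("stage-entry survival curves follow their closed forms", {
  m <- default_model()
  th <- param_values(m)
  # stage IV on treatment has no onward progression: geometric survival
  s4 <- survival_curve(m, "stage_IV", "on_treatment", years = 5, theta = th)
  expect_equal(s4, (1 - th[["p_death_IV"]])^(0:5), tolerance = 1e-12)

  th0 <- th
  th0[["p_death_IV"]] <- 0
  flat <- survival_curve(m, "stage_IV", "on_treatment", years = 5, theta = th0)
  expect_equal(flat, rep(1, 6))

  s1 <- survival_curve(m, "stage_I", "on_treatment", years = 10, theta = th)
  expect_equal(s1[1], 1)
  expect_true(all(diff(s1) <= 0))
  # progression to deadlier stages pulls survival below the stage-I envelope
  expect_true(all(s1[-1] <= (1 - th[["p_death_I"]])^(1:10) + 1e-12))
  expect_error(survival_curve(m, "precancer"), "cancer stage")
})
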