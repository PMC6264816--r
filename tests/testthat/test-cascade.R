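test_that("degenerate cascades behave as expected", {
  cfg <- list(
    steps = list(list(name = "a", sens_precancer = 1, spec = 1,
                      compliance = list(no_cancer = 1, precancer = 1,
                                        cancer_early = 1, cancer_late = 1),
                      cost = list(direct = 10))),
    biopsy = list(compliance = 1, cost = 100),
    confirmation = list(no_cancer = "a"),
    management_cost = 2
  )
  casc <- build_cascade(cfg, c(dummy = 0))
  perfect <- evaluate_cascade("precancer", casc)
  expect_equal(perfect$p_confirmed, 1)
  expect_equal(perfect$expected_cost, 10 + 100 + 2)

  cfg$steps[[1]]$compliance <- list(no_cancer = 0, precancer = 0,
                                    cancer_early = 0, cancer_late = 0)
  casc0 <- build_cascade(cfg, c(dummy = 0))
  nobody <- evaluate_cascade("precancer", casc0)
  expect_equal(nobody$p_confirmed, 0)
  expect_equal(nobody$expected_cost, 2)  # management only
  expect_equal(nobody$p_any_contact, 0)
})

test_that("bundled cascades reproduce the hand-multiplied chains", {
  m <- default_model()
  th <- param_values(m)
  scr <- build_cascade(m$cascades$screening, th)
  pc <- evaluate_cascade("precancer", scr)
  chain <- 0.97 * 0.20 * 0.80 * 0.44 * 0.76 * 0.87 * 0.91 * 0.76 * 0.62
  expect_equal(pc$p_confirmed, chain, tolerance = 1e-12)
  expect_equal(pc$p_confirmed, 0.0194, tolerance = 1e-2)

  # invasive cancer: full compliance and perfect accuracy leave only biopsy
  for (st in c("stage_I", "stage_II", "stage_III", "stage_IV")) {
    expect_equal(evaluate_cascade(st, scr)$p_confirmed, 0.62,
                 tolerance = 1e-12)
  }

  ns <- build_cascade(m$cascades$no_screening, th)
  pcn <- evaluate_no_screening("precancer", ns)
  expect_equal(pcn$p_confirmed, 0.04 * 0.84 * 0.76 * 0.51, tolerance = 1e-12)
  expect_equal(pcn$p_confirmed, 0.0130, tolerance = 1e-2)

  # disease-free: never confirmed, but false positives cost money
  nc <- evaluate_no_screening("no_cancer", ns)
  expect_equal(nc$p_confirmed, 0)
  expect_gt(nc$expected_cost, 0)

  # late-stage self-referral is the only barrier when everything downstream
  # is perfect
  th2 <- th
  th2[c("sens_gd", "sens_veos_ns", "c_biopsy_noscreening")] <- 1
  ns2 <- build_cascade(m$cascades$no_screening, th2)
  expect_equal(evaluate_cascade("stage_III", ns2)$p_confirmed, 0.82,
               tolerance = 1e-12)
})

test_that("cascade evaluator agrees with exhaustive outcome-tree oracle", {
  set.seed(101)
  for (rep in 1:200) {
    cfg <- random_cascade_config(sample(1:5, 1))
    casc <- build_cascade(cfg, c(dummy = 0))
    for (st in oralscreen:::HEALTH_STATES) {
      got <- evaluate_cascade(st, casc)
      want <- oracle_cascade(st, casc)
      expect_equal(got$p_confirmed, want$p_confirmed, tolerance = 1e-12)
      expect_equal(got$expected_cost, want$expected_cost, tolerance = 1e-12)
    }
  }
})

test_that("detection is monotone in sensitivity and compliance", {
  set.seed(7)
  cfg <- random_cascade_config(4)
  base <- build_cascade(cfg, c(dummy = 0))
  p0 <- evaluate_cascade("precancer", base)$p_confirmed
  for (i in 1:4) {
    up <- cfg
    up$steps[[i]]$sens_precancer <- min(1, up$steps[[i]]$sens_precancer + 0.1)
    expect_gte(evaluate_cascade("precancer", build_cascade(up, c(dummy = 0)))$p_confirmed, p0)
    up2 <- cfg
    up2$steps[[i]]$compliance$precancer <- min(1, up2$steps[[i]]$compliance$precancer + 0.1)
    expect_gte(evaluate_cascade("precancer", build_cascade(up2, c(dummy = 0)))$p_confirmed, p0)
  }
  # healthy-state cost is non-increasing in every specificity
  c0 <- evaluate_cascade("no_cancer", base)$expected_cost
  for (i in 1:4) {
    up <- cfg
    up$steps[[i]]$spec <- min(1, up$steps[[i]]$spec + 0.1)
    expect_lte(evaluate_cascade("no_cancer", build_cascade(up, c(dummy = 0)))$expected_cost,
               c0 + 1e-12)
  }
})

test_that("removing an imperfect step never hurts detection", {
  m <- default_model()
  th <- param_values(m)
  p_conf <- function(id) {
    casc <- build_cascade(scenario_cascade(m, id), th)
    evaluate_cascade("precancer", casc)$p_confirmed
  }
  pA <- p_conf("A")
  expect_gte(p_conf("B"), pA)  # drops MSE (sens 0.20)
  expect_gte(p_conf("C"), pA)
  expect_gte(p_conf("D"), pA)  # drops VETDN (sens 0.44): scenario-D mechanism
  expect_gte(p_conf("C"), p_conf("D"))
})

test_that("scenario cascades keep the right steps", {
  m <- default_model()
  step_names <- function(id)
    vapply(scenario_cascade(m, id)$steps, function(s) s$name, "")
  expect_equal(step_names("A"), c("mse", "vetdn", "vetdt", "veos"))
  expect_equal(step_names("B"), c("vetdn", "vetdt", "veos"))
  expect_equal(step_names("C"), c("vetdt", "veos"))
  expect_equal(step_names("D"), c("mse", "vetdt", "veos"))
  expect_error(scenario_cascade(m, "E"), "unknown scenario")
})

test_that("cascade validation rejects broken configurations", {
  m <- default_model()
  th <- param_values(m)
  cfg <- m$cascades$screening
  cfg$steps[[1]]$compliance$precancer <- NULL
  expect_error(build_cascade(cfg, th), "compliance")

  cfg2 <- m$cascades$screening
  cfg2$steps[[1]]$sens_precancer <- "not_a_parameter"
  expect_error(build_cascade(cfg2, th), "not_a_parameter")

  cfg3 <- m$cascades$screening
  cfg3$confirmation$no_cancer <- "gone"
  expect_error(validate_cascade_config(list(screening = cfg3)), "confirmation")
})
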