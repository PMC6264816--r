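test_that("ICER arithmetic and dominance flags are correct", {
  r <- icer(2765, 21.6233, 1403, 21.6189)
  expect_equal(r$delta_cost, 1362)
  expect_equal(r$delta_qaly, 0.0044, tolerance = 1e-9)
  expect_equal(r$icer, 1362 / 0.0044, tolerance = 1e-9)  # about 309,545
  expect_equal(r$dominance, "none")

  expect_equal(icer(10, 1, 5, 1)$dominance, "undefined")
  expect_true(is.na(icer(10, 1, 5, 1)$icer))
  expect_equal(icer(4, 2, 5, 1)$dominance, "dominant")
  expect_equal(icer(6, 0.5, 5, 1)$dominance, "dominated")
})

test_that("net monetary benefit and the ICER decision rule agree", {
  expect_equal(nmb(500, 2, 0), -500)
  expect_equal(nmb(160000, 1, 160000), 0)
  expect_error(nmb(1, 1, -5), "non-negative")

  set.seed(9)
  for (i in 1:200) {
    c1 <- runif(1, 0, 5000); c0 <- runif(1, 0, 5000)
    q1 <- runif(1, 10, 30); q0 <- runif(1, 10, 30)
    lam <- runif(1, 0, 4e5)
    if (q1 == q0) next
    dnmb <- nmb(c1, q1, lam) - nmb(c0, q0, lam)
    r <- icer(c1, q1, c0, q0)
    if (r$delta_qaly > 0 && r$dominance == "none") {
      expect_equal(dnmb > 0, r$icer < lam)
    }
  }
})

test_that("the deterministic base case is seed-independent and coherent", {
  m <- default_model()
  bc1 <- run_base_case(m)
  set.seed(999)
  bc2 <- run_base_case(m)
  expect_identical(bc1$icer, bc2$icer)
  expect_equal(bc1$delta_cost,
               bc1$screening[["cost"]] - bc1$no_screening[["cost"]])
  expect_equal(bc1$icer, bc1$delta_cost / bc1$delta_qaly)
})

test_that("PSA draws are reproducible and the CEAC has the right limits", {
  m <- default_model()
  p1 <- run_psa(m, n = 40, seed = 5)
  p2 <- run_psa(m, n = 40, seed = 5)
  expect_identical(p1$draws, p2$draws)

  dc <- p1$draws$cost_screening - p1$draws$cost_no_screening
  dq <- p1$draws$qaly_screening - p1$draws$qaly_no_screening
  expect_equal(ceac_at(p1, 0), mean(dc < 0))
  expect_equal(ceac_at(p1, 1e12), mean(dq > 0))
  expect_true(all(p1$ceac$probability >= 0 & p1$ceac$probability <= 1))
})

test_that("degenerate PSA collapses to the deterministic result", {
  m <- default_model()
  m$params$se <- NA_real_
  m$params$family <- "fixed"
  m$params <- parameter_table(as.data.frame(m$params))
  psa <- run_psa(m, n = 5, seed = 1)
  expect_equal(length(unique(psa$draws$cost_screening)), 1)
  bc <- run_base_case(m)
  # the CEAC is a step function located at the deterministic ICER
  expect_equal(psa$ceac$probability,
               as.numeric(psa$ceac$lambda > bc$icer))
})

test_that("one-way analysis follows the confidence bounds", {
  m <- default_model()
  ow <- one_way(m, "sens_mse")
  cb <- confidence_bounds(m$params[m$params$name == "sens_mse", ])
  expect_equal(ow$low, cb[["low"]])
  expect_equal(ow$high, cb[["high"]])
  # better sensitivity means a lower ICER
  expect_lt(ow$icer_high, ow$icer_low)
  base <- run_base_case(m)$icer
  expect_lt(ow$icer_high, base)
  expect_gt(ow$icer_low, base)

  expect_error(one_way(m, "c_screen_cancer"), "not varied")
  expect_error(one_way(m, "nonexistent"), "unknown parameter")
  ob <- one_way(m, "c_screen_cancer", bounds = c(0.8, 1))
  expect_lt(ob$icer_high, ob$icer_low)
})

test_that("two-way grid mode reduces to the base case on a trivial grid", {
  m <- default_model()
  base <- run_base_case(m)$icer
  tw <- two_way(m, "sens_mse", "spec_mse", rel = 0)
  expect_equal(nrow(tw$surface), 1)
  expect_equal(tw$surface$icer, base, tolerance = 1e-12)
  expect_error(two_way(m, "sens_mse", "spec_mse", rel = numeric(0)), "grid")
  expect_error(two_way(m, "nope", mode = "paired"), "paired accuracy")
})

test_that("paired accuracy sweeps fall monotonically and cross the threshold", {
  m <- default_model()
  tw <- two_way(m, "mse", mode = "paired", values = seq(0.3, 0.9, 0.1))
  expect_true(all(diff(tw$sweep$icer) < 0))
  expect_false(is.na(tw$crossing))
  expect_gt(tw$crossing, 0.3)
  expect_lt(tw$crossing, 0.9)
})

test_that("scenario table is internally consistent", {
  m <- default_model()
  sc <- run_scenarios(m)
  expect_equal(sc$scenario, c("A", "B", "C", "D"))
  expect_equal(sc$icer, sc$delta_cost / sc$delta_qaly, tolerance = 1e-12)
  # scenario A is the base cascade
  expect_equal(sc$icer[1], run_base_case(m)$icer, tolerance = 1e-12)

  # a "screening" programme identical to usual care changes nothing
  m2 <- m
  m2$cascades$screening <- m2$cascades$no_screening
  bc <- run_base_case(m2)
  expect_equal(bc$delta_qaly, 0, tolerance = 1e-12)
  expect_equal(bc$dominance, "undefined")
})
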