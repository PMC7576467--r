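test_that("discount factors follow (1 + r)^(-t/12) with no half-cycle shift", {
  expect_equal(discount_factor(0, 0.015), 1)
  expect_equal(discount_factor(240, 0), 1)
  expect_equal(discount_factor(12, 0.015), 1 / 1.015)
  expect_equal(discount_factor(12, 0.015), 0.9852217, tolerance = 1e-7)
})

test_that("the compiled engine reproduces the plain-R cycle semantics", {
  p <- small_params()
  co <- generate_cohort(150, p, seed = 20)
  withr::with_seed(21, draws <- hftelesim:::make_draws(nrow(co), p$horizon_months))
  for (arm in c("standard", "telemonitoring")) {
    fast <- hftelesim:::run_arm(co, p, arm, draws)
    slow <- hftelesim:::simulate_arm_r(co, p, arm, draws)
    expect_equal(as.data.frame(fast), as.data.frame(slow), label = arm)
  }
})

test_that("death is absorbing and forced death stops accrual", {
  p <- small_params()
  co <- generate_cohort(1, p, seed = 1)
  inp <- hftelesim:::engine_inputs(co, p, "standard")
  state <- list(current = "NYHA2", resident_nyha = 2L,
                months_since_discharge = NA, month = 0L, age = 50)

  expect_error(step_patient(list(current = "DEAD"), inp, runif(3)),
               "absorbing")

  inp$p_death_comm <- 1
  step <- step_patient(state, inp, c(0.99, 0.5, 0.5))
  expect_identical(step$state$current, "DEAD")

  # a patient with near-certain monthly death survives exactly one cycle
  p1 <- p
  p1$shfm$baseline_annual_hazard <- 1e6
  res <- simulate_cohort(co, p1, seed = 2, arms = "standard")
  expect_identical(res$life_months, 1L)
})

test_that("a forced NYHA transition follows the cumulative row in order", {
  p <- small_params()
  co <- generate_cohort(1, p, seed = 1)
  co$nyha_class <- 1L
  inp <- hftelesim:::engine_inputs(co, p, "standard")
  inp$p_death_comm <- 0
  inp$admit_prob <- rep(0, 4)
  state <- list(current = "NYHA1", resident_nyha = 1L,
                months_since_discharge = NA, month = 0L, age = 50)
  # row I cumulates to 0.977 / 0.996 / 1.000; a draw of 0.98 lands in II
  step <- step_patient(state, inp, c(0.5, 0.9, 0.98))
  expect_identical(step$state$current, "NYHA2")
  step <- step_patient(state, inp, c(0.5, 0.9, 0.9975))
  expect_identical(step$state$current, "NYHA3")
})

test_that("a benign patient accrues exactly utility/12 per cycle", {
  # no deaths, no admissions, no discounting, class I throughout
  p <- tm_parameters(horizon_months = 12L, discount_rate_annual = 0,
                     hosp_prob_monthly = c(NYHA1 = 0, NYHA2 = 0,
                                           NYHA3 = 0, NYHA4 = 0),
                     readmit_prob_30d = 0,
                     nyha_transition_matrix = diag(4))
  p$shfm$baseline_annual_hazard <- 1e-12
  co <- generate_cohort(5, p, seed = 3)
  co$nyha_class <- 1L
  res <- simulate_cohort(co, p, seed = 4, arms = "standard")
  expect_equal(res$qaly, rep(0.81, 5))
  expect_equal(res$life_months, rep(12L, 5))
  expect_equal(res$admissions, rep(0L, 5))
})

test_that("class occupancy is conserved under an identity transition matrix", {
  p <- tm_parameters(horizon_months = 24L, discount_rate_annual = 0,
                     hosp_prob_monthly = c(NYHA1 = 0, NYHA2 = 0,
                                           NYHA3 = 0, NYHA4 = 0),
                     readmit_prob_30d = 0,
                     nyha_transition_matrix = diag(4))
  p$shfm$baseline_annual_hazard <- 1e-12
  co <- generate_cohort(40, p, seed = 5)
  co <- co[co$age_years < 60, ] # keep the drug age gate shut throughout
  res <- simulate_cohort(co, p, seed = 6, arms = "standard")
  # each patient's QALYs and costs identify a constant class over 24 cycles
  u <- tm_parameters()$utilities_by_class[co$nyha_class]
  expect_equal(res$qaly, unname(24 * u / 12))
})

test_that("results are deterministic given the seed", {
  p <- small_params()
  co <- generate_cohort(80, p, seed = 7)
  a <- simulate_cohort(co, p, seed = 8)
  b <- simulate_cohort(co, p, seed = 8)
  expect_identical(a, b)
  expect_error(simulate_cohort(co[0, ], p, seed = 1), "empty")
})

test_that("a null intervention gives identical arms under common random numbers", {
  p <- null_intervention_params(horizon_months = 120L)
  co <- generate_cohort(250, p, seed = 9)
  w <- wide_results(simulate_cohort(co, p, seed = 10))
  expect_identical(w$cost_standard, w$cost_telemonitoring)
  expect_identical(w$qaly_standard, w$qaly_telemonitoring)
  expect_identical(w$life_months_standard, w$life_months_telemonitoring)
  expect_identical(w$admissions_standard, w$admissions_telemonitoring)
})

test_that("raising the readmission probability raises mean admissions", {
  p_lo <- small_params(readmit_prob_30d = 0.05)
  p_hi <- small_params(readmit_prob_30d = 0.30)
  co <- generate_cohort(400, p_lo, seed = 11)
  a <- simulate_cohort(co, p_lo, seed = 12, arms = "standard")
  b <- simulate_cohort(co, p_hi, seed = 12, arms = "standard")
  expect_gt(mean(b$admissions), mean(a$admissions))
})

test_that("global accounting bounds hold on a simulated cohort", {
  p <- small_params()
  co <- generate_cohort(200, p, seed = 13)
  res <- simulate_cohort(co, p, seed = 14)
  expect_true(all(res$cost >= 0))
  expect_true(all(res$qaly >= 0))
  expect_true(all(res$life_months <= p$horizon_months))
  expect_true(all(res$qaly <= p$horizon_months / 12 *
                    max(p$utilities_by_class)))

  # discounting can only shrink totals
  p0 <- small_params(discount_rate_annual = 0)
  res0 <- simulate_cohort(co, p0, seed = 14)
  expect_true(all(res0$cost >= res$cost))
  expect_true(all(res0$qaly >= res$qaly))
})

test_that("single-patient simulation matches the cohort path", {
  p <- small_params()
  co <- generate_cohort(1, p, seed = 15)
  a <- simulate_patient(co, p, arm = "standard", seed = 16)
  b <- simulate_cohort(co, p, seed = 16, arms = "standard")
  expect_equal(as.data.frame(a), as.data.frame(b))
})
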