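test_that("monthly state costs assemble the printed component totals", {
  p <- tm_parameters()
  expect_equal(monthly_state_cost(1, 70, p)$total, 149.00)
  expect_equal(monthly_state_cost(2, 70, p)$total, 149.00)
  expect_equal(monthly_state_cost(3, 70, p)$total, 252.13)
  expect_equal(monthly_state_cost(4, 70, p)$total, 380.86)
  # below the drug-benefit age the drug component drops out
  expect_equal(monthly_state_cost(3, 50, p)$total, 172.70)
  expect_equal(monthly_state_cost(1, 50, p)$total, 97.00)

  out <- monthly_state_cost(c(1, 4), c(70, 70), p)
  expect_equal(out$total, out$ed + out$gp + out$outpatient + out$drug)
  expect_equal(out$drug, c(52.00, 208.16))
  expect_error(monthly_state_cost(5, 70, p), "1..4")
})

test_that("utilization-based costs divide 6-month counts by the cycle", {
  expect_equal(monthly_cost_from_utilization(c(ed = 1))$ed, 62.83,
               tolerance = 0.005 / 62.83)
  expect_equal(monthly_cost_from_utilization(c(outpatient = 2))$outpatient,
               97.11, tolerance = 1e-4)
  z <- monthly_cost_from_utilization(c(ed = 0, gp = 0, outpatient = 0))
  expect_equal(z$total, 0)
})

test_that("program costs combine kit, operational and amortized fixed costs", {
  p <- tm_parameters()
  expect_equal(program_monthly_cost("FK", p), 112.23)
  expect_equal(program_monthly_cost("BYOP", p), 63.54)
  expect_equal(program_monthly_cost("BYOE", p), 48.47)
  expect_error(program_monthly_cost("XX", p), "Unknown kit")

  expect_equal(amortized_fixed_cost(p), 102.50)
  expect_equal(amortized_fixed_cost(tm_parameters(tm_site_capacity = 500)),
               205.00)
  expect_equal(amortized_fixed_cost(tm_parameters(tm_fixed_site_cost = 0)), 0)
})

make_paired <- function(cost_std, cost_tm, qaly_std, qaly_tm) {
  n <- length(cost_std)
  dplyr::bind_rows(
    tibble::tibble(patient_id = 1:n, arm = "standard", cost = cost_std,
                   qaly = qaly_std, life_months = 1L, admissions = 0L),
    tibble::tibble(patient_id = 1:n, arm = "telemonitoring", cost = cost_tm,
                   qaly = qaly_tm, life_months = 1L, admissions = 0L))
}

test_that("ICER computation matches the printed deltas and flags dominance", {
  # two patients constructed to give the reference deltas exactly
  res <- make_paired(c(90000, 100000), c(95011, 105011),
                     c(4.7, 5.2), c(5.266, 5.766))
  cea <- compute_icer(res)
  expect_equal(cea$delta_cost, 5011)
  expect_equal(cea$delta_qaly, 0.566)
  expect_equal(cea$icer, 5011 / 0.566) # ~8853.4, prints as 8850 rounded
  expect_identical(cea$classification, "cost_effective_quadrant")

  dom <- compute_icer(make_paired(1000, 900, 1, 1.5))
  expect_identical(dom$classification, "dominant")
  expect_lt(dom$icer, 0) # negative ratio reported alongside the flag

  dotted <- compute_icer(make_paired(1000, 1100, 1, 1))
  expect_identical(dotted$classification, "undefined")
  expect_true(is.na(dotted$icer))

  dominated <- compute_icer(make_paired(1000, 1100, 1.5, 1))
  expect_identical(dominated$classification, "dominated")
})

test_that("Monte Carlo standard errors are sd/sqrt(n)", {
  res <- make_paired(c(0, 2), c(0, 2), c(1, 1), c(1, 1))
  cea <- compute_icer(res)
  expect_equal(cea$by_arm$cost_mcse, c(1, 1)) # sd(0,2)/sqrt(2) = 1
  one <- compute_icer(make_paired(100, 120, 1, 1.1))
  expect_equal(one$by_arm$cost_mcse, c(0, 0)) # single patient: 0 by convention
  expect_equal(one$by_arm$cost, c(100, 120))
})

test_that("the ICER is invariant to a constant cost added to both arms", {
  res <- make_paired(c(100, 200, 300), c(140, 260, 330),
                     c(1, 2, 3), c(1.2, 2.3, 3.4))
  base <- compute_icer(res)
  shifted <- res
  shifted$cost <- shifted$cost + 5000
  expect_equal(compute_icer(shifted)$icer, base$icer)
  expect_equal(compute_icer(shifted)$delta_cost_mcse, base$delta_cost_mcse)
})

test_that("mismatched cohorts are rejected", {
  res <- make_paired(c(100, 200), c(150, 250), c(1, 2), c(1.1, 2.2))
  res$patient_id[res$arm == "telemonitoring"] <- 3:4
  expect_error(compute_icer(res), "different patients")
})

test_that("net monetary benefit matches its definition and sign rule", {
  expect_equal(net_monetary_benefit(5011, 0.566, 0), -5011)
  expect_equal(net_monetary_benefit(5011, 0.566, 50000), 23289)
  expect_equal(net_monetary_benefit(123, 0, 99000), -123)
  # sign agrees with the ICER-vs-WTP comparison whenever dQ > 0
  dc <- c(-500, 200, 900); dq <- c(0.1, 0.05, 0.2); wtp <- 4000
  expect_equal(net_monetary_benefit(dc, dq, wtp) > 0, dc / dq < wtp)
})

test_that("tidiers expose the per-arm table and the incremental row", {
  res <- make_paired(c(100, 200), c(150, 250), c(1, 2), c(1.2, 2.3))
  cea <- compute_icer(res)
  td <- tidy(cea)
  expect_identical(td$arm, c("standard", "telemonitoring"))
  gl <- glance(cea)
  expect_identical(names(gl)[1:5],
                   c("delta_cost", "delta_cost_mcse", "delta_qaly",
                     "delta_qaly_mcse", "icer"))
  expect_equal(gl$delta_cost, 50)
})
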