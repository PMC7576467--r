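# Shared fixtures. Everything is generated in code; expensive reference-case
# objects are memoized so several test files can reuse one computation.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Small parameter set for fast engine tests.
small_params <- function(...) {
  tm_parameters(horizon_months = 60L, cohort_size = 100L, ...)
}

# Parameters with a null intervention: no treatment effect, no program cost.
null_intervention_params <- function(...) {
  tm_parameters(
    rr_mortality = 1, rr_hospitalization = 1,
    tm_fixed_site_cost = 0, tm_operational_monthly = 0,
    kit_monthly_cost = c(FK = 0, BYOP = 0, BYOE = 0), ...)
}

# A two-covariate toy survival model for closed-form checks.
toy_survival_model <- function(baseline = 0.1) {
  list(baseline_annual_hazard = baseline,
       coefficients = tibble::tibble(
         term = c("x1", "x2"), center = c(0, 0),
         coefficient = c(0.5, -0.2)))
}

# Reference-case setup shared by the acceptance tests: cohort, calibrated
# parameters, and the deterministic paired run.
reference_setup <- function() {
  memo("reference", {
    params <- tm_parameters()
    cohort <- generate_cohort(1000, params, seed = 101)
    params <- calibrate_baseline_hazard(cohort, params, target_qaly = 4.95,
                                        seed = 102)
    results <- simulate_cohort(cohort, params, seed = 103)
    list(params = params, cohort = cohort, results = results,
         cea = compute_icer(results))
  })
}

wide_results <- function(results) {
  tidyr::pivot_wider(results, names_from = arm,
                     values_from = c(cost, qaly, life_months, admissions))
}
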