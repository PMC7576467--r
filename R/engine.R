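#' Discount factor for a model cycle
#'
#' `(1 + annual_rate)^(-month / 12)` with no half-cycle correction; costs
#' and utilities accrued in a cycle are discounted at the cycle start.
#'
#' @param month Cycle index (0-based), >= 0.
#' @param annual_rate Annual discount rate, >= 0 (default 0.015).
#' @return Discount factor(s) in (0, 1].
#' @export
#' @examples
#' discount_factor(12, 0.015)  # 1 / 1.015
discount_factor <- function(month, annual_rate = 0.015) {
  stopifnot(all(month >= 0), annual_rate >= 0)
  (1 + annual_rate)^(-month / 12)
}

# Assemble the per-arm vectors the engine consumes. `sampled` may carry
# per-iteration PSA overrides already merged into `params`.
engine_inputs <- function(cohort, params, arm) {
  arm <- match.arg(arm, ARM_LEVELS)
  tm <- arm == "telemonitoring"

  score <- linear_predictor(cohort, params$shfm)
  hazard <- annual_hazard(score, params$shfm)
  rr_m <- if (tm) params$rr_mortality else 1
  p_comm <- monthly_death_probability(hazard, rr_m)
  p_hosp <- if (is.null(params$inhospital_mortality_monthly)) {
    p_comm
  } else {
    rep(params$inhospital_mortality_monthly, nrow(cohort))
  }

  rr_h <- if (tm) params$rr_hospitalization else 1
  admit <- params$hosp_prob_monthly * rr_h
  readmit <- params$readmit_prob_30d *
    (if (params$rr_applies_to_readmission) rr_h else 1)
  if (any(admit > 1) || readmit > 1) {
    warn("(Re)admission probability exceeded 1 after RR scaling; clamped.")
    admit <- pmin(admit, 1)
    readmit <- min(readmit, 1)
  }

  costs <- params$state_cost_components
  program_monthly <- if (tm) {
    unname(params$kit_monthly_cost[cohort$kit_type]) +
      params$tm_operational_monthly
  } else {
    rep(0, nrow(cohort))
  }
  if (anyNA(program_monthly)) {
    abort("Every patient needs a kit_type before simulating the telemonitoring arm; see assign_deployment().")
  }

  list(
    init_class = as.integer(cohort$nyha_class),
    p_death_comm = p_comm,
    p_death_hosp = p_hosp,
    admit_prob = unname(admit),
    readmit_prob = readmit,
    trans_cum = t(apply(params$nyha_transition_matrix, 1, cumsum)),
    cost_nondrug = unname(rowSums(costs[, c("ed", "gp", "outpatient")])),
    cost_drug = unname(costs[, "drug"]),
    age0 = cohort$age_years,
    drug_age_threshold = params$drug_age_threshold,
    utility = unname(params$utilities_by_class),
    hosp_disutility = params$hosp_disutility,
    admission_cost = params$hosp_cost_mean,
    program_monthly = program_monthly,
    program_entry_cost = if (tm) amortized_fixed_cost(params) else 0,
    discount = discount_factor(seq_len(params$horizon_months) - 1,
                               params$discount_rate_annual),
    readmit_window = params$readmit_window_months
  )
}

# Uniform draw array shared by both arms: n x 3 x T, consuming the current
# RNG stream.
make_draws <- function(n, horizon_months) {
  array(runif(n * 3 * horizon_months), dim = c(n, 3, horizon_months))
}

run_arm <- function(cohort, params, arm, draws) {
  inp <- engine_inputs(cohort, params, arm)
  res <- engine_run(inp$init_class, inp$p_death_comm, inp$p_death_hosp,
                    inp$admit_prob, inp$readmit_prob, inp$trans_cum,
                    inp$cost_nondrug, inp$cost_drug, inp$age0,
                    inp$drug_age_threshold, inp$utility, inp$hosp_disutility,
                    inp$admission_cost, inp$program_monthly,
                    inp$program_entry_cost, inp$discount, inp$readmit_window,
                    as.numeric(draws))
  tibble(
    patient_id = cohort$patient_id,
    arm = arm,
    cost = res[, "cost"],
    qaly = res[, "qaly"],
    life_months = as.integer(res[, "life_months"]),
    admissions = as.integer(res[, "admissions"]))
}

#' Simulate a cohort through both care arms
#'
#' Runs every patient through the 7-state monthly microsimulation twice —
#' once under standard care and once under telemonitoring — using common
#' random numbers: both arms consume the identical per-patient draw stream,
#' so arm differences reflect only the treatment effects and program costs.
#'
#' @param cohort Tibble from [generate_cohort()] (kit types assigned).
#' @param params A `tm_parameters` object.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param arms Arms to simulate (default both).
#' @return A tibble with one row per patient and arm: `patient_id`, `arm`,
#'   discounted `cost` (CAD), discounted `qaly`, `life_months`,
#'   `admissions`.
#' @export
#' @examples
#' params <- tm_parameters()
#' cohort <- generate_cohort(50, params, seed = 1)
#' res <- simulate_cohort(cohort, params, seed = 2)
#' dplyr::count(res, arm)
simulate_cohort <- function(cohort, params = tm_parameters(), seed = NULL,
                            arms = ARM_LEVELS) {
  if (nrow(cohort) == 0) abort("Cohort is empty.")
  if (!is.null(seed)) set.seed(seed)
  draws <- make_draws(nrow(cohort), params$horizon_months)
  dplyr::bind_rows(lapply(arms, function(a) run_arm(cohort, params, a, draws)))
}

#' Simulate a single patient in one arm
#'
#' Convenience wrapper over the engine for a one-row cohort.
#'
#' @param profile One-row tibble of patient characteristics.
#' @param params A `tm_parameters` object.
#' @param arm `"standard"` or `"telemonitoring"`.
#' @param seed Optional integer seed.
#' @return A one-row result tibble (see [simulate_cohort()]).
#' @export
simulate_patient <- function(profile, params = tm_parameters(),
                             arm = "standard", seed = NULL) {
  stopifnot(nrow(profile) == 1)
  if (!is.null(seed)) set.seed(seed)
  draws <- make_draws(1, params$horizon_months)
  run_arm(profile, params, match.arg(arm, ARM_LEVELS), draws)
}

# ---------------------------------------------------------------------------
# R reference implementation of the cycle step. Slow but transparent; the
# test suite checks that the C++ engine reproduces it draw-for-draw.

#' Advance one patient by one model cycle (reference implementation)
#'
#' Event resolution order within a cycle: accrual for the state occupied,
#' then death, then discharge (hospital survivors return to the NYHA class
#' held at admission), then readmission or index admission, then NYHA class
#' transition. Exactly three uniform draws are consumed per cycle.
#'
#' This is the plain-R specification of the engine semantics; the compiled
#' engine used by [simulate_cohort()] must agree with it exactly.
#'
#' @param state List with `current` (one of `"NYHA1"`..`"NYHA4"`,
#'   `"HOSP_INDEX"`, `"HOSP_READMIT"`, `"DEAD"`), `resident_nyha` (1..4),
#'   `months_since_discharge` (`NA` until first discharge), `month`
#'   (0-based cycle index) and `age` (years).
#' @param inputs Engine inputs for one patient and arm, as built by the
#'   internal `engine_inputs()` restricted to that patient.
#' @param draws Numeric vector of 3 uniforms for this cycle.
#' @return List with the updated `state`, the cycle's discounted `cost`,
#'   discounted `qaly` increment, and logical `admitted`.
#' @keywords internal
step_patient <- function(state, inputs, draws) {
  if (state$current == "DEAD") abort("DEAD is absorbing; do not step it.")
  stopifnot(length(draws) >= 3)
  in_hospital <- state$current %in% c("HOSP_INDEX", "HOSP_READMIT")
  cls <- if (in_hospital) state$resident_nyha
         else match(state$current, STATE_LEVELS)
  disc <- inputs$discount[state$month + 1]

  cost <- inputs$cost_nondrug[cls] + inputs$program_monthly[1]
  if (state$age >= inputs$drug_age_threshold) {
    cost <- cost + inputs$cost_drug[cls]
  }
  utility <- inputs$utility[cls]
  if (in_hospital) {
    cost <- cost + inputs$admission_cost
    utility <- utility - inputs$hosp_disutility
  }

  admitted <- FALSE
  if (in_hospital) {
    if (draws[1] < inputs$p_death_hosp[1]) {
      state$current <- "DEAD"
    } else {
      state$current <- STATE_LEVELS[state$resident_nyha]
      state$months_since_discharge <- 0
    }
  } else {
    if (draws[1] < inputs$p_death_comm[1]) {
      state$current <- "DEAD"
    } else {
      elevated <- !is.na(state$months_since_discharge) &&
        state$months_since_discharge < inputs$readmit_window
      p_admit <- if (elevated) inputs$readmit_prob else inputs$admit_prob[cls]
      if (draws[2] < p_admit) {
        state$resident_nyha <- cls
        state$current <- if (elevated) "HOSP_READMIT" else "HOSP_INDEX"
        admitted <- TRUE
      } else {
        state$current <- STATE_LEVELS[which(draws[3] < inputs$trans_cum[cls, ])[1]]
        if (!is.na(state$months_since_discharge)) {
          state$months_since_discharge <- state$months_since_discharge + 1
        }
      }
    }
  }
  state$month <- state$month + 1
  state$age <- state$age + 1 / 12

  list(state = state, cost = disc * cost, qaly = disc * utility / 12,
       admitted = admitted)
}

# Full R mirror of engine_run for one arm; consumes the same draw layout.
simulate_arm_r <- function(cohort, params, arm, draws) {
  inp <- engine_inputs(cohort, params, arm)
  n <- nrow(cohort)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    pinp <- inp
    pinp$p_death_comm <- inp$p_death_comm[i]
    pinp$p_death_hosp <- inp$p_death_hosp[i]
    pinp$program_monthly <- inp$program_monthly[i]
    state <- list(current = STATE_LEVELS[inp$init_class[i]],
                  resident_nyha = inp$init_class[i],
                  months_since_discharge = NA,
                  month = 0L,
                  age = inp$age0[i])
    cost <- inp$program_entry_cost
    qaly <- 0
    life <- 0L
    adm <- 0L
    for (t in seq_len(params$horizon_months)) {
      step <- step_patient(state, pinp, draws[i, , t])
      cost <- cost + step$cost
      qaly <- qaly + step$qaly
      life <- life + 1L
      adm <- adm + step$admitted
      state <- step$state
      if (state$current == "DEAD") break
    }
    out[[i]] <- tibble(patient_id = cohort$patient_id[i], arm = arm,
                       cost = cost, qaly = qaly, life_months = life,
                       admissions = adm)
  }
  dplyr::bind_rows(out)
}
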