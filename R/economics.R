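#' Monthly cost of living with heart failure, by NYHA class
#'
#' Assembles the monthly state cost from its components: emergency
#' department, general practitioner, outpatient, and drug costs, with the
#' drug component included only for patients at or above the public
#' drug-benefit age threshold (65 years). NYHA IV components equal NYHA III
#' except the drug component.
#'
#' @param nyha_class Integer vector of classes in 1..4.
#' @param age Ages in years (recycled against `nyha_class`).
#' @param params A `tm_parameters` object.
#' @return A tibble with columns `nyha_class`, `age`, `ed`, `gp`,
#'   `outpatient`, `drug`, `total` (CAD/month).
#' @export
#' @examples
#' monthly_state_cost(4, 70, tm_parameters())$total  # 380.86
#' monthly_state_cost(3, 50, tm_parameters())$total  # 172.70
monthly_state_cost <- function(nyha_class, age, params = tm_parameters()) {
  if (any(!nyha_class %in% 1:4)) abort("nyha_class must be in 1..4.")
  stopifnot(all(age >= 0))
  comp <- params$state_cost_components[nyha_class, , drop = FALSE]
  drug <- ifelse(age >= params$drug_age_threshold, comp[, "drug"], 0)
  tibble(
    nyha_class = as.integer(nyha_class),
    age = age,
    ed = unname(comp[, "ed"]),
    gp = unname(comp[, "gp"]),
    outpatient = unname(comp[, "outpatient"]),
    drug = unname(drug)
  ) |>
    dplyr::mutate(total = .data$ed + .data$gp + .data$outpatient + .data$drug)
}

#' Monthly state cost rebuilt from service utilization
#'
#' Multiplies 6-month utilization counts by unit costs and converts to a
#' monthly rate (`count * unit_cost / 6`). This is the route the
#' probabilistic analysis can use to rebuild state costs from sampled
#' utilization counts.
#'
#' @param visits_per_6mo Named numeric vector of 6-month visit counts over
#'   any of `ed`, `gp`, `outpatient`.
#' @param unit_costs Named vector of unit costs (defaults from the
#'   parameter set: ED 377.00, GP 77.20, outpatient 291.33 CAD).
#' @param drug_monthly Monthly drug cost to add (0 by default; gated by age
#'   elsewhere).
#' @return A one-row tibble with `ed`, `gp`, `outpatient`, `drug`, `total`
#'   (CAD/month).
#' @export
#' @examples
#' monthly_cost_from_utilization(c(ed = 1))$ed        # 377 / 6 = 62.83
#' monthly_cost_from_utilization(c(outpatient = 2))$outpatient  # 97.11
monthly_cost_from_utilization <- function(visits_per_6mo,
                                          unit_costs = tm_parameters()$unit_costs,
                                          drug_monthly = 0) {
  stopifnot(all(visits_per_6mo >= 0))
  counts <- c(ed = 0, gp = 0, outpatient = 0)
  counts[names(visits_per_6mo)] <- visits_per_6mo
  comp <- counts * unit_costs[names(counts)] / 6
  tibble(ed = unname(comp["ed"]), gp = unname(comp["gp"]),
         outpatient = unname(comp["outpatient"]), drug = drug_monthly,
         total = sum(comp) + drug_monthly)
}

#' Monthly telemonitoring program cost per patient
#'
#' Kit rental cost (Full Kit, Bring Your Own Phone, or Bring Your Own
#' Everything) plus the per-patient operational cost of the nurse-led
#' program.
#'
#' @param kit_type Character vector over `"FK"`, `"BYOP"`, `"BYOE"`.
#' @param params A `tm_parameters` object.
#' @return Monthly cost(s), CAD.
#' @export
#' @examples
#' program_monthly_cost("FK")    # 67.56 + 44.67 = 112.23
#' program_monthly_cost("BYOE")  # 48.47
program_monthly_cost <- function(kit_type, params = tm_parameters()) {
  if (any(!kit_type %in% KIT_TYPES)) {
    abort(paste0("Unknown kit type; expected one of ",
                 paste(KIT_TYPES, collapse = ", ")))
  }
  unname(params$kit_monthly_cost[kit_type]) + params$tm_operational_monthly
}

#' Amortized program fixed cost per patient
#'
#' One-time per-patient share of the site implementation fixed cost, i.e.
#' fixed cost divided by the site capacity the implementation was budgeted
#' for; charged at program entry in the telemonitoring arm.
#'
#' @param params A `tm_parameters` object.
#' @return Cost per patient, CAD.
#' @export
#' @examples
#' amortized_fixed_cost(tm_parameters())  # 102500 / 1000 = 102.50
amortized_fixed_cost <- function(params = tm_parameters()) {
  stopifnot(params$tm_site_capacity > 0)
  params$tm_fixed_site_cost / params$tm_site_capacity
}

#' Incremental cost-effectiveness from paired arm results
#'
#' Summarizes paired per-patient results into per-arm means with Monte
#' Carlo standard errors (sd/sqrt(n)), incremental cost and QALY (with
#' paired MCSEs, exploiting common random numbers), the ICER, and a
#' dominance classification: `"cost_effective_quadrant"` (costlier and more
#' effective; the ICER is the relevant statistic), `"dominant"` (cheaper
#' and more effective), `"dominated"` (costlier and less effective), or
#' `"cheaper_less_effective"`. A negative ICER is never reported bare: it
#' is always accompanied by the classification. When the incremental QALY
#' is exactly zero the ICER is undefined (`NA`).
#'
#' @param results Paired tibble from [simulate_cohort()] with both arms for
#'   the same patients.
#' @param comparator Name of the comparator arm (default `"standard"`).
#' @return A `tm_cea` object; see [tidy.tm_cea()] and [glance.tm_cea()].
#' @export
compute_icer <- function(results, comparator = "standard") {
  arms <- unique(results$arm)
  if (length(arms) != 2) abort("Results must contain exactly two arms.")
  intervention <- setdiff(arms, comparator)
  if (length(intervention) != 1) {
    abort(paste0("Comparator arm '", comparator, "' not found."))
  }
  wide_c <- dplyr::filter(results, .data$arm == comparator)
  wide_i <- dplyr::filter(results, .data$arm == intervention)
  if (!identical(sort(wide_c$patient_id), sort(wide_i$patient_id))) {
    abort("The two arms cover different patients; cannot pair results.")
  }
  wide_c <- dplyr::arrange(wide_c, .data$patient_id)
  wide_i <- dplyr::arrange(wide_i, .data$patient_id)
  n <- nrow(wide_c)
  mcse <- function(x) if (length(x) < 2) 0 else sd(x) / sqrt(length(x))

  by_arm <- tibble(
    arm = c(comparator, intervention),
    n = n,
    cost = c(mean(wide_c$cost), mean(wide_i$cost)),
    cost_mcse = c(mcse(wide_c$cost), mcse(wide_i$cost)),
    qaly = c(mean(wide_c$qaly), mean(wide_i$qaly)),
    qaly_mcse = c(mcse(wide_c$qaly), mcse(wide_i$qaly)),
    life_months = c(mean(wide_c$life_months), mean(wide_i$life_months)),
    admissions = c(mean(wide_c$admissions), mean(wide_i$admissions)))

  dc <- wide_i$cost - wide_c$cost
  dq <- wide_i$qaly - wide_c$qaly
  delta_cost <- mean(dc)
  delta_qaly <- mean(dq)
  classification <- dplyr::case_when(
    delta_qaly > 0 & delta_cost >= 0 ~ "cost_effective_quadrant",
    delta_qaly > 0 & delta_cost < 0 ~ "dominant",
    delta_qaly < 0 & delta_cost > 0 ~ "dominated",
    delta_qaly < 0 & delta_cost <= 0 ~ "cheaper_less_effective",
    TRUE ~ "undefined")
  icer <- if (delta_qaly == 0) NA_real_ else delta_cost / delta_qaly

  structure(
    list(by_arm = by_arm,
         comparator = comparator,
         intervention = intervention,
         n_patients = n,
         delta_cost = delta_cost,
         delta_cost_mcse = mcse(dc),
         delta_qaly = delta_qaly,
         delta_qaly_mcse = mcse(dq),
         icer = icer,
         classification = classification),
    class = "tm_cea")
}

#' @export
print.tm_cea <- function(x, ...) {
  cat("<tm_cea>", x$intervention, "vs", x$comparator,
      sprintf("(n = %d)\n", x$n_patients))
  print(x$by_arm)
  cat(sprintf("  incremental cost %.0f CAD (MCSE %.0f), incremental QALY %.3f (MCSE %.3f)\n",
              x$delta_cost, x$delta_cost_mcse, x$delta_qaly, x$delta_qaly_mcse))
  if (is.na(x$icer)) {
    cat("  ICER undefined (zero incremental QALY)\n")
  } else {
    cat(sprintf("  ICER %.0f CAD/QALY [%s]\n", x$icer, x$classification))
  }
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = wtp * delta_qaly - delta_cost`. Positive iff the intervention is
#' cost-effective at the willingness-to-pay `wtp`; for positive incremental
#' QALYs this is equivalent to `ICER < wtp`.
#'
#' @param delta_cost Incremental cost (CAD).
#' @param delta_qaly Incremental QALYs.
#' @param wtp Willingness to pay per QALY (CAD), >= 0.
#' @return Net monetary benefit (CAD).
#' @export
#' @examples
#' net_monetary_benefit(5011, 0.566, 50000)  # 23289
net_monetary_benefit <- function(delta_cost, delta_qaly, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * delta_qaly - delta_cost
}
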