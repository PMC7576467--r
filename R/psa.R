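#' Probabilistic sensitivity analysis
#'
#' Second-order PSA: for each iteration one parameter set is drawn from the
#' distribution specifications and held fixed while the whole cohort is
#' simulated through both arms. Within an iteration the two arms share one
#' patient-level draw stream (common random numbers); across iterations the
#' patient-level draws are refreshed, so the iteration distribution combines
#' parameter uncertainty with first-order Monte Carlo noise rather than
#' conditioning the whole analysis on a single draw realization. With
#' all-fixed specifications the first iteration reproduces the
#' deterministic run exactly (same seed, same draw stream).
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param params A `tm_parameters` object.
#' @param n_iterations Number of PSA iterations (default
#'   `params$psa_iterations`).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param specs Distribution specifications (default
#'   [default_psa_specs()]).
#' @return A `tm_psa` tibble with one row per iteration: per-arm mean cost
#'   and QALY, `delta_cost`, `delta_qaly`, and the cost-utility plane
#'   `quadrant`.
#' @export
run_psa <- function(cohort, params = tm_parameters(),
                    n_iterations = params$psa_iterations, seed = NULL,
                    specs = default_psa_specs(params)) {
  stopifnot(n_iterations >= 1)
  if (nrow(cohort) == 0) abort("Cohort is empty.")
  if (!is.null(seed)) set.seed(seed)

  rows <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    p_it <- sample_parameters(params, specs)
    draws <- make_draws(nrow(cohort), params$horizon_months)
    std <- run_arm(cohort, p_it, "standard", draws)
    tmg <- run_arm(cohort, p_it, "telemonitoring", draws)
    rows[[it]] <- tibble(
      iteration = it,
      cost_standard = mean(std$cost),
      cost_telemonitoring = mean(tmg$cost),
      qaly_standard = mean(std$qaly),
      qaly_telemonitoring = mean(tmg$qaly),
      delta_cost = mean(tmg$cost) - mean(std$cost),
      delta_qaly = mean(tmg$qaly) - mean(std$qaly))
  }
  out <- dplyr::bind_rows(rows)
  out$quadrant <- dplyr::case_when(
    out$delta_qaly > 0 & out$delta_cost >= 0 ~ "costlier_more_effective",
    out$delta_qaly > 0 & out$delta_cost < 0 ~ "cheaper_more_effective",
    out$delta_qaly <= 0 & out$delta_cost >= 0 ~ "costlier_less_effective",
    TRUE ~ "cheaper_less_effective")
  class(out) <- c("tm_psa", class(out))
  out
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the fraction of PSA iterations with
#' positive net monetary benefit (`wtp * delta_qaly - delta_cost > 0`),
#' i.e. the probability that the intervention is cost-effective.
#'
#' @param psa A `tm_psa` tibble (or any tibble with `delta_cost` and
#'   `delta_qaly`).
#' @param wtp_grid Nonnegative willingness-to-pay values (CAD/QALY).
#' @return A `tm_ceac` tibble with columns `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 1000)) {
  if (nrow(psa) == 0) abort("Need at least one PSA iteration.")
  stopifnot(all(wtp_grid >= 0))
  out <- tibble(
    wtp = wtp_grid,
    probability = vapply(wtp_grid, function(l) {
      mean(net_monetary_benefit(psa$delta_cost, psa$delta_qaly, l) > 0)
    }, numeric(1)))
  class(out) <- c("tm_ceac", class(out))
  out
}

#' Probability of cost-effectiveness at one threshold
#'
#' @param psa A `tm_psa` tibble.
#' @param wtp Willingness to pay per QALY (default 50,000 CAD).
#' @return A probability in `[0, 1]`.
#' @export
prob_cost_effective <- function(psa, wtp = 50000) {
  ceac(psa, wtp)$probability
}
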