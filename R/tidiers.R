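#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cost-effectiveness result
#'
#' One row per arm: mean discounted cost and QALY with Monte Carlo standard
#' errors, mean life months and admissions — the per-arm layout of a
#' standard deterministic-results table.
#'
#' @param x A `tm_cea` object from [compute_icer()].
#' @param ... Unused.
#' @return A tibble with one row per arm.
#' @export
tidy.tm_cea <- function(x, ...) {
  x$by_arm
}

#' Summarize a cost-effectiveness result in one row
#'
#' @param x A `tm_cea` object.
#' @param ... Unused.
#' @return A one-row tibble: incremental cost and QALY with paired MCSEs,
#'   ICER, dominance classification and cohort size.
#' @export
glance.tm_cea <- function(x, ...) {
  tibble(
    delta_cost = x$delta_cost,
    delta_cost_mcse = x$delta_cost_mcse,
    delta_qaly = x$delta_qaly,
    delta_qaly_mcse = x$delta_qaly_mcse,
    icer = x$icer,
    classification = x$classification,
    n_patients = x$n_patients)
}

#' Tidy PSA iterations
#'
#' @param x A `tm_psa` tibble.
#' @param ... Unused.
#' @return The iteration-level tibble (iteration, per-arm means, deltas,
#'   quadrant) as a plain tibble.
#' @export
tidy.tm_psa <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Summarize a PSA in one row
#'
#' @param x A `tm_psa` tibble.
#' @param wtp Willingness-to-pay threshold for the acceptance probability
#'   (default 50,000 CAD/QALY).
#' @param ... Unused.
#' @return A one-row tibble: iteration count, mean deltas, probability of
#'   cost-effectiveness at `wtp`, and quadrant proportions.
#' @export
glance.tm_psa <- function(x, wtp = 50000, ...) {
  tibble(
    n_iterations = nrow(x),
    mean_delta_cost = mean(x$delta_cost),
    mean_delta_qaly = mean(x$delta_qaly),
    prob_cost_effective = prob_cost_effective(x, wtp),
    wtp = wtp,
    prop_costlier_more_effective =
      mean(x$quadrant == "costlier_more_effective"),
    prop_cheaper_more_effective =
      mean(x$quadrant == "cheaper_more_effective"),
    prop_costlier_less_effective =
      mean(x$quadrant == "costlier_less_effective"),
    prop_cheaper_less_effective =
      mean(x$quadrant == "cheaper_less_effective"))
}
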