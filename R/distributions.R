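#' Parameter uncertainty distributions for the probabilistic analysis
#'
#' Constructors that turn printed summary statistics (means and SDs, point
#' estimates with 95% intervals, transition rows) into sampling
#' distributions, as used by the second-order probabilistic sensitivity
#' analysis: gamma for right-skewed costs, beta for probabilities and
#' utilities, Dirichlet for transition-matrix rows, log-normal for relative
#' risks, and negative binomial for utilization counts.
#'
#' @name tm_distributions
NULL

new_dist <- function(family, ..., provenance = NULL) {
  structure(list(family = family, ..., provenance = provenance),
            class = "tm_dist")
}

#' @export
print.tm_dist <- function(x, ...) {
  pars <- x[setdiff(names(x), c("family", "provenance"))]
  cat("<tm_dist>", x$family,
      paste(names(pars), signif(unlist(pars), 6), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' @rdname tm_distributions
#' @param mean,sd Moments of a gamma distribution (both > 0); method of
#'   moments gives `shape = mean^2/sd^2`, `scale = sd^2/mean`.
#' @return A `tm_dist` specification.
#' @export
#' @examples
#' dist_gamma_moments(8908, 16867)
dist_gamma_moments <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) abort("Gamma moments must be positive.")
  new_dist("gamma", shape = mean^2 / sd^2, scale = sd^2 / mean,
           provenance = list(mean = mean, sd = sd))
}

#' @rdname tm_distributions
#' @param point Point estimate; for the log-normal it is the geometric
#'   median, `mu = log(point)`.
#' @param lower,upper 95% interval bounds;
#'   `sigma = (log(upper) - log(lower)) / (2 * 1.959964)`.
#' @export
#' @examples
#' dist_lognormal_ci(0.81, 0.70, 0.94)
dist_lognormal_ci <- function(point, lower, upper) {
  if (!(lower > 0 && lower <= point && point <= upper)) {
    abort("Require 0 < lower <= point <= upper for a log-normal CI.")
  }
  new_dist("lognormal", mu = log(point),
           sigma = (log(upper) - log(lower)) / (2 * qnorm(0.975)),
           provenance = list(point = point, lower = lower, upper = upper))
}

#' @rdname tm_distributions
#' @details `dist_beta_range()` treats the point estimate as the mean and
#'   the printed range as a 95% interval width, `sd = (upper - lower) /
#'   (2 * 1.959964)`; alpha and beta follow by method of moments. Printed
#'   ranges with the point at one endpoint are used as printed. A
#'   zero-width range collapses to a fixed value.
#' @export
#' @examples
#' dist_beta_range(0.5, 0.4, 0.6)
dist_beta_range <- function(point, lower, upper) {
  if (point < 0 || point > 1) abort("Beta point estimate must be in [0, 1].")
  if (lower > upper) {
    tmp <- lower; lower <- upper; upper <- tmp
  }
  s <- (upper - lower) / (2 * qnorm(0.975))
  if (s == 0) return(dist_fixed(point))
  if (s^2 >= point * (1 - point)) {
    abort("Range too wide for a beta with this mean; sd^2 >= mean(1-mean).")
  }
  nu <- point * (1 - point) / s^2 - 1
  new_dist("beta", alpha = point * nu, beta = (1 - point) * nu,
           provenance = list(point = point, lower = lower, upper = upper))
}

#' @rdname tm_distributions
#' @param row Four transition probabilities summing to 1.
#' @param concentration_n Effective sample size; concentrations are
#'   `row * concentration_n`, with zero cells floored at 1e-6 to keep the
#'   distribution proper.
#' @export
#' @examples
#' dist_dirichlet_row(c(0.977, 0.019, 0.004, 0), 500)
dist_dirichlet_row <- function(row, concentration_n = 500) {
  if (abs(sum(row) - 1) > 1e-9 || any(row < 0)) {
    abort("Dirichlet row must be nonnegative and sum to 1.")
  }
  if (concentration_n <= 0) abort("concentration_n must be > 0.")
  new_dist("dirichlet", alpha = pmax(row * concentration_n, 1e-6),
           provenance = list(row = row, concentration_n = concentration_n))
}

#' @rdname tm_distributions
#' @param value Fixed (degenerate) value.
#' @export
dist_fixed <- function(value) {
  new_dist("fixed", value = value)
}

#' Fit a negative binomial to utilization counts by maximum likelihood
#'
#' Wraps [fitdistrplus::fitdist()] in the size/mean (`mu`)
#' parameterization. Equidispersed or underdispersed counts (variance <=
#' mean), where the dispersion estimate diverges, fall back to a Poisson
#' fit with a warning.
#'
#' @param counts Nonnegative integer counts; at least 2 observations, not
#'   all zero.
#' @return A `tm_dist` of family `"negbin"` (fields `size`, `mu`) or
#'   `"poisson"` (field `lambda`) on fallback.
#' @export
fit_utilization_negbin <- function(counts) {
  if (length(counts) < 2) abort("Need at least 2 observations.")
  if (all(counts == 0)) abort("All-zero counts are degenerate.")
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Counts must be nonnegative integers.")
  }
  m <- mean(counts)
  if (var(counts) <= m) {
    warn("Counts not overdispersed; falling back to a Poisson fit.")
    return(new_dist("poisson", lambda = m,
                    provenance = list(n = length(counts))))
  }
  fit <- fitdistrplus::fitdist(as.integer(counts), "nbinom")
  new_dist("negbin",
           size = unname(fit$estimate["size"]),
           mu = unname(fit$estimate["mu"]),
           loglik = fit$loglik,
           provenance = list(n = length(counts)))
}

#' Draw from a distribution specification
#'
#' @param spec A `tm_dist` object.
#' @param n Number of draws.
#' @return For a Dirichlet spec, an `n x 4` matrix of simplex rows;
#'   otherwise a numeric vector of length `n`.
#' @export
dist_sample <- function(spec, n = 1) {
  switch(
    spec$family,
    fixed = rep(spec$value, n),
    gamma = rgamma(n, shape = spec$shape, scale = spec$scale),
    beta = rbeta(n, spec$alpha, spec$beta),
    lognormal = rlnorm(n, spec$mu, spec$sigma),
    negbin = rnbinom(n, size = spec$size, mu = spec$mu),
    poisson = stats::rpois(n, spec$lambda),
    dirichlet = {
      g <- matrix(rgamma(n * length(spec$alpha), shape = spec$alpha),
                  nrow = n, byrow = TRUE)
      g / rowSums(g)
    },
    abort(paste0("Unknown distribution family: ", spec$family)))
}

# ---------------------------------------------------------------------------
# Default PSA specification: everything whose printed distribution column is
# not "Fixed" is sampled.

#' Default distribution specifications for the probabilistic analysis
#'
#' One spec per sampled parameter, built from the printed moments and 95%
#' ranges in the parameter set: beta for utilities, hospitalization and
#' readmission probabilities and the hospitalization disutility; Dirichlet
#' (effective sample size `params$dirichlet_n`) for each NYHA transition
#' row; gamma for the per-admission hospitalization cost and the ED,
#' outpatient and drug monthly cost components (the GP fee is a fixed
#' schedule price); log-normal for the two relative risks. Setting
#' `fixed = TRUE` returns the degenerate specification under which the PSA
#' reproduces the deterministic run exactly.
#'
#' @param params A `tm_parameters` object.
#' @param fixed If `TRUE`, every spec is the fixed point estimate.
#' @return Named list of `tm_dist` specs (lists of specs for per-class
#'   parameters).
#' @export
default_psa_specs <- function(params, fixed = FALSE) {
  fx <- dist_fixed
  cost_sd_ratio_drug <- params$drug_cost_6mo_sd / params$drug_cost_6mo_mean
  comp <- params$state_cost_components
  # monthly component SD implied by the unit-cost SD at the same utilization:
  # cost = count * unit / 6  =>  sd(cost) = cost * sd(unit) / unit
  ed_sd <- comp[, "ed"] * params$unit_cost_sds["ed"] / params$unit_costs["ed"]
  outp_sd <- comp[, "outpatient"] * params$unit_cost_sds["outpatient"] /
    params$unit_costs["outpatient"]
  gamma_or_fixed <- function(mean, sd) {
    if (mean > 0 && sd > 0) dist_gamma_moments(mean, sd) else fx(mean)
  }

  specs <- list(
    utilities_by_class = lapply(1:4, function(k) {
      dist_beta_range(params$utilities_by_class[k],
                      params$utilities_range[k, "lower"],
                      params$utilities_range[k, "upper"])
    }),
    hosp_prob_monthly = lapply(1:4, function(k) {
      dist_beta_range(params$hosp_prob_monthly[k],
                      params$hosp_prob_range[k, "lower"],
                      params$hosp_prob_range[k, "upper"])
    }),
    readmit_prob_30d = dist_beta_range(params$readmit_prob_30d,
                                       params$readmit_prob_range["lower"],
                                       params$readmit_prob_range["upper"]),
    hosp_disutility = dist_beta_range(params$hosp_disutility,
                                      params$hosp_disutility_range["lower"],
                                      params$hosp_disutility_range["upper"]),
    nyha_transition_matrix = lapply(1:4, function(k) {
      dist_dirichlet_row(params$nyha_transition_matrix[k, ],
                         params$dirichlet_n)
    }),
    hosp_cost_mean = dist_gamma_moments(params$hosp_cost_mean,
                                        params$hosp_cost_sd),
    rr_mortality = dist_lognormal_ci(params$rr_mortality,
                                     params$rr_mortality_ci["lower"],
                                     params$rr_mortality_ci["upper"]),
    rr_hospitalization = dist_lognormal_ci(
      params$rr_hospitalization,
      params$rr_hospitalization_ci["lower"],
      params$rr_hospitalization_ci["upper"]),
    cost_ed = lapply(1:4, function(k) {
      gamma_or_fixed(comp[k, "ed"], unname(ed_sd[k]))
    }),
    cost_outpatient = lapply(1:4, function(k) {
      gamma_or_fixed(comp[k, "outpatient"], unname(outp_sd[k]))
    }),
    cost_drug = lapply(1:4, function(k) {
      gamma_or_fixed(comp[k, "drug"], comp[k, "drug"] * cost_sd_ratio_drug)
    })
  )

  if (fixed) specs <- fix_specs(specs, params)
  specs
}

fix_specs <- function(specs, params) {
  list(
    utilities_by_class = lapply(1:4, function(k) dist_fixed(params$utilities_by_class[[k]])),
    hosp_prob_monthly = lapply(1:4, function(k) dist_fixed(params$hosp_prob_monthly[[k]])),
    readmit_prob_30d = dist_fixed(params$readmit_prob_30d),
    hosp_disutility = dist_fixed(params$hosp_disutility),
    nyha_transition_matrix = lapply(1:4, function(k) {
      new_dist("fixed", value = params$nyha_transition_matrix[k, ])
    }),
    hosp_cost_mean = dist_fixed(params$hosp_cost_mean),
    rr_mortality = dist_fixed(params$rr_mortality),
    rr_hospitalization = dist_fixed(params$rr_hospitalization),
    cost_ed = lapply(1:4, function(k) dist_fixed(params$state_cost_components[k, "ed"])),
    cost_outpatient = lapply(1:4, function(k) dist_fixed(params$state_cost_components[k, "outpatient"])),
    cost_drug = lapply(1:4, function(k) dist_fixed(params$state_cost_components[k, "drug"]))
  )
}

#' Sample one parameter set from the PSA specifications
#'
#' Draws every non-fixed parameter from its distribution, clamps sampled
#' probabilities and utilities to `[0, 1]`, and returns a valid parameter
#' set. Deterministic given the RNG state; with all-fixed specs the input
#' is returned unchanged.
#'
#' @param params A `tm_parameters` object.
#' @param specs Specifications from [default_psa_specs()].
#' @return A new `tm_parameters` object with sampled values.
#' @export
sample_parameters <- function(params, specs = default_psa_specs(params)) {
  draw1 <- function(spec) {
    if (spec$family == "fixed") return(spec$value)
    dist_sample(spec, 1)
  }
  clamp01 <- function(x) pmin(pmax(x, 0), 1)

  out <- params
  out$utilities_by_class[] <-
    clamp01(vapply(specs$utilities_by_class, draw1, numeric(1)))
  out$hosp_prob_monthly[] <-
    clamp01(vapply(specs$hosp_prob_monthly, draw1, numeric(1)))
  out$readmit_prob_30d <- clamp01(draw1(specs$readmit_prob_30d))
  out$hosp_disutility <- clamp01(draw1(specs$hosp_disutility))
  tmat <- t(vapply(specs$nyha_transition_matrix, function(s) {
    if (s$family == "fixed") s$value else as.numeric(dist_sample(s, 1))
  }, numeric(4)))
  dimnames(tmat) <- dimnames(params$nyha_transition_matrix)
  out$nyha_transition_matrix <- tmat / rowSums(tmat)
  out$hosp_cost_mean <- draw1(specs$hosp_cost_mean)
  out$rr_mortality <- draw1(specs$rr_mortality)
  out$rr_hospitalization <- draw1(specs$rr_hospitalization)
  comp <- params$state_cost_components
  comp[, "ed"] <- vapply(specs$cost_ed, draw1, numeric(1))
  comp[, "outpatient"] <- vapply(specs$cost_outpatient, draw1, numeric(1))
  comp[, "drug"] <- vapply(specs$cost_drug, draw1, numeric(1))
  out$state_cost_components <- comp
  out
}
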