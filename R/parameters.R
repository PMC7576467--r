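#' Model parameters for the telemonitoring cost-utility model
#'
#' Builds the full parameter set of the microsimulation: monthly NYHA
#' transition probabilities, hospitalization and readmission probabilities,
#' state utilities and hospitalization disutility, monthly state cost
#' components (emergency department, general practitioner, outpatient, and
#' age-gated drug costs), hospitalization costs, telemonitoring program costs
#' (per-kit monthly, operational, and amortized site fixed cost), treatment
#' effects (relative risks for all-cause mortality and hospitalization),
#' discounting, horizon, the survival-score coefficient set, and the cohort
#' generator's marginal moments, correlation matrix, NYHA cutpoints and clip
#' bounds. All costs are 2019 Canadian dollars.
#'
#' Defaults can be overridden by passing named values, e.g.
#' `tm_parameters(rr_mortality = 0.70)`. Overrides are validated; see
#' [validate_parameters()].
#'
#' @param ... Named overrides of any default field.
#' @param validate Validate the resulting parameter set (default `TRUE`).
#' @return An object of class `tm_parameters` (a named list).
#' @export
#' @examples
#' p <- tm_parameters()
#' p$discount_rate_annual
#' tm_parameters(rr_mortality = 1)$rr_mortality
tm_parameters <- function(..., validate = TRUE) {
  params <- default_parameters()
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      abort("All parameter overrides must be named.")
    }
    unknown <- setdiff(names(overrides), names(params))
    if (length(unknown)) {
      abort(paste0("Unknown parameter field(s): ",
                   paste(unknown, collapse = ", ")))
    }
    params[names(overrides)] <- overrides
    attr(params, "provenance") <- names(overrides)
  } else {
    attr(params, "provenance") <- character()
  }
  class(params) <- "tm_parameters"
  if (validate) {
    v <- validate_parameters(params)
    if (nrow(v)) {
      abort(paste0("Invalid parameters:\n",
                   paste0("- ", v$field, ": ", v$message, collapse = "\n")))
    }
  }
  params
}

default_parameters <- function() {
  list(
    # -- economics / horizon -------------------------------------------------
    discount_rate_annual = 0.015,
    horizon_months       = 300L,
    cohort_size          = 1000L,
    psa_iterations       = 1000L,

    # -- monthly NYHA transition probabilities (rows I..IV, columns I..IV) ---
    nyha_transition_matrix = matrix(
      c(0.977, 0.019, 0.004, 0.000,
        0.008, 0.981, 0.010, 0.001,
        0.000, 0.034, 0.960, 0.006,
        0.000, 0.000, 0.055, 0.945),
      nrow = 4, byrow = TRUE,
      dimnames = list(paste0("NYHA", 1:4), paste0("NYHA", 1:4))),

    # -- hospitalization / readmission ---------------------------------------
    hosp_prob_monthly = c(NYHA1 = 0.0152, NYHA2 = 0.024,
                          NYHA3 = 0.024,  NYHA4 = 0.154),
    hosp_prob_range = matrix(
      c(0.008, 0.023, 0.012, 0.036, 0.012, 0.036, 0.077, 0.231),
      nrow = 4, byrow = TRUE,
      dimnames = list(paste0("NYHA", 1:4), c("lower", "upper"))),
    readmit_prob_30d   = 0.159,
    readmit_prob_range = c(lower = 0.089, upper = 0.159),
    # Post-discharge cycles in which the elevated 30-day readmission
    # probability applies, renewed at each discharge (the "vulnerable
    # phase" after a heart-failure hospitalization). 1: only the first
    # post-discharge cycle; Inf: a permanent elevation. The default, 12
    # months, is the upper end of the vulnerable-phase window described in
    # the heart-failure readmission literature.
    readmit_window_months = 12,
    # Whether the hospitalization RR also scales the 30-day readmission
    # probability (FALSE: the treatment effect acts on index admissions;
    # post-discharge readmission risk is a property of the disease course).
    rr_applies_to_readmission = FALSE,
    # NULL: in-hospital cycles use the patient's own model-based monthly
    # death probability; a number in [0,1] replaces it with a fixed
    # per-cycle in-hospital mortality.
    inhospital_mortality_monthly = NULL,

    # -- utilities -----------------------------------------------------------
    utilities_by_class = c(NYHA1 = 0.81, NYHA2 = 0.72,
                           NYHA3 = 0.59, NYHA4 = 0.508),
    utilities_range = matrix(
      c(0.81, 0.90, 0.72, 0.83, 0.59, 0.74, 0.508, 0.59),
      nrow = 4, byrow = TRUE,
      dimnames = list(paste0("NYHA", 1:4), c("lower", "upper"))),
    hosp_disutility       = 0.059,
    hosp_disutility_range = c(lower = 0, upper = 0.11),

    # -- monthly state cost components, CAD/month ----------------------------
    # NYHA IV equals NYHA III except the drug component.
    state_cost_components = matrix(
      c(0.00,  0.00,  97.00,  52.00,
        0.00,  0.00,  97.00,  52.00,
        62.83, 12.87, 97.00,  79.43,
        62.83, 12.87, 97.00, 208.16),
      nrow = 4, byrow = TRUE,
      dimnames = list(paste0("NYHA", 1:4),
                      c("ed", "gp", "outpatient", "drug"))),
    drug_age_threshold = 65,

    # -- unit costs and 6-month utilization anchors (PSA / utilization route)
    unit_costs = c(ed = 377.00, gp = 77.20, outpatient = 291.33),
    unit_cost_sds = c(ed = 374.00, gp = 0, outpatient = 161.11),
    drug_cost_6mo_mean = 1248.96,
    drug_cost_6mo_sd   = 2233.52,

    # -- hospitalization episode costs ---------------------------------------
    hosp_cost_mean = 8908,
    hosp_cost_sd   = 16867,
    los_mean_days  = 5.9,
    los_sd_days    = 11.2,

    # -- telemonitoring program costs ----------------------------------------
    tm_fixed_site_cost     = 102500,
    tm_site_capacity       = 1000,
    tm_operational_monthly = 44.67,
    kit_monthly_cost   = c(FK = 67.56, BYOP = 18.87, BYOE = 3.80),
    deployment_ratio   = c(FK = 2, BYOP = 1, BYOE = 2),

    # -- treatment effects ---------------------------------------------------
    rr_mortality           = 0.81,
    rr_mortality_ci        = c(lower = 0.70, upper = 0.94),
    rr_hospitalization     = 0.753,
    rr_hospitalization_ci  = c(lower = 0.634, upper = 0.879),
    # Alternative program-evaluation estimate, selectable via override.
    rr_hospitalization_alt    = 0.857,
    rr_hospitalization_alt_ci = c(lower = 0.703, upper = 1.014),

    # -- CEAC grid -----------------------------------------------------------
    wtp_grid = seq(0, 100000, by = 1000),

    # -- survival score ------------------------------------------------------
    shfm = default_shfm_model(),

    # -- cohort generator ----------------------------------------------------
    cohort_moments     = default_moments(),
    correlation_matrix = default_correlation(),
    nyha_cutpoints     = qnorm(c(44, 210, 303) / 304),
    clip_bounds = list(
      age_years               = c(18, 100),
      lvef_pct                = c(1, 100),
      sbp_mmHg                = c(60, 250),
      lymphocytes_pct         = c(1, 60),
      sodium_mEq_L            = c(110, 160),
      cholesterol_mg_dL       = c(50, 500),
      hemoglobin_g_dL         = c(4, 22),
      urate_mg_dL             = c(1, 20),
      weight_kg               = c(30, 250),
      furosemide_equiv_mg_day = c(0, 2000)),

    # -- PSA -----------------------------------------------------------------
    dirichlet_n = 500
  )
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the model parameters: transition
#' rows sum to 1 (tolerance 1e-9), probabilities and utilities lie in
#' \[0, 1\], costs are nonnegative, the correlation matrix is symmetric with
#' unit diagonal and positive semidefinite, deployment ratio entries are
#' nonnegative with a positive sum, and the baseline hazard is positive.
#'
#' @param params A `tm_parameters` object.
#' @return A tibble of violations with columns `field`, `rule`, `message`;
#'   zero rows when the parameter set is valid.
#' @export
validate_parameters <- function(params) {
  v <- list()
  bad <- function(field, rule, message) {
    v[[length(v) + 1L]] <<- tibble(field = field, rule = rule,
                                   message = message)
  }

  tm <- params$nyha_transition_matrix
  if (!is.matrix(tm) || any(dim(tm) != c(4, 4))) {
    bad("nyha_transition_matrix", "shape", "must be a 4x4 matrix")
  } else {
    rs <- rowSums(tm)
    off <- which(abs(rs - 1) > 1e-9)
    for (i in off) {
      bad("nyha_transition_matrix", "row_sum",
          sprintf("row %d (NYHA %s) sums to %.6f, not 1", i, c("I", "II", "III", "IV")[i], rs[i]))
    }
    if (any(tm < 0 | tm > 1)) {
      bad("nyha_transition_matrix", "probability_range",
          "entries must lie in [0, 1]")
    }
  }

  check_prob <- function(x, field) {
    if (any(!is.finite(x)) || any(x < 0 | x > 1)) {
      bad(field, "probability_range",
          sprintf("values must lie in [0, 1]; got %s",
                  paste(signif(x, 4), collapse = ", ")))
    }
  }
  check_prob(params$hosp_prob_monthly, "hosp_prob_monthly")
  check_prob(params$readmit_prob_30d, "readmit_prob_30d")
  if (!is.null(params$inhospital_mortality_monthly)) {
    check_prob(params$inhospital_mortality_monthly,
               "inhospital_mortality_monthly")
  }
  check_prob(params$utilities_by_class, "utilities_by_class")
  check_prob(params$hosp_disutility, "hosp_disutility")

  nonneg <- function(x, field) {
    if (any(!is.finite(x)) || any(x < 0)) {
      bad(field, "nonnegative", "costs must be nonnegative and finite")
    }
  }
  nonneg(params$state_cost_components, "state_cost_components")
  nonneg(params$hosp_cost_mean, "hosp_cost_mean")
  nonneg(params$hosp_cost_sd, "hosp_cost_sd")
  nonneg(params$tm_fixed_site_cost, "tm_fixed_site_cost")
  nonneg(params$tm_operational_monthly, "tm_operational_monthly")
  nonneg(params$kit_monthly_cost, "kit_monthly_cost")

  if (params$discount_rate_annual < 0) {
    bad("discount_rate_annual", "nonnegative", "discount rate must be >= 0")
  }
  if (params$horizon_months < 1) {
    bad("horizon_months", "positive", "horizon must be >= 1 month")
  }
  if (params$tm_site_capacity <= 0) {
    bad("tm_site_capacity", "positive", "site capacity must be > 0")
  }

  dr <- params$deployment_ratio
  if (any(dr < 0) || sum(dr) <= 0) {
    bad("deployment_ratio", "ratio",
        "entries must be >= 0 with a positive sum")
  }

  if (params$rr_mortality <= 0 || params$rr_hospitalization <= 0) {
    bad("rr_mortality", "positive", "relative risks must be > 0")
  }

  cm <- params$correlation_matrix
  if (!isSymmetric(unname(cm), tol = 1e-8)) {
    bad("correlation_matrix", "symmetric", "matrix must be symmetric")
  } else {
    if (any(abs(diag(cm) - 1) > 1e-8)) {
      bad("correlation_matrix", "unit_diagonal",
          "diagonal entries must equal 1")
    }
    ev <- min(eigen(cm, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8) {
      bad("correlation_matrix", "positive_semidefinite",
          sprintf("smallest eigenvalue %.3g < 0", ev))
    }
  }

  if (is.unsorted(params$nyha_cutpoints, strictly = TRUE)) {
    bad("nyha_cutpoints", "increasing",
        "cutpoints must be strictly increasing")
  }

  if (params$shfm$baseline_annual_hazard <= 0) {
    bad("shfm", "positive_hazard", "baseline annual hazard must be > 0")
  }

  if (length(v) == 0) {
    return(tibble(field = character(), rule = character(),
                  message = character()))
  }
  dplyr::bind_rows(v)
}

#' @export
print.tm_parameters <- function(x, ...) {
  cat("<tm_parameters>\n")
  cat(sprintf("  horizon: %d months, discount %.1f%%/yr, cohort %d, PSA %d\n",
              x$horizon_months, 100 * x$discount_rate_annual,
              x$cohort_size, x$psa_iterations))
  cat(sprintf("  RR mortality %.3g, RR hospitalization %.3g\n",
              x$rr_mortality, x$rr_hospitalization))
  cat(sprintf("  baseline annual hazard %.4f; %d survival covariates\n",
              x$shfm$baseline_annual_hazard, nrow(x$shfm$coefficients)))
  ov <- attr(x, "provenance")
  if (length(ov)) cat("  user overrides:", paste(ov, collapse = ", "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Config file I/O

#' Read model parameters from a YAML or JSON config file
#'
#' Missing fields are filled from the packaged defaults; present fields
#' override them. The file may be empty, in which case the full default set
#' is returned. A `.json` extension selects the JSON parser, anything else
#' is read as YAML.
#'
#' @param path Path to a config file.
#' @return A validated `tm_parameters` object; the `provenance` attribute
#'   lists the fields that were overridden by the file.
#' @seealso [write_parameters()], [tm_parameters()]
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) abort("Config file must contain a mapping of fields.")
  params <- default_parameters()
  unknown <- setdiff(names(cfg), names(params))
  if (length(unknown)) {
    abort(paste0("Unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  for (nm in names(cfg)) {
    # assign via [ so a NULL value (e.g. inhospital_mortality_monthly) is
    # kept as an explicit NULL field rather than dropping the element
    params[nm] <- list(config_decode_field(nm, cfg[[nm]], params[[nm]]))
  }
  attr(params, "provenance") <- names(cfg)
  class(params) <- "tm_parameters"
  v <- validate_parameters(params)
  if (nrow(v)) {
    abort(paste0("Invalid config ", path, ":\n",
                 paste0("- ", v$field, ": ", v$message, collapse = "\n")))
  }
  params
}

#' Write model parameters to a YAML or JSON config file
#'
#' The written file round-trips: `read_parameters(write_parameters(p, f))`
#' reproduces `p`.
#'
#' @param params A `tm_parameters` object.
#' @param path Output path; a `.json` extension writes JSON, otherwise YAML.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  lst <- config_encode(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  } else {
    yaml::write_yaml(lst, path, precision = 15)
  }
  invisible(path)
}

# Encode a parameter list into plain nested lists for YAML/JSON.
config_encode <- function(params) {
  enc <- unclass(params)
  enc$nyha_transition_matrix <- matrix_to_rows(params$nyha_transition_matrix)
  enc$hosp_prob_range        <- matrix_to_rows(params$hosp_prob_range)
  enc$utilities_range        <- matrix_to_rows(params$utilities_range)
  enc$state_cost_components  <- matrix_to_rows(params$state_cost_components)
  enc$correlation_matrix <- list(
    characteristics = colnames(params$correlation_matrix),
    rows = matrix_to_rows(unname(params$correlation_matrix)))
  enc$cohort_moments <- purrr::transpose(as.list(params$cohort_moments))
  enc$shfm <- list(
    baseline_annual_hazard = params$shfm$baseline_annual_hazard,
    coefficients = purrr::transpose(as.list(params$shfm$coefficients)))
  enc$readmit_window_months <-
    if (is.infinite(params$readmit_window_months)) ".inf" else
      params$readmit_window_months
  attr(enc, "provenance") <- NULL
  enc
}

config_decode_field <- function(name, value, default) {
  switch(
    name,
    nyha_transition_matrix = rows_to_matrix(value, default),
    hosp_prob_range        = rows_to_matrix(value, default),
    utilities_range        = rows_to_matrix(value, default),
    state_cost_components  = rows_to_matrix(value, default),
    correlation_matrix = {
      m <- rows_to_matrix(value$rows, NULL)
      dimnames(m) <- list(value$characteristics, value$characteristics)
      m
    },
    cohort_moments = dplyr::mutate(
      dplyr::bind_rows(lapply(value, function(r) {
        r[vapply(r, is.null, logical(1))] <- NA
        as_tibble(r)
      })),
      mean = as.numeric(.data$mean), sd = as.numeric(.data$sd)),
    shfm = list(
      baseline_annual_hazard = value$baseline_annual_hazard,
      coefficients = dplyr::bind_rows(lapply(value$coefficients, as_tibble))),
    readmit_window_months =
      if (identical(value, ".inf")) Inf else as.numeric(value),
    horizon_months = as.integer(value),
    cohort_size    = as.integer(value),
    psa_iterations = as.integer(value),
    clip_bounds    = lapply(value, as.numeric),
    {
      # scalar / plain vector fields: preserve the default's names
      out <- unlist(value, use.names = FALSE)
      if (!is.null(names(default)) && length(out) == length(default)) {
        names(out) <- names(default)
      } else if (!is.null(names(value))) {
        names(out) <- names(value)
      }
      out
    }
  )
}

matrix_to_rows <- function(m) {
  lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
}

rows_to_matrix <- function(rows, default) {
  m <- do.call(rbind, lapply(rows, as.numeric))
  if (!is.null(default)) dimnames(m) <- dimnames(default)
  m
}
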