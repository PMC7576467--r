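#' Marginal moments of the reference heart-failure cohort
#'
#' One row per generated patient characteristic. Continuous characteristics
#' carry a mean and SD; binary characteristics carry the cohort proportion in
#' `mean`; the NYHA class is generated on a latent standard-normal scale and
#' discretized with [assign_nyha_class()], so its row carries no moments.
#'
#' @return A tibble with columns `characteristic`, `type`
#'   (`"continuous"`, `"binary"` or `"ordinal"`), `mean`, `sd`.
#' @export
default_moments <- function() {
  tibble::tribble(
    ~characteristic,            ~type,        ~mean,   ~sd,
    "age_years",                "continuous",  58.23,  15.43,
    "sex_female",               "binary",       0.220, NA,
    "ischemic_etiology",        "binary",       0.285, NA,
    "on_beta_blocker",          "binary",       0.894, NA,
    "on_aldosterone_blocker",   "binary",       0.712, NA,
    "on_arb",                   "binary",       0.272, NA,
    "on_ace_inhibitor",         "binary",       0.455, NA,
    "on_allopurinol",           "binary",       0.136, NA,
    "lvef_pct",                 "continuous",  32.07,  13.62,
    "nyha_class",               "ordinal",     NA,     NA,
    "sbp_mmHg",                 "continuous", 110.36,  17.91,
    "lymphocytes_pct",          "continuous",  22.18,   9.07,
    "sodium_mEq_L",             "continuous", 137.73,   3.06,
    "cholesterol_mg_dL",        "continuous", 154.77,  52.71,
    "hemoglobin_g_dL",          "continuous",  13.33,   1.99,
    "urate_mg_dL",              "continuous",   7.97,   2.70,
    "weight_kg",                "continuous",  83.39,  20.04,
    "furosemide_equiv_mg_day",  "continuous",  99.57, 123.93,
    "has_icd",                  "binary",       0.565, NA)
}

#' Default latent correlation matrix for cohort generation
#'
#' A modest, clinically plausible correlation structure on the latent normal
#' scale (e.g. older patients have higher systolic pressure and urate; lower
#' ejection fraction goes with worse NYHA class and higher diuretic dose;
#' allopurinol users have higher urate). Any user-supplied symmetric
#' positive-semidefinite matrix over the same characteristics can replace it
#' through [tm_parameters()] or the config file.
#'
#' @return A named 19x19 correlation matrix.
#' @export
default_correlation <- function() {
  chars <- default_moments()$characteristic
  m <- diag(length(chars))
  dimnames(m) <- list(chars, chars)
  set_cor <- function(a, b, r) {
    m[a, b] <<- r
    m[b, a] <<- r
  }
  set_cor("age_years", "sbp_mmHg", 0.20)
  set_cor("age_years", "urate_mg_dL", 0.10)
  set_cor("lvef_pct", "nyha_class", -0.30)
  set_cor("lvef_pct", "sbp_mmHg", 0.10)
  set_cor("nyha_class", "furosemide_equiv_mg_day", 0.25)
  set_cor("nyha_class", "sbp_mmHg", -0.10)
  set_cor("nyha_class", "hemoglobin_g_dL", -0.10)
  set_cor("sex_female", "weight_kg", -0.30)
  set_cor("sex_female", "hemoglobin_g_dL", -0.15)
  set_cor("on_allopurinol", "urate_mg_dL", 0.30)
  set_cor("urate_mg_dL", "furosemide_equiv_mg_day", 0.20)
  set_cor("sodium_mEq_L", "furosemide_equiv_mg_day", -0.15)
  set_cor("weight_kg", "furosemide_equiv_mg_day", 0.10)
  m
}

#' Build a correlated virtual-patient sampler
#'
#' Constructs a NORTA-style sampler: latent standard-normal vectors with the
#' requested correlation (via the Cholesky factor of `correlation`) are
#' back-transformed per characteristic — continuous values as
#' `mean + sd * z`, binary indicators as `z < qnorm(proportion)`, and the
#' NYHA class by cutpoint thresholding ([assign_nyha_class()]).
#'
#' @param moments Tibble as returned by [default_moments()].
#' @param correlation Symmetric unit-diagonal matrix over the same
#'   characteristics.
#' @param nyha_cutpoints Three increasing latent thresholds for NYHA classes.
#' @param repair If `TRUE`, a non-positive-semidefinite matrix is repaired to
#'   the nearest correlation matrix ([Matrix::nearPD()]) with a warning;
#'   otherwise it is an error.
#' @return A function `f(n)` drawing `n` profiles (a tibble) from the
#'   current RNG stream.
#' @export
build_correlated_sampler <- function(moments,
                                     correlation,
                                     nyha_cutpoints = qnorm(c(44, 210, 303) / 304),
                                     repair = FALSE) {
  chars <- moments$characteristic
  if (!setequal(rownames(correlation), chars)) {
    abort("Correlation matrix characteristics must match the moments table.")
  }
  correlation <- correlation[chars, chars]
  if (!isSymmetric(unname(correlation), tol = 1e-8)) {
    abort("Correlation matrix must be symmetric.")
  }
  ev <- min(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-10) {
    if (!repair) {
      abort(sprintf(
        "Correlation matrix is not positive semidefinite (min eigenvalue %.3g); set repair = TRUE to project to the nearest correlation matrix.",
        ev))
    }
    repaired <- as.matrix(Matrix::nearPD(correlation, corr = TRUE)$mat)
    warn(sprintf("Correlation matrix repaired; adjustment Frobenius norm %.4g",
                 norm(repaired - correlation, "F")))
    correlation <- repaired
    dimnames(correlation) <- list(chars, chars)
  }
  if (is.unsorted(nyha_cutpoints, strictly = TRUE)) {
    abort("NYHA cutpoints must be strictly increasing.")
  }
  cf <- chol(correlation)  # upper triangular, t(cf) %*% cf == correlation

  function(n) {
    stopifnot(n >= 0)
    z <- matrix(rnorm(n * length(chars)), nrow = n,
                ncol = length(chars)) %*% cf
    colnames(z) <- chars
    out <- vector("list", length(chars))
    names(out) <- chars
    for (i in seq_along(chars)) {
      row <- moments[i, ]
      out[[i]] <- switch(
        row$type,
        continuous = row$mean + row$sd * z[, i],
        binary     = as.integer(z[, i] < qnorm(row$mean)),
        ordinal    = assign_nyha_class(z[, i], nyha_cutpoints))
    }
    as_tibble(out)
  }
}

#' Discretize a latent normal value into an NYHA class
#'
#' Class 1 below the first cutpoint, 2 below the second, 3 below the third,
#' otherwise 4. The default cutpoints are the standard-normal quantiles of
#' the reference cohort's cumulative class proportions (44, 210, 303 of 304
#' patients), so draws reproduce the observed class distribution
#' 44/166/93/1 including the rare class IV.
#'
#' @param latent Numeric vector of latent standard-normal values.
#' @param cutpoints Three strictly increasing thresholds.
#' @return Integer vector of classes in 1..4.
#' @export
assign_nyha_class <- function(latent,
                              cutpoints = qnorm(c(44, 210, 303) / 304)) {
  if (length(cutpoints) != 3 || is.unsorted(cutpoints, strictly = TRUE)) {
    abort("cutpoints must be 3 strictly increasing values.")
  }
  as.integer(findInterval(latent, cutpoints) + 1L)
}

#' Clip out-of-range continuous characteristics to plausible bounds
#'
#' Normal sampling can produce physiologically impossible values (negative
#' diuretic doses, ejection fractions above 100). Values outside the
#' per-field bounds are clipped; the number of clipped values is recorded in
#' the `clip_counts` attribute.
#'
#' @param profiles Tibble of patient profiles.
#' @param bounds Named list of `c(lower, upper)` per field (see
#'   `tm_parameters()$clip_bounds`).
#' @return The clipped tibble with a `clip_counts` attribute.
#' @export
truncate_profiles <- function(profiles, bounds) {
  counts <- integer(0)
  for (nm in names(bounds)) {
    if (!nm %in% names(profiles)) next
    b <- bounds[[nm]]
    x <- profiles[[nm]]
    n_clip <- sum(x < b[1] | x > b[2], na.rm = TRUE)
    if (n_clip > 0) profiles[[nm]] <- pmin(pmax(x, b[1]), b[2])
    counts[nm] <- n_clip
  }
  attr(profiles, "clip_counts") <- counts
  profiles
}

#' Generate a correlated virtual patient cohort
#'
#' Draws `n` patient profiles from the Gaussian-copula sampler defined by the
#' parameter set's marginal moments, correlation matrix and NYHA cutpoints,
#' clips continuous values to the configured physiological bounds, and
#' assigns kit types according to the deployment ratio
#' (see [assign_deployment()]).
#'
#' @param n Number of patients (>= 0).
#' @param params A `tm_parameters` object.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param assign_kits Assign kit types from `params$deployment_ratio`
#'   (default `TRUE`).
#' @return A tibble with one row per patient: `patient_id`, the 19
#'   characteristics, and `kit_type`.
#' @export
#' @examples
#' cohort <- generate_cohort(100, tm_parameters(), seed = 1)
#' mean(cohort$age_years)
generate_cohort <- function(n, params = tm_parameters(), seed = NULL,
                            assign_kits = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  sampler <- build_correlated_sampler(params$cohort_moments,
                                      params$correlation_matrix,
                                      params$nyha_cutpoints)
  profiles <- sampler(n)
  if (n == 0) {
    profiles$patient_id <- integer(0)
    profiles$kit_type <- character(0)
    return(dplyr::relocate(profiles, "patient_id"))
  }
  profiles <- truncate_profiles(profiles, params$clip_bounds)
  clip_counts <- attr(profiles, "clip_counts")
  profiles$patient_id <- seq_len(n)
  profiles <- dplyr::relocate(profiles, "patient_id")
  if (assign_kits) {
    profiles <- assign_deployment(profiles, params$deployment_ratio)
  } else {
    profiles$kit_type <- NA_character_
  }
  attr(profiles, "clip_counts") <- clip_counts
  profiles
}
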