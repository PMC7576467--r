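test_that("gamma-from-moments matches the method-of-moments closed form", {
  g <- dist_gamma_moments(5, 5)
  expect_equal(g$shape, 1) # exponential
  g2 <- dist_gamma_moments(8908, 16867)
  expect_equal(g2$shape, 0.2789233, tolerance = 1e-6)
  expect_equal(g2$scale, 31937.10, tolerance = 1e-6)
  expect_error(dist_gamma_moments(-1, 2))

  withr::with_seed(1, x <- dist_sample(g2, 1e5))
  expect_equal(mean(x), 8908, tolerance = 0.01)
  expect_equal(sd(x), 16867, tolerance = 0.03)
})

test_that("log-normal-from-CI reproduces the interval on back-transform", {
  d <- dist_lognormal_ci(0.81, 0.70, 0.94)
  expect_equal(d$mu, -0.2107210, tolerance = 1e-6)
  expect_equal(d$sigma, 0.0752053, tolerance = 1e-6)
  # the printed CI is slightly asymmetric around log(point); the implied
  # symmetric interval reproduces it to within rounding
  expect_lt(max(abs(exp(d$mu + c(-1, 1) * qnorm(0.975) * d$sigma) -
                      c(0.70, 0.94))), 0.005)

  deg <- dist_lognormal_ci(0.81, 0.81, 0.81)
  expect_equal(deg$sigma, 0)
  expect_error(dist_lognormal_ci(0.81, 0.94, 0.70), "lower <= point")

  withr::with_seed(2, x <- dist_sample(d, 1e5))
  expect_equal(median(x), 0.81, tolerance = 0.005)
})

test_that("beta-from-range fixes the mean at the point estimate", {
  b <- dist_beta_range(0.5, 0.4, 0.6)
  expect_equal(b$alpha, 47.51824, tolerance = 1e-6)
  expect_equal(b$beta, 47.51824, tolerance = 1e-6)
  expect_equal(b$alpha / (b$alpha + b$beta), 0.5)

  expect_identical(dist_beta_range(0.3, 0.3, 0.3)$family, "fixed")
  expect_error(dist_beta_range(1.2, 1, 1.4), "\\[0, 1\\]")

  # the utility spec with the point at the range's lower end, as printed
  u <- dist_beta_range(0.81, 0.81, 0.90)
  withr::with_seed(3, x <- dist_sample(u, 1e5))
  expect_equal(mean(x), 0.81, tolerance = 0.005 / 0.81)
  expect_equal(sd(x), (0.90 - 0.81) / (2 * qnorm(0.975)), tolerance = 0.02)
})

test_that("Dirichlet rows stay on the simplex and recover their mean", {
  row1 <- c(0.977, 0.019, 0.004, 0)
  d <- dist_dirichlet_row(row1, 500)
  withr::with_seed(4, s <- dist_sample(d, 1e5))
  expect_true(all(abs(rowSums(s) - 1) < 1e-12))
  expect_true(all(abs(colMeans(s) - row1) < 0.005))

  # concentration limit: the sample collapses onto the row
  d_big <- dist_dirichlet_row(row1, 1e6)
  withr::with_seed(5, s_big <- dist_sample(d_big, 200))
  expect_lt(max(abs(sweep(s_big, 2, row1))), 0.01)

  expect_error(dist_dirichlet_row(c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
  expect_error(dist_dirichlet_row(c(1, 0, 0, 0), 0), "concentration_n")
})

test_that("negative binomial MLE recovers simulated parameters", {
  withr::with_seed(6, counts <- rnbinom(5000, size = 1, mu = 2))
  fit <- fit_utilization_negbin(counts)
  expect_identical(fit$family, "negbin")
  expect_equal(fit$mu, 2, tolerance = 0.1 / 2)
  expect_equal(fit$size, 1, tolerance = 0.2 / 1)
  # MLE fixes the fitted mean at the sample mean
  expect_equal(fit$mu, mean(counts), tolerance = 1e-4)

  # independent log-likelihood oracle: the reported optimum beats a grid of
  # neighbouring size values and nests the Poisson fit
  ll <- function(size) sum(dnbinom(counts, size = size, mu = fit$mu, log = TRUE))
  grid <- seq(0.5 * fit$size, 2 * fit$size, length.out = 41)
  expect_gte(ll(fit$size) + 1e-6, max(sapply(grid, ll)))
  ll_pois <- sum(dpois(counts, lambda = mean(counts), log = TRUE))
  expect_gte(ll(fit$size), ll_pois)
})

test_that("degenerate utilization counts fall back to Poisson", {
  expect_warning(fit <- fit_utilization_negbin(rep(2L, 50)),
                 "Poisson")
  expect_identical(fit$family, "poisson")
  expect_equal(fit$lambda, 2)
  expect_error(fit_utilization_negbin(integer(0)))
  expect_error(fit_utilization_negbin(c(0L, 0L, 0L)), "degenerate")
})

test_that("parameter sampling is seed-deterministic and respects fixed specs", {
  p <- tm_parameters()
  fixed <- default_psa_specs(p, fixed = TRUE)
  q <- withr::with_seed(7, sample_parameters(p, fixed))
  for (nm in c("utilities_by_class", "hosp_prob_monthly", "readmit_prob_30d",
               "hosp_cost_mean", "rr_mortality", "rr_hospitalization",
               "nyha_transition_matrix", "state_cost_components")) {
    expect_equal(q[[nm]], p[[nm]], label = nm)
  }

  full <- default_psa_specs(p)
  a <- withr::with_seed(8, sample_parameters(p, full))
  b <- withr::with_seed(8, sample_parameters(p, full))
  expect_identical(a, b)
  expect_false(identical(a$hosp_cost_mean, p$hosp_cost_mean))

  # every sampled set remains a valid parameter set
  for (s in 1:5) {
    q <- withr::with_seed(s, sample_parameters(p, full))
    expect_identical(nrow(validate_parameters(q)), 0L)
  }
})

test_that("sampled parameters recover their printed point values", {
  p <- tm_parameters()
  full <- default_psa_specs(p)
  draws <- withr::with_seed(9, replicate(1000, {
    q <- sample_parameters(p, full)
    c(hosp_cost = q$hosp_cost_mean, rr_m = q$rr_mortality,
      u1 = unname(q$utilities_by_class[1]),
      t11 = q$nyha_transition_matrix[1, 1])
  }))
  # CLT bound: the gamma is heavily right-skewed (sd 16,867), so the mean
  # of 1000 draws is checked at 3 standard errors
  expect_lt(abs(mean(draws["hosp_cost", ]) - 8908), 3 * 16867 / sqrt(1000))
  expect_equal(median(draws["rr_m", ]), 0.81, tolerance = 0.01)
  expect_equal(mean(draws["u1", ]), 0.81, tolerance = 0.01)
  expect_equal(mean(draws["t11", ]), 0.977, tolerance = 0.005)
})
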