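test_that("latent correlation is reproduced by the Cholesky sampler", {
  moments <- tibble::tibble(
    characteristic = c("a", "b"), type = "continuous",
    mean = c(0, 10), sd = c(1, 2))
  n <- 50000

  # independence
  corr <- diag(2); dimnames(corr) <- list(c("a", "b"), c("a", "b"))
  s <- build_correlated_sampler(moments, corr)
  withr::with_seed(1, x <- s(n))
  expect_lt(abs(cor(x$a, x$b)), 3 / sqrt(n))

  # strong positive correlation
  corr[1, 2] <- corr[2, 1] <- 0.8
  s <- build_correlated_sampler(moments, corr)
  withr::with_seed(2, x <- s(n))
  expect_equal(cor(x$a, x$b), 0.8, tolerance = 0.02 / 0.8)
})

test_that("binary characteristics recover their target proportion", {
  moments <- tibble::tibble(
    characteristic = c("f", "z"), type = c("binary", "continuous"),
    mean = c(0.22, 0), sd = c(NA, 1))
  corr <- diag(2); dimnames(corr) <- list(c("f", "z"), c("f", "z"))
  s <- build_correlated_sampler(moments, corr)
  withr::with_seed(3, x <- s(50000))
  expect_true(all(x$f %in% 0:1))
  expect_equal(mean(x$f), 0.22, tolerance = 0.01 / 0.22)
})

test_that("cohort generation is deterministic given the seed", {
  p <- tm_parameters()
  a <- generate_cohort(500, p, seed = 7)
  b <- generate_cohort(500, p, seed = 7)
  expect_identical(a, b)
  c <- generate_cohort(500, p, seed = 8)
  expect_false(identical(a$age_years, c$age_years))
  expect_identical(nrow(generate_cohort(0, p, seed = 1)), 0L)
  expect_identical(anyDuplicated(a$patient_id), 0L)
})

test_that("marginal moments converge to the reference cohort values", {
  p <- tm_parameters()
  n <- 10000
  co <- generate_cohort(n, p, seed = 42)
  m <- p$cohort_moments

  # CLT tolerance (3 SE) for continuous characteristics where the clip
  # bounds are rarely hit; heavily clipped fields (e.g. the diuretic dose,
  # whose normal marginal puts ~20% of mass below zero) shift by design.
  light_clip <- c("age_years", "lvef_pct", "sbp_mmHg", "lymphocytes_pct",
                  "sodium_mEq_L", "cholesterol_mg_dL", "hemoglobin_g_dL",
                  "urate_mg_dL", "weight_kg")
  for (ch in light_clip) {
    row <- m[m$characteristic == ch, ]
    expect_equal(mean(co[[ch]]), row$mean,
                 tolerance = 3 * row$sd / sqrt(n) / abs(row$mean),
                 label = paste("mean of", ch))
    expect_equal(sd(co[[ch]]), row$sd, tolerance = 0.05, label = paste("sd of", ch))
  }
  for (ch in m$characteristic[m$type == "binary"]) {
    prop <- m$mean[m$characteristic == ch]
    expect_equal(mean(co[[ch]]), prop,
                 tolerance = (3 * sqrt(prop * (1 - prop) / n) + 1e-9) / prop,
                 label = paste("proportion of", ch))
  }
})

test_that("NYHA class assignment reproduces the observed distribution", {
  expect_identical(assign_nyha_class(-10), 1L)
  expect_identical(assign_nyha_class(10), 4L)
  expect_error(assign_nyha_class(0, cutpoints = c(1, 1, 2)),
               "strictly increasing")

  withr::with_seed(5, z <- rnorm(1e5))
  cls <- assign_nyha_class(z)
  props <- as.numeric(table(factor(cls, levels = 1:4))) / 1e5
  target <- c(44, 166, 93, 1) / 304
  expect_true(all(abs(props - target) < 0.01))
})

test_that("profiles are clipped to physiological bounds", {
  prof <- tibble::tibble(
    lvef_pct = c(-5, 45),
    furosemide_equiv_mg_day = c(-20, 80),
    sodium_mEq_L = c(137, 137))
  bounds <- tm_parameters()$clip_bounds
  out <- truncate_profiles(prof, bounds)
  expect_equal(out$lvef_pct, c(1, 45))
  expect_equal(out$furosemide_equiv_mg_day, c(0, 80))
  expect_equal(out$sodium_mEq_L, prof$sodium_mEq_L) # in range: unchanged
  expect_equal(attr(out, "clip_counts")[["lvef_pct"]], 1L)

  co <- generate_cohort(2000, tm_parameters(), seed = 9)
  expect_true(all(co$lvef_pct >= 1 & co$lvef_pct <= 100))
  expect_true(all(co$furosemide_equiv_mg_day >= 0))
  expect_true(all(co$nyha_class %in% 1:4))
})

test_that("non-positive-semidefinite matrices error unless repaired", {
  moments <- tibble::tibble(
    characteristic = c("a", "b", "c"), type = "continuous",
    mean = 0, sd = 1)
  corr <- matrix(c(1, 0.9, -0.9,
                   0.9, 1, 0.9,
                   -0.9, 0.9, 1), 3, 3,
                 dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_error(build_correlated_sampler(moments, corr),
               "not positive semidefinite")
  expect_warning(s <- build_correlated_sampler(moments, corr, repair = TRUE),
                 "repaired")
  withr::with_seed(1, x <- s(1000))
  expect_identical(nrow(x), 1000L)
})
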