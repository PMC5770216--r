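test_that("one seed fully determines the cohort and seeds derive stable substreams", {
  cfg <- small_config(seed = 50L, H = 8L, size = 40L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  cfg2 <- small_config(seed = 51L, H = 8L, size = 40L)
  expect_false(identical(generate_cohort(cfg2), a))
})

test_that("growing the hospital count leaves earlier hospitals unchanged", {
  small <- generate_cohort(generator_config(n_clusters = 5L, n_total = 200L,
                                            seed = 52L))
  big <- generate_cohort(generator_config(n_clusters = 10L, n_total = 400L,
                                          seed = 52L))
  expect_identical(small[small$cluster_id <= 5L, ],
                   big[big$cluster_id <= 5L, ])
})

test_that("replicates are reproducible, distinct, and empty at n_reps = 0", {
  cfg <- small_config(seed = 53L, H = 4L, size = 30L)
  r1 <- generate_replicates(cfg, 2L, base_seed = 7L)
  r2 <- generate_replicates(cfg, 2L, base_seed = 7L)
  expect_identical(r1, r2)
  expect_false(identical(r1[[1]], r1[[2]]))
  expect_false(identical(generate_replicates(cfg, 1L, 8L)[[1]], r1[[1]]))
  expect_length(generate_replicates(cfg, 0L, 7L), 0L)
})

test_that("a null generating model yields a fifty-percent event rate", {
  beta0 <- default_generating_beta() * 0
  cfg <- generator_config(intercept_mu = 0, sigma_intercept = 0,
                          beta = beta0, period_log_or = 0, seed = 54L)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 14857L)
  expect_lt(abs(mean(co$outcome) - 0.5), 0.01)
})

test_that("defaults produce the registry-scale structure with a plausible event rate", {
  co <- generate_cohort(generator_config(seed = 55L))
  expect_equal(nrow(co), 14857L)
  expect_equal(length(unique(co$cluster_id)), 90L)
  expect_equal(sum(co$period == 0), 7560L, tolerance = 0.01)
  expect_gt(mean(co$outcome), 0.28)
  expect_lt(mean(co$outcome), 0.36)
  # continuous covariates are pre-centred
  for (nm in c("age", "sbp", "resp_rate", "urea"))
    expect_lt(abs(mean(co[[nm]])) / stats::sd(co[[nm]]), 0.05)
})

test_that("between-hospital spread of empirical log-odds grows with sigma_intercept", {
  spread <- function(s) {
    co <- generate_cohort(generator_config(n_clusters = 40L, n_total = 8000L,
                                           sigma_intercept = s, seed = 56L))
    lo <- tapply(co$outcome, co$cluster_id,
                 function(y) stats::qlogis((sum(y) + 0.5) / (length(y) + 1)))
    stats::sd(lo)
  }
  expect_gt(spread(0.5), spread(0.1))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(sigma_intercept = -0.1), "SDs")
  expect_error(generator_config(binary_prevalence = c(
    low_sodium = 1.5, low_hemoglobin = 0.1, cancer = 0.1, copd = 0.1,
    cvd = 0.1, cirrhosis = 0.01, dementia = 0.1)), "prevalences")
  expect_error(generator_config(covariate_random_sd = c(nonexistent = 0.2)),
               "unknown covariate")
  expect_error(generator_config(period1_fraction = 1.2), "period1_fraction")
  expect_error(generator_config(beta = c(age = 0.1)), "marginals")
})

test_that("generator configs survive a JSON round trip", {
  cfg <- generator_config(n_clusters = 12L, n_total = 600L, seed = 57L,
                          covariate_random_sd = c(low_sodium = 0.29))
  path <- withr::local_tempfile(fileext = ".json")
  write_generator_config(cfg, path)
  back <- read_generator_config(path)
  expect_equal(unclass(back), unclass(cfg), tolerance = 1e-12)
  expect_identical(generate_cohort(back), generate_cohort(cfg))
})

test_that("generating truth is recovered by the fixed-effects fit at registry scale", {
  n_rep <- 5L
  cfg <- generator_config()
  fits <- lapply(generate_replicates(cfg, n_rep, base_seed = 58L),
                 function(raw) run_model1(prepare_cohort(raw))$fit)
  est <- sapply(fits, function(f)
    f$beta$estimate[match(names(cfg$beta), f$beta$term)])
  ses <- sapply(fits, function(f)
    f$beta$se[match(names(cfg$beta), f$beta$term)])
  # joint recovery: standardised deviations of the 11 replicate means
  # behave like 11 approximately independent standard normals
  z <- (rowMeans(est) - cfg$beta) / (rowMeans(ses) / sqrt(n_rep))
  expect_lt(max(abs(z)), 4)
  expect_lt(sum(z^2), stats::qchisq(0.999, df = length(z)))
  # regression of mean fitted on true log-ORs has slope near 1
  sl <- stats::coef(stats::lm(rowMeans(est) ~ 0 + cfg$beta))
  expect_gt(sl, 0.9)
  expect_lt(sl, 1.1)
})
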