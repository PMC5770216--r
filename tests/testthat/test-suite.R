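# Structural and statistical behaviour of the nine-model suite on
# generated cohorts kept small enough for repeated fitting.

test_that("Model 1 attaches the intercept-included linear predictor", {
  co <- small_cohort(seed = 21L, H = 10L, size = 80L)
  m1 <- run_model1(co)
  expect_false(is.null(m1$table$linear_predictor))
  spec <- attr(co, "spec")
  X <- cbind(1, as.matrix(as.data.frame(
    m1$table)[, c(spec$continuous, spec$binary)]))
  expect_equal(unname(m1$table$linear_predictor),
               unname(drop(X %*% m1$fit$beta$estimate)), tolerance = 1e-10)
})

test_that("Model 1 on a permuted outcome gives null covariate effects", {
  co <- small_cohort(seed = 22L, H = 30L, size = 100L)
  set.seed(99L)
  co$outcome <- sample(co$outcome)
  fit <- run_model1(co)$fit
  b <- fit$beta[-1, ]  # drop intercept
  covers_null <- b$ci_lo < 0 & 0 < b$ci_hi
  expect_gte(sum(covers_null), 9L)
})

test_that("Model 1 still fits a single-hospital cohort", {
  co <- small_cohort(seed = 23L, H = 6L, size = 500L)
  co1 <- co[co$cluster_id == 1, ]
  attributes(co1)[c("spec", "cluster_levels")] <-
    attributes(co)[c("spec", "cluster_levels")]
  expect_true(run_model1(co1)$fit$converged)
})

test_that("recalibration slope is identified: doubling the LP halves the slope", {
  tab <- cohort_with_lp(seed = 24L, H = 25L, size = 80L)
  m3 <- run_model3(tab)
  tab2 <- tab
  tab2$linear_predictor <- 2 * tab2$linear_predictor
  m3b <- run_model3(tab2)
  i <- match("linear_predictor", m3$beta$term)
  expect_equal(m3b$beta$estimate[i], m3$beta$estimate[i] / 2,
               tolerance = 0.01)
})

test_that("the nesting chain never loses marginal log-likelihood", {
  tab <- cohort_with_lp(seed = 25L, H = 25L, size = 80L,
                        sigma_intercept = 0.3, sigma_lp_slope = 0.2)
  m3 <- run_model3(tab)
  m4 <- run_model4(tab, m3 = m3)
  m6 <- run_model6(tab)
  m7 <- run_model7(tab)
  # 0.05 slack covers the Laplace-vs-quadrature difference for q >= 2 fits
  expect_gte(m4$fit$loglik, m3$loglik - 0.05)
  expect_gte(m7$loglik, m6$loglik - 1e-3)
  expect_equal(m4$test$df, 2L)
})

test_that("Model 5 tests three variance-covariance terms and tolerates failures", {
  tab <- cohort_with_lp(seed = 26L, H = 25L, size = 80L,
                        sigma_intercept = 0.25,
                        covariate_random_sd = c(low_sodium = 0.4))
  r <- run_model5(tab, "low_sodium")
  expect_equal(r$test$df, 3L)
  expect_equal(dim(r$fit$G), c(3L, 3L))
  # the covariate's fixed add-on effect is reported
  expect_true("low_sodium" %in% r$fit$beta$term)
  expect_gte(r$fit$loglik, run_model4(tab)$fit$loglik - 0.05)

  expect_error(run_model5(tab, "not_a_predictor"), "not a predictor")

  # a failing covariate is recorded as a note, not an abort
  res <- run_suite(tab, models = c("M1", "M5"),
                   m5_covariates = c("low_sodium"))
  expect_true("M5[low_sodium]" %in% names(res$fits))
})

test_that("Model 5 variant keeps the other predictors fixed as in Model 2", {
  tab <- cohort_with_lp(seed = 27L, H = 20L, size = 80L)
  r <- run_model5(tab, "dementia", variant = "model2_fixed")
  expect_equal(dim(r$fit$G), c(2L, 2L))
  expect_true(all(c("age", "sbp", "dementia") %in% r$fit$beta$term))
})

test_that("Model 8 has 12 main effects, 11 interactions, and exact nulls on mirrored phases", {
  co <- small_cohort(seed = 28L, H = 10L, size = 60L)
  # duplicate the same patients into both phases: interactions must vanish
  co0 <- as.data.frame(co); co0$period <- 0L
  co1 <- as.data.frame(co); co1$period <- 1L
  mirrored <- rbind(co0, co1)
  tab <- prepare_cohort(mirrored, attr(co, "spec"))
  fit <- run_model8(tab)
  inter <- grepl(":", fit$beta$term)
  expect_equal(sum(inter), 11L)
  expect_equal(nrow(fit$beta), 1L + 12L + 11L)
  expect_lt(max(abs(fit$beta$estimate[inter])), 0.01)
})

test_that("Model 9 returns its three tests with df 4, 3 and 5", {
  tab <- cohort_with_lp(seed = 29L, H = 30L, size = 70L,
                        sigma_intercept = 0.3, sigma_lp_slope = 0.25,
                        sigma_period = 0.2)
  m9 <- run_model9(tab)
  expect_equal(vapply(m9$tests, `[[`, integer(1), "df"),
               c(interaction = 4L, temporal = 3L, lp_or_temporal = 5L))
  expect_equal(length(m9$full$spec$random), 4L)
  expect_equal(length(m9$reduced$spec$random), 3L)
  expect_gte(m9$full$loglik, m9$reduced$loglik - 0.05)
})

test_that("a fixed input yields a byte-identical serialized suite", {
  co <- small_cohort(seed = 30L, H = 10L, size = 60L)
  r1 <- run_suite(co, models = c("M1", "M2"))
  r2 <- run_suite(co, models = c("M1", "M2"))
  expect_identical(as.character(fit_to_json(r1$fits$M2)),
                   as.character(fit_to_json(r2$fits$M2)))
  expect_identical(r1$tests, r2$tests)
})

test_that("a constant period column makes the temporal models fail loudly", {
  tab <- cohort_with_lp(seed = 31L, H = 8L, size = 50L)
  tab$period <- 0L
  expect_error(run_model6(tab))
})
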