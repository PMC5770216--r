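# Random-effects fits: cross-checked against glmmTMB (an independent
# marginal-likelihood implementation) and against structural invariants.

test_that("random-intercept fit agrees with an independent mixed-model implementation", {
  co <- small_cohort(seed = 11L, H = 40L, size = 80L,
                     sigma_intercept = 0.3)
  spec <- model_spec(fixed = c("age", "low_sodium", "period"), random = "1")
  fit <- fit_glmm(co, spec)
  expect_true(fit$converged)
  expect_match(fit$method, "quadrature")

  ref <- glmmTMB::glmmTMB(
    outcome ~ age + low_sodium + period + (1 | cluster_id),
    data = transform(co, cluster_id = factor(cluster_id)),
    family = binomial())
  sigma_ref <- sqrt(as.numeric(glmmTMB::VarCorr(ref)$cond$cluster_id))
  expect_equal(sqrt(diag(fit$G))[[1]], sigma_ref, tolerance = 0.01)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 0.1)
  expect_equal(fit$beta$estimate, unname(glmmTMB::fixef(ref)$cond),
               tolerance = 0.01)
})

test_that("null between-hospital variance is recovered near zero in most replicates", {
  sigmas <- vapply(1:5, function(i) {
    co <- small_cohort(seed = 12L + i, H = 90L, size = 60L,
                       sigma_intercept = 0)
    sqrt(fit_glmm(co, model_spec(fixed = c("age", "dementia"),
                                 random = "1"))$G[1, 1])
  }, numeric(1))
  expect_lt(stats::median(sigmas), 0.05)
  expect_lt(max(sigmas), 0.12)
})

test_that("with negligible cluster variance the GLMM betas collapse to the fixed-effects betas", {
  co <- small_cohort(seed = 13L, H = 30L, size = 80L, sigma_intercept = 0)
  spec_f <- model_spec(fixed = c("age", "cancer"))
  spec_r <- model_spec(fixed = c("age", "cancer"), random = "1")
  ff <- fit_fixed_logistic(co, spec_f)
  fr <- fit_glmm(co, spec_r)
  if (fr$boundary) {
    expect_equal(fr$beta$estimate, ff$beta$estimate, tolerance = 1e-5)
  } else {
    expect_equal(fr$beta$estimate, ff$beta$estimate, tolerance = 0.02)
  }
  # the marginal likelihood can only improve on the fixed-effects one
  expect_gte(fr$loglik, ff$loglik - 1e-4)
})

test_that("quadrature refinement converges: 7 -> 15 -> 31 nodes", {
  co <- small_cohort(seed = 14L, H = 20L, size = 120L,
                     sigma_intercept = 0.4)
  spec <- model_spec(fixed = "age", random = "1")
  ll <- vapply(c(7L, 15L, 31L),
               function(k) fit_glmm(co, spec, nodes = k)$loglik, numeric(1))
  expect_lt(abs(ll[2] - ll[3]), 0.01)
  expect_lte(abs(ll[2] - ll[3]), abs(ll[1] - ll[3]) + 1e-12)
})

test_that("empirical-Bayes modes shrink relative to the estimated sigma", {
  co <- small_cohort(seed = 15L, H = 40L, size = 60L,
                     sigma_intercept = 0.4)
  fit <- fit_glmm(co, model_spec(fixed = "age", random = "1"))
  expect_equal(nrow(fit$eb_modes), 40L)
  expect_lte(stats::sd(fit$eb_modes[, 1]), sqrt(fit$G[1, 1]) + 1e-8)
})

test_that("G is symmetric PSD and clusters of size one are tolerated", {
  co <- small_cohort(seed = 16L, H = 12L, size = 50L,
                     sigma_intercept = 0.3, sigma_lp_slope = 0.2)
  co_lp <- run_model1(co)$table
  # make one hospital a singleton
  keep <- co_lp$cluster_id != 1 | seq_len(nrow(co_lp)) == 1
  co1 <- co_lp[keep, ]
  attributes(co1)[c("spec", "cluster_levels", "lp_offset")] <-
    attributes(co_lp)[c("spec", "cluster_levels", "lp_offset")]
  fit <- fit_glmm(co1, model_spec(fixed = "linear_predictor",
                                  random = c("1", "linear_predictor")))
  expect_equal(fit$G, t(fit$G), tolerance = 1e-10)
  expect_gte(min(eigen(fit$G, symmetric = TRUE)$values), -1e-8)
  expect_equal(fit$method, "laplace")
})

test_that("a full random-coefficients model over all predictors is refused", {
  co <- small_cohort(seed = 17L, H = 10L, size = 30L)
  covs <- c("age", "sbp", "resp_rate", "urea", "low_sodium",
            "low_hemoglobin", "cancer")
  expect_error(fit_glmm(co, model_spec(fixed = covs,
                                       random = c("1", covs))),
               "refused")
})

test_that("random-effects fits demand at least two hospitals", {
  co <- small_cohort(seed = 18L, H = 5L, size = 30L)
  co1 <- co[co$cluster_id == 1, ]
  attributes(co1)[c("spec", "cluster_levels")] <-
    attributes(co)[c("spec", "cluster_levels")]
  expect_error(fit_glmm(co1, model_spec(fixed = "age", random = "1")),
               "at least 2")
})

test_that("variance-component LRT reproduces chi-square tail probabilities", {
  f <- list(loglik = -100, converged = TRUE,
            spec = model_spec(fixed = "x", random = c("1", "x"), label = "full"))
  r <- list(loglik = -100, converged = TRUE,
            spec = model_spec(fixed = "x", random = "1", label = "red"))

  t0 <- lrt_variance_components(f, r, df = 2L)
  expect_equal(t0$chi2, 0)
  expect_equal(t0$p_value, 1)

  # printed (chi2, df, p) triples from the geographic and joint analyses
  f$loglik <- r$loglik + 6.08 / 2
  expect_equal(round(lrt_variance_components(f, r, df = 2L)$p_value, 4),
               0.0478)
  f$loglik <- r$loglik + 11.43 / 2
  expect_equal(round(lrt_variance_components(f, r, df = 3L)$p_value, 4),
               0.0096)
  f$loglik <- r$loglik + 12.33 / 2
  expect_equal(round(lrt_variance_components(f, r, df = 5L)$p_value, 2),
               0.03)

  # small negative differences are clamped at zero
  f$loglik <- r$loglik - 1e-6
  expect_equal(lrt_variance_components(f, r, df = 2L)$chi2, 0)

  # df defaults to the difference in unstructured-G parameter counts
  f$loglik <- r$loglik + 1
  expect_equal(lrt_variance_components(f, r)$df, 2L)

  # non-nested specs are refused; unconverged fits are flagged unreliable
  r_bad <- r; r_bad$spec <- model_spec(fixed = "z", random = "1")
  expect_error(lrt_variance_components(f, r_bad), "not nested")
  r$converged <- FALSE
  expect_false(lrt_variance_components(f, r, df = 2L)$reliable)
})
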