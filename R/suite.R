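# The nine-model heterogeneity suite.
#
# M1  fixed-effects logistic fit of the prediction model; its fitted linear
#     predictor (intercept included) feeds the later models.
# M2  M1 plus hospital random intercepts (geographic baseline-risk
#     heterogeneity).
# M3  outcome ~ linear predictor, random intercept (recalibration across
#     hospitals; slope near 1 and intercept near 0 when the LP comes from
#     the same data).
# M4  M3 plus a random slope on the linear predictor (heterogeneous
#     calibration slope); tested against M3 on 2 variance-covariance terms.
# M5  per covariate: random intercept + random LP slope + random add-on
#     coefficient for that covariate, with the LP centred; tested on the 3
#     variance-covariance terms of the covariate.
# M6  M3 plus a fixed temporal-period effect.
# M7  M6 plus a period-by-LP interaction.
# M8  period, the 11 covariates, and all period-by-covariate interactions,
#     random intercept.
# M9  random intercept, random LP slope, random temporal effect, and random
#     period-by-LP interaction (q = 4), with tests on 4, 3 and 5
#     variance-covariance terms.

suite_spec_m1 <- function(covs) model_spec(fixed = covs, label = "M1")
suite_spec_m2 <- function(covs) model_spec(fixed = covs, random = "1",
                                           label = "M2")

#' Run the fixed-effects prediction model (Model 1)
#'
#' Fits the prediction model's covariates by plain logistic regression and
#' attaches the fitted linear predictor (intercept included) to the cohort,
#' for use by the recalibration and temporal models.
#'
#' @param table A prepared `cohort_table`.
#' @return List with `fit` (a `glmm_fit`) and `table` (the cohort with a
#'   `linear_predictor` column).
#' @export
run_model1 <- function(table) {
  covs <- all_predictors(attr(table, "spec", exact = TRUE))
  fit <- fit_fixed_logistic(table, suite_spec_m1(covs))
  table$linear_predictor <- fit$fitted_lp
  list(fit = fit, table = table)
}

#' Run the random-intercept prediction model (Model 2)
#'
#' @param table A prepared `cohort_table`.
#' @param nodes Adaptive Gauss-Hermite nodes.
#' @return A `glmm_fit`.
#' @export
run_model2 <- function(table, nodes = 15L) {
  covs <- all_predictors(attr(table, "spec", exact = TRUE))
  fit_glmm(table, suite_spec_m2(covs), nodes = nodes)
}

require_lp <- function(table) {
  if (is.null(table[["linear_predictor"]]))
    stop("cohort has no 'linear_predictor' column; run run_model1() first",
         call. = FALSE)
  invisible(table)
}

#' Recalibration model with hospital random intercepts (Model 3)
#'
#' Regresses the outcome on the uncentred Model 1 linear predictor with a
#' random intercept. With the intercept-included LP from the same data, the
#' fixed slope is near 1 and the fixed intercept near 0, so the random
#' intercept describes hospital deviations for a reference patient (LP = 0).
#'
#' @inheritParams run_model2
#' @return A `glmm_fit`.
#' @export
run_model3 <- function(table, nodes = 15L) {
  require_lp(table)
  fit_glmm(table, model_spec(fixed = "linear_predictor", random = "1",
                             label = "M3"), nodes = nodes)
}

#' Random calibration-slope model and its test (Model 4)
#'
#' Adds a hospital-level random slope on the linear predictor to Model 3
#' (unstructured 2x2 G) and tests the 2 added variance-covariance terms.
#'
#' @inheritParams run_model2
#' @param m3 Optionally, an already-fitted Model 3 to reuse in the test.
#' @return List with `fit` and `test` (an `lrt_result`, df = 2).
#' @export
run_model4 <- function(table, nodes = 15L, m3 = NULL) {
  require_lp(table)
  if (is.null(m3)) m3 <- run_model3(table, nodes = nodes)
  # the LRT compares Laplace to Laplace: refit the reduced model at the
  # full model's integration accuracy so the chi-square difference is not
  # contaminated by quadrature error
  m3L <- laplace_refit(table, m3)
  fit <- fit_best_start(table, model_spec(fixed = "linear_predictor",
                                          random = c("1", "linear_predictor"),
                                          label = "M4"), nodes, from = m3L)
  list(fit = fit, test = lrt_variance_components(fit, m3L, df = 2L))
}

# Laplace refit of a q = 1 fit, warm started from its own optimum
laplace_refit <- function(table, fit) {
  if (identical(fit$method, "quadrature(1)")) return(fit)
  fit_glmm(table, fit$spec, nodes = 1L,
           start = list(theta = fit$theta, fixef = fit$fixef))
}

#' Per-covariate random-effect model and its test (Model 5)
#'
#' With the linear predictor centred, allows one covariate's coefficient to
#' vary across hospitals on top of the random intercept and random LP slope
#' (unstructured 3x3 G), and tests the 3 variance-covariance terms of the
#' covariate against the centred-LP refit of Model 4. The covariate's fixed
#' add-on effect (relative to its contribution inside the LP) is reported
#' alongside.
#'
#' The `variant = "model2_fixed"` formulation instead keeps all covariates
#' as fixed effects (as in Model 2) and adds the single random coefficient.
#'
#' @inheritParams run_model2
#' @param covariate Name of the covariate whose effect may vary.
#' @param m4c Optionally, the centred-LP Model 4 refit to reuse.
#' @param variant `"calibration"` (default) or `"model2_fixed"`.
#' @return List with `fit`, `test` (df = 3) and `covariate`.
#' @export
run_model5 <- function(table, covariate, nodes = 15L, m4c = NULL,
                       variant = c("calibration", "model2_fixed")) {
  require_lp(table)
  variant <- match.arg(variant)
  spec <- attr(table, "spec", exact = TRUE)
  covs <- all_predictors(spec)
  if (!covariate %in% covs)
    stop("'", covariate, "' is not a predictor of this cohort", call. = FALSE)
  tab <- center_linear_predictor(table)

  if (variant == "model2_fixed") {
    red <- fit_glmm(tab, suite_spec_m2(covs), nodes = 1L)
    fit <- fit_best_start(tab, model_spec(fixed = covs,
                                          random = c("1", covariate),
                                          label = paste0("M5[", covariate, "]v")),
                          nodes, from = red)
    return(list(fit = fit,
                test = lrt_variance_components(fit, red, df = 2L),
                covariate = covariate))
  }

  if (is.null(m4c)) m4c <- model5_baseline(tab, nodes)
  fit <- fit_best_start(tab, model_spec(
    fixed = c("linear_predictor", covariate),
    random = c("1", "linear_predictor", covariate),
    label = paste0("M5[", covariate, "]")), nodes, from = m4c)
  list(fit = fit, test = lrt_variance_components(fit, m4c, df = 3L),
       covariate = covariate)
}

# the centred-LP random-intercept + random-calibration-slope fit against
# which each Model 5 variant is tested
model5_baseline <- function(tab_centered, nodes = 15L) {
  m3c <- fit_glmm(tab_centered,
                  model_spec(fixed = "linear_predictor", random = "1",
                             label = "M3c"), nodes = 1L)
  fit_best_start(tab_centered,
                 model_spec(fixed = "linear_predictor",
                            random = c("1", "linear_predictor"),
                            label = "M4c"), nodes, from = m3c)
}

#' Temporal main-effect model (Model 6)
#'
#' Random-intercept model with fixed effects for the linear predictor and
#' the temporal period.
#'
#' @inheritParams run_model2
#' @return A `glmm_fit`.
#' @export
run_model6 <- function(table, nodes = 15L) {
  require_lp(table)
  fit_glmm(table, model_spec(fixed = c("linear_predictor", "period"),
                             random = "1", label = "M6"), nodes = nodes)
}

#' Period-by-linear-predictor interaction model (Model 7)
#'
#' @inheritParams run_model2
#' @return A `glmm_fit`; the `linear_predictor:period` row of its
#'   coefficient table carries the interaction estimate, Wald CI and test.
#' @export
run_model7 <- function(table, nodes = 15L) {
  require_lp(table)
  fit_glmm(table, model_spec(
    fixed = c("linear_predictor", "period"),
    interactions = list(c("linear_predictor", "period")),
    random = "1", label = "M7"), nodes = nodes)
}

#' Per-covariate temporal-interaction model (Model 8)
#'
#' Random-intercept model with the period, the 11 covariates, and every
#' period-by-covariate interaction (12 main effects + 11 interactions).
#' Phase-specific odds ratios for covariate j are `exp(beta_j)` in phase 1
#' and `exp(beta_j + gamma_j)` in phase 2.
#'
#' @inheritParams run_model2
#' @return A `glmm_fit`.
#' @export
run_model8 <- function(table, nodes = 15L) {
  covs <- all_predictors(attr(table, "spec", exact = TRUE))
  fit_glmm(table, model_spec(
    fixed = c("period", covs),
    interactions = lapply(covs, function(v) c(v, "period")),
    random = "1", label = "M8"), nodes = nodes)
}

#' Joint geographic-temporal heterogeneity model (Model 9)
#'
#' The full model carries hospital-level random effects for the intercept,
#' the linear-predictor slope, the temporal effect, and their interaction
#' (unstructured 4x4 G; Laplace approximation). Three variance-component
#' tests are run:
#' \describe{
#'   \item{interaction (df = 4)}{full model vs the model that keeps the
#'     fixed period-by-LP interaction but drops its 4 variance-covariance
#'     terms.}
#'   \item{temporal (df = 3)}{on the reduced model (fixed interaction and
#'     its variance terms removed): the 3 terms of the random temporal
#'     effect.}
#'   \item{lp_or_temporal (df = 5)}{on the reduced model: the 5 terms
#'     involving the LP slope or the temporal effect.}
#' }
#'
#' @inheritParams run_model2
#' @return List with `full`, `reduced` (both `glmm_fit`) and `tests`
#'   (named list of three `lrt_result`s).
#' @export
run_model9 <- function(table, nodes = 15L) {
  require_lp(table)
  inter <- list(c("linear_predictor", "period"))
  # nested fits first; the higher-dimensional fits are warm started from
  # them (and fall back to a cold start if that lands lower)
  q1 <- fit_glmm(table, model_spec(
    fixed = c("linear_predictor", "period"),
    random = "1", label = "M9r-int"), nodes = 1L)
  q2 <- fit_best_start(table, model_spec(
    fixed = c("linear_predictor", "period"),
    random = c("1", "linear_predictor"), label = "M9r-noT"), nodes,
    from = q1)
  reduced <- fit_best_start(table, model_spec(
    fixed = c("linear_predictor", "period"),
    random = c("1", "linear_predictor", "period"),
    label = "M9r"), nodes, from = q2)
  aux <- fit_best_start(table, model_spec(
    fixed = c("linear_predictor", "period"), interactions = inter,
    random = c("1", "linear_predictor", "period"),
    label = "M9a"), nodes, from = reduced, use_fixef = FALSE)
  full <- fit_best_start(table, model_spec(
    fixed = c("linear_predictor", "period"), interactions = inter,
    random = c("1", "linear_predictor", "period", "linear_predictor:period"),
    label = "M9"), nodes, from = aux)
  list(full = full, reduced = reduced,
       tests = list(
         interaction = lrt_variance_components(full, aux, df = 4L),
         temporal = lrt_variance_components(reduced, q2, df = 3L),
         lp_or_temporal = lrt_variance_components(reduced, q1, df = 5L)))
}

# fit with a warm start taken from a nested fit, keeping whichever of the
# warm- and cold-started optima has the higher marginal likelihood
fit_best_start <- function(table, spec, nodes, from, use_fixef = TRUE) {
  q_new <- spec_q(spec)
  q_old <- spec_q(from$spec)
  start <- list(theta = pad_theta(from$theta, q_old, q_new))
  if (use_fixef && identical(fixed_rhs(spec), fixed_rhs(from$spec)))
    start$fixef <- from$fixef
  warm <- tryCatch(fit_glmm(table, spec, nodes = nodes, start = start),
                   error = function(e) NULL)
  if (!is.null(warm) && warm$loglik >= from$loglik - 1e-6) return(warm)
  cold <- tryCatch(fit_glmm(table, spec, nodes = nodes),
                   error = function(e) NULL)
  if (is.null(warm) && is.null(cold))
    stop("model ", spec$label, " could not be fitted", call. = FALSE)
  if (is.null(cold) || (!is.null(warm) && warm$loglik >= cold$loglik))
    warm else cold
}

#' Run the full heterogeneity suite
#'
#' Executes Models 1-9 in order on a prepared cohort: the fixed-effects fit
#' and its linear predictor, the geographic models with their
#' variance-component tests (one Model 5 variant per covariate; individual
#' failures are recorded as notes rather than aborting), the temporal
#' models, and the joint Model 9 with its three tests.
#'
#' @param table A prepared `cohort_table`.
#' @param models Character subset of `c("M1", ..., "M9")`; models whose
#'   prerequisites are excluded are fitted on demand. `"M1"` always runs.
#' @param nodes Adaptive Gauss-Hermite nodes for single-random-term models.
#' @param m5_covariates Covariates to cycle through in Model 5 (default:
#'   all of them).
#' @return A `suite_result`: `fits` (named list of `glmm_fit`), `tests`
#'   (named list of `lrt_result`), `lp_offset`, and `notes` (diagnostics,
#'   boundary flags, failures).
#' @export
run_suite <- function(table, models = paste0("M", 1:9), nodes = 15L,
                      m5_covariates = NULL) {
  models <- union("M1", models)
  fits <- list()
  tests <- list()
  notes <- character(0)

  note_fit <- function(fit) {
    lab <- fit$spec$label
    if (!fit$converged)
      notes <<- c(notes, paste0(lab, ": did not converge (",
                                fit$diagnostic %||% "no diagnostic", ")"))
    if (fit$boundary)
      notes <<- c(notes, paste0(lab, ": variance estimate at the zero boundary"))
    fit
  }

  m1 <- run_model1(table)
  fits$M1 <- note_fit(m1$fit)
  table <- m1$table

  if ("M2" %in% models) fits$M2 <- note_fit(run_model2(table, nodes))
  m3 <- NULL
  if (any(c("M3", "M4") %in% models)) {
    m3 <- run_model3(table, nodes)
    if ("M3" %in% models) fits$M3 <- note_fit(m3)
  }
  if ("M4" %in% models) {
    m4 <- run_model4(table, nodes, m3 = m3)
    fits$M4 <- note_fit(m4$fit)
    tests$M4_vs_M3 <- m4$test
  }
  if ("M5" %in% models) {
    spec <- attr(table, "spec", exact = TRUE)
    covs <- m5_covariates %||% all_predictors(spec)
    tab_c <- center_linear_predictor(table)
    m4c <- tryCatch(
      note_fit(model5_baseline(tab_c, nodes)),
      error = function(e) {
        notes <<- c(notes, paste0("M4c: ", conditionMessage(e)))
        NULL
      })
    for (v in covs) {
      res <- tryCatch(run_model5(table, v, nodes = nodes, m4c = m4c),
                      error = function(e) e)
      lab <- paste0("M5[", v, "]")
      if (inherits(res, "error")) {
        notes <- c(notes, paste0(lab, ": could not be fitted (",
                                 conditionMessage(res), ")"))
      } else {
        fits[[lab]] <- note_fit(res$fit)
        tests[[lab]] <- res$test
      }
    }
  }
  if ("M6" %in% models) fits$M6 <- note_fit(run_model6(table, nodes))
  if ("M7" %in% models) fits$M7 <- note_fit(run_model7(table, nodes))
  if ("M8" %in% models) fits$M8 <- note_fit(run_model8(table, nodes))
  if ("M9" %in% models) {
    m9 <- tryCatch(run_model9(table, nodes), error = function(e) e)
    if (inherits(m9, "error")) {
      notes <- c(notes, paste0("M9: could not be fitted (",
                               conditionMessage(m9), ")"))
    } else {
      fits$M9 <- note_fit(m9$full)
      fits[["M9-reduced"]] <- note_fit(m9$reduced)
      tests$M9_interaction <- m9$tests$interaction
      tests$M9_temporal <- m9$tests$temporal
      tests$M9_lp_or_temporal <- m9$tests$lp_or_temporal
    }
  }

  structure(
    list(fits = fits, tests = tests,
         lp_offset = attr(table, "lp_offset", exact = TRUE) %||% 0,
         notes = notes),
    class = "suite_result"
  )
}

#' @export
print.suite_result <- function(x, ...) {
  cat("Heterogeneity suite:", length(x$fits), "fits,",
      length(x$tests), "variance-component tests\n")
  for (lab in names(x$fits)) {
    f <- x$fits[[lab]]
    cat(sprintf("  %-18s logLik %12.3f  %-15s %s\n", lab, f$loglik, f$method,
                if (f$converged) "" else "[not converged]"))
  }
  for (lab in names(x$tests)) {
    t <- x$tests[[lab]]
    cat(sprintf("  %-22s chi2 = %7.3f (df = %d), P = %.4g\n",
                lab, t$chi2, t$df, t$p_value))
  }
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
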