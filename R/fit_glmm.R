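#' Random-effects logistic regression by maximum marginal likelihood
#'
#' Fits a logistic model with cluster-level Gaussian random effects,
#' maximising the marginal likelihood in which the random effects are
#' integrated out. A single random term (`q = 1`) is integrated by adaptive
#' Gauss-Hermite quadrature (15 nodes by default); with `q >= 2` the Laplace
#' approximation is used, which keeps the four-dimensional models of the
#' suite tractable. The covariance `G` of the random effects is unstructured
#' and parameterised through its Cholesky factor, so positive
#' semi-definiteness holds by construction. Estimation is delegated to
#' [lme4::glmer()].
#'
#' A variance estimated at the zero boundary is reported as 0 with
#' `boundary = TRUE`, not as an error. Non-convergence after the iteration
#' cap returns the last iterate with `converged = FALSE` and a diagnostic
#' message. A random-effect dimension above 6 (e.g. a full random
#' coefficients model over all 11 predictors plus intercept) is refused:
#' the marginal likelihood of such models is not reliably maximisable at
#' registry scale and the suite deliberately does not attempt it.
#'
#' @param table A prepared `cohort_table`.
#' @param spec A [model_spec()] with at least one random term.
#' @param nodes Number of adaptive Gauss-Hermite nodes used when `q = 1`.
#' @param start Optional starting values forwarded to [lme4::glmer()]
#'   (a list with `theta` and optionally `fixef`); used by the suite to warm
#'   start high-dimensional fits from their nested neighbours.
#' @return A `glmm_fit`: fixed coefficients with Wald 95% limits, the
#'   estimated `G` (with SDs and correlations), the maximized marginal
#'   log-likelihood, the integration method, per-hospital empirical-Bayes
#'   modes (`eb_modes`), and convergence metadata.
#' @export
fit_glmm <- function(table, spec, nodes = 15L, start = NULL) {
  q <- spec_q(spec)
  if (q < 1L) stop("spec has no random terms; use fit_fixed_logistic()",
                   call. = FALSE)
  if (q > 6L)
    stop("a model with ", q, " correlated random terms per hospital is ",
         "refused: an unstructured G of this dimension (", q * (q + 1) / 2,
         " variance-covariance parameters) is not reliably estimable; ",
         "examine predictors one at a time instead", call. = FALSE)
  H <- length(unique(table$cluster_id))
  if (H < 2L) stop("random-effects fits require at least 2 hospitals",
                   call. = FALSE)

  check_design_rank(table, spec)
  dat <- as.data.frame(table)
  dat$cluster_id <- factor(dat$cluster_id)
  nagq <- if (q == 1L) as.integer(nodes) else 1L
  form <- glmm_formula(spec)

  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(form, data = dat, family = stats::binomial(),
                nAGQ = nagq, start = start,
                control = lme4::glmerControl(calc.derivs = FALSE)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )

  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- lme4::VarCorr(fit)[["cluster_id"]]
  G <- matrix(as.numeric(vc), nrow(vc), ncol(vc),
              dimnames = list(rownames(vc), colnames(vc)))
  eb <- as.matrix(lme4::ranef(fit)[["cluster_id"]])

  boundary <- any(diag(G) < 1e-8) || lme4::isSingular(fit, tol = 1e-4)
  conv_msgs <- fit@optinfo$conv$lme4$messages
  hard_fail <- fit@optinfo$conv$opt != 0 ||
    any(grepl("failed to converge", c(msgs, unlist(conv_msgs)),
              ignore.case = TRUE))

  out <- new_glmm_fit(
    beta = data.frame(term = names(b), estimate = unname(b), se = se,
                      ci_lo = unname(b) - 1.96 * se,
                      ci_hi = unname(b) + 1.96 * se, row.names = NULL),
    G = G,
    loglik = as.numeric(stats::logLik(fit)),
    method = if (q == 1L) paste0("quadrature(", nagq, ")") else "laplace",
    converged = !hard_fail,
    boundary = boundary,
    eb_modes = eb,
    spec = spec,
    n_obs = nrow(dat),
    n_clusters = H,
    fitted_lp = NULL,
    diagnostic = if (length(msgs) || length(conv_msgs))
      paste(unique(c(msgs, unlist(conv_msgs))), collapse = "; ") else NULL
  )
  out$theta <- lme4::getME(fit, "theta")
  out$fixef <- b
  out
}

# embed the relative Cholesky factor of a q-dimensional fit into the first
# q rows/columns of a (q+k)-dimensional one (new terms start at zero)
pad_theta <- function(theta, q_old, q_new) {
  L <- matrix(0, q_new, q_new)
  Lo <- matrix(0, q_old, q_old)
  Lo[lower.tri(Lo, diag = TRUE)] <- theta
  L[seq_len(q_old), seq_len(q_old)] <- Lo
  L[lower.tri(L, diag = TRUE)]
}

#' Likelihood-ratio test for variance-covariance components
#'
#' Compares two nested maximum-likelihood fits with
#' `chi2 = 2 * (loglik_full - loglik_reduced)` referred to a chi-squared
#' distribution whose degrees of freedom equal the number of
#' variance-covariance parameters removed. No boundary mixture correction
#' is applied: the naive chi-squared reference is used deliberately, which
#' is conservative when variances sit on the zero boundary.
#'
#' @param full,reduced `glmm_fit` objects, `reduced` nested in `full`.
#' @param df Degrees of freedom: the number of variance-covariance terms
#'   set to zero in the reduced model. When `NULL`, computed as the
#'   difference in unstructured-G parameter counts of the two specs.
#' @return An `lrt_result` with fields `chi2` (clamped at 0), `df`,
#'   `p_value`, the two spec labels, and `reliable` (`FALSE` when either
#'   fit failed to converge).
#' @export
lrt_variance_components <- function(full, reduced, df = NULL) {
  if (!spec_is_nested(reduced$spec, full$spec))
    stop("'reduced' model is not nested in 'full'", call. = FALSE)
  if (is.null(df))
    df <- spec_n_vc(full$spec) - spec_n_vc(reduced$spec)
  df <- as.integer(df)
  if (df < 1L) stop("df must be >= 1", call. = FALSE)
  chi2 <- 2 * (full$loglik - reduced$loglik)
  if (chi2 < 0) {
    # small deficits are optimizer / integration noise at a null optimum;
    # a large one means the full model's optimizer failed
    if (chi2 < -0.5)
      warning("full-model log-likelihood below reduced-model value by ",
              format(-chi2 / 2), "; chi-square clamped at 0")
    chi2 <- 0
  }
  structure(
    list(chi2 = chi2, df = df,
         p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
         full = full$spec$label, reduced = reduced$spec$label,
         reliable = full$converged && reduced$converged),
    class = "lrt_result"
  )
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("Variance-component LRT%s: chi2 = %.4g (df = %d), P = %.4g%s\n",
              if (!is.null(x$full))
                sprintf(" [%s vs %s]", x$full, x$reduced) else "",
              x$chi2, x$df, x$p_value,
              if (!x$reliable) "  [unreliable: a fit did not converge]" else ""))
  invisible(x)
}
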