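#' Fixed-effects logistic regression by iteratively reweighted least squares
#'
#' Maximises the Bernoulli log-likelihood with Newton-Raphson (IRLS) steps.
#' Standard errors come from the inverse observed information at the
#' optimum. Separation is flagged when a coefficient exceeds 15 on the
#' logit scale while the likelihood is still improving; the last iterate is
#' returned with `converged = FALSE`.
#'
#' @param table A prepared `cohort_table`.
#' @param spec A [model_spec()] with no random terms.
#' @param max_iter Newton iteration cap.
#' @param tol Relative log-likelihood convergence tolerance.
#' @return A `glmm_fit` with `method = "exact"` and an empty random part.
#' @export
fit_fixed_logistic <- function(table, spec, max_iter = 100L, tol = 1e-10) {
  if (spec_q(spec) > 0L)
    stop("spec has random terms; use fit_glmm()", call. = FALSE)
  y <- table$outcome
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; the MLE does not exist", call. = FALSE)
  X <- check_design_rank(table, spec)

  beta <- numeric(ncol(X))
  beta[1] <- stats::qlogis(mean(y))
  ll_old <- -Inf
  converged <- FALSE
  separation <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    ll <- sum(y * eta - log1p(exp(eta)))
    w <- mu * (1 - mu)
    # Newton step: (X'WX)^{-1} X'(y - mu)
    XtWX <- crossprod(X, X * w)
    score <- crossprod(X, y - mu)
    step <- solve(XtWX, score)
    beta <- beta + drop(step)
    if (max(abs(beta)) > 15 && ll > ll_old) {
      separation <- TRUE
      break
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  loglik <- sum(y * eta - log1p(exp(eta)))
  vcov <- solve(crossprod(X, X * (mu * (1 - mu))))
  se <- sqrt(diag(vcov))

  new_glmm_fit(
    beta = data.frame(term = colnames(X), estimate = beta, se = se,
                      ci_lo = beta - 1.96 * se, ci_hi = beta + 1.96 * se,
                      row.names = NULL),
    G = matrix(numeric(0), 0, 0),
    loglik = loglik,
    method = "exact",
    converged = converged && !separation,
    boundary = FALSE,
    separation = separation,
    eb_modes = NULL,
    spec = spec,
    n_obs = nrow(table),
    n_clusters = length(unique(table$cluster_id)),
    fitted_lp = eta
  )
}
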