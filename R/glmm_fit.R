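# Constructor and methods for fitted-model objects shared by the exact
# (fixed-effects) and marginal-likelihood (random-effects) fitters.

new_glmm_fit <- function(beta, G, loglik, method, converged, boundary,
                         separation = FALSE, eb_modes = NULL, spec,
                         n_obs, n_clusters, fitted_lp = NULL,
                         diagnostic = NULL) {
  structure(
    list(beta = beta, G = G, loglik = loglik, method = method,
         converged = converged, boundary = boundary, separation = separation,
         eb_modes = eb_modes, spec = spec, n_obs = n_obs,
         n_clusters = n_clusters, fitted_lp = fitted_lp,
         n_params = nrow(beta) + length(G[upper.tri(G, diag = TRUE)]),
         diagnostic = diagnostic),
    class = "glmm_fit"
  )
}

#' Coefficient table of a fitted model
#'
#' @param object A `glmm_fit`.
#' @param ... Unused.
#' @return Data frame with columns `term`, `estimate`, `se`, `ci_lo`,
#'   `ci_hi` (95% Wald limits on the log-odds scale).
#' @export
coef.glmm_fit <- function(object, ...) object$beta

#' @export
logLik.glmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

# random-effect SDs (empty for a fixed-effects fit)
re_sd <- function(fit) {
  if (length(fit$G) == 0L) return(numeric(0))
  sqrt(diag(fit$G))
}

#' @export
print.glmm_fit <- function(x, digits = 4, ...) {
  lab <- x$spec$label %||% "model"
  cat(sprintf("Logistic %s fit [%s], n = %d, hospitals = %d\n",
              if (spec_q(x$spec) > 0L) "mixed-model" else "regression",
              lab, x$n_obs, x$n_clusters))
  cat(sprintf("  method: %s   logLik: %.3f   converged: %s%s%s\n",
              x$method, x$loglik, x$converged,
              if (x$boundary) "   [variance at boundary]" else "",
              if (x$separation) "   [separation]" else ""))
  b <- x$beta
  b$or <- exp(b$estimate)
  cat("  fixed effects (log-odds scale, OR = exp):\n")
  print(format(b, digits = digits), row.names = FALSE)
  if (spec_q(x$spec) > 0L) {
    cat("  random-effect SDs over hospitals:\n")
    sds <- re_sd(x)
    names(sds) <- x$spec$random
    print(round(sds, digits))
  }
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Emits coefficients with standard errors and Wald limits, the
#' random-effects covariance matrix, the maximized marginal log-likelihood,
#' the integration method, and convergence metadata.
#'
#' @param fit A `glmm_fit`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
fit_to_json <- function(fit, path = NULL) {
  payload <- list(
    label = fit$spec$label,
    fixed = fit$beta,
    G = fit$G,
    random_terms = fit$spec$random,
    loglik = fit$loglik,
    method = fit$method,
    converged = fit$converged,
    boundary = fit$boundary,
    n_obs = fit$n_obs,
    n_clusters = fit$n_clusters,
    n_params = fit$n_params
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor", null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
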