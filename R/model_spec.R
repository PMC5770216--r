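#' Declarative specification of one logistic model
#'
#' Describes the fixed terms, interactions, and cluster-level random terms
#' of one model in the heterogeneity suite. The random-effects covariance is
#' always unstructured over the listed random terms.
#'
#' @param fixed Character vector of fixed-effect column names (an intercept
#'   is always included implicitly).
#' @param interactions List of length-2 character vectors, each a pair of
#'   column names whose product enters as a fixed effect.
#' @param random Character vector of terms with cluster-level random
#'   coefficients; `"1"` denotes the random intercept, and an interaction is
#'   written `"a:b"`. May be empty (purely fixed-effects model).
#' @param label Optional display label (e.g. `"M2"`).
#' @return A `model_spec` object; its random-effect dimension `q` equals
#'   `length(random)`.
#' @export
model_spec <- function(fixed = character(), interactions = list(),
                       random = character(), label = NULL) {
  fixed <- as.character(fixed)
  random <- as.character(random)
  inter_lab <- vapply(interactions, function(p) paste(p, collapse = ":"), "")
  allowed <- c("1", fixed, inter_lab)
  if (!all(random %in% allowed))
    stop("random terms must be '1', a fixed term, or a declared interaction; ",
         "offending: ", paste(setdiff(random, allowed), collapse = ", "),
         call. = FALSE)
  structure(
    list(fixed = fixed, interactions = interactions, random = random,
         label = label),
    class = "model_spec"
  )
}

spec_q <- function(spec) length(spec$random)

# number of free variance-covariance parameters of an unstructured q x q G
spec_n_vc <- function(spec) {
  q <- spec_q(spec)
  q * (q + 1L) / 2L
}

# right-hand side of the fixed part, e.g. "x1 + x2 + a:b"
fixed_rhs <- function(spec) {
  terms <- c(spec$fixed,
             vapply(spec$interactions, function(p) paste(p, collapse = ":"), ""))
  if (length(terms) == 0L) "1" else paste(terms, collapse = " + ")
}

# full lme4 formula, e.g. y ~ x1 + x2 + (1 + x1 | cluster_id)
glmm_formula <- function(spec) {
  rhs <- fixed_rhs(spec)
  if (spec_q(spec) > 0L) {
    r <- spec$random
    bar <- if ("1" %in% r) {
      paste(c("1", setdiff(r, "1")), collapse = " + ")
    } else {
      paste(c("0", r), collapse = " + ")
    }
    rhs <- paste0(rhs, " + (", bar, " | cluster_id)")
  }
  stats::as.formula(paste("outcome ~", rhs))
}

# fixed-effects design matrix, with an error naming collinear columns
check_design_rank <- function(table, spec) {
  X <- stats::model.matrix(stats::as.formula(paste("~", fixed_rhs(spec))),
                           data = table)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  X
}

# is `reduced` nested in `full`? (terms are compared as label sets)
spec_is_nested <- function(reduced, full) {
  ri <- vapply(reduced$interactions, function(p) paste(p, collapse = ":"), "")
  fi <- vapply(full$interactions, function(p) paste(p, collapse = ":"), "")
  all(reduced$fixed %in% full$fixed) && all(ri %in% fi) &&
    all(reduced$random %in% full$random)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model spec%s: outcome ~ %s\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              fixed_rhs(x)))
  if (spec_q(x) > 0L)
    cat("  random over hospitals:", paste(x$random, collapse = ", "),
        sprintf("(q = %d, unstructured G)\n", spec_q(x)))
  invisible(x)
}
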