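#' Median odds ratio of a random-intercept distribution
#'
#' For hospital random intercepts with SD `sigma` on the log-odds scale,
#' the median, over random pairs of hospitals, of the odds ratio between
#' the higher- and lower-risk hospital for identical patients:
#' `exp(sqrt(2) * sigma * qnorm(0.75))`. The 0.75 normal quantile is
#' evaluated at full precision rather than the conventional 0.6745.
#'
#' @param sigma Random-intercept SD (log-odds scale), `>= 0`.
#' @return The median odds ratio, always `>= 1`.
#' @export
median_odds_ratio <- function(sigma) {
  if (any(sigma < 0)) stop("sigma must be non-negative", call. = FALSE)
  exp(sqrt(2) * sigma * stats::qnorm(0.75))
}

#' Central range of hospital-specific outcome probabilities
#'
#' Inverse-logit of `mu +/- z * sigma`: the interval containing the
#' hospital-specific outcome probability of a reference patient (linear
#' predictor zero) for the central `coverage` share of hospitals, under a
#' normal random-intercept distribution.
#'
#' @param mu Mean of the random-intercept distribution (log-odds scale).
#' @param sigma Its SD, `>= 0`.
#' @param coverage Nominal central mass, in (0, 1); default 0.95.
#' @return Named numeric `c(lower, upper)` of probabilities.
#' @export
reference_probability_range <- function(mu, sigma, coverage = 0.95) {
  z <- range_z(sigma, coverage)
  c(lower = stats::plogis(mu - z * sigma),
    upper = stats::plogis(mu + z * sigma))
}

#' Central range of hospital-specific odds ratios
#'
#' `exp(mu +/- z * sigma)` for a covariate whose hospital-level log-odds
#' coefficients are `N(mu, sigma^2)`.
#'
#' @inheritParams reference_probability_range
#' @param mu Mean of the hospital-level coefficient distribution.
#' @return Named numeric `c(lower, upper)` of odds ratios.
#' @export
odds_ratio_range <- function(mu, sigma, coverage = 0.95) {
  z <- range_z(sigma, coverage)
  c(lower = exp(mu - z * sigma), upper = exp(mu + z * sigma))
}

range_z <- function(sigma, coverage) {
  if (any(sigma < 0)) stop("sigma must be non-negative", call. = FALSE)
  if (coverage <= 0 || coverage >= 1)
    stop("coverage must lie in (0, 1)", call. = FALSE)
  stats::qnorm(1 - (1 - coverage) / 2)
}

#' Heterogeneity summary of one random effect
#'
#' Bundles the mean and SD of a fitted random-effect distribution with the
#' derived median odds ratio and central-95% ranges, ready for reporting.
#'
#' @param mu Mean of the effect distribution (log-odds or coefficient
#'   scale).
#' @param sigma Its SD.
#' @param coverage Central mass for the ranges.
#' @param kind `"intercept"` (probability range for a reference patient) or
#'   `"coefficient"` (odds-ratio range).
#' @return A `heterogeneity_summary` list with `mu`, `sigma`, `mor`,
#'   `range_prob` or `range_or`, and `coverage`.
#' @export
heterogeneity_summary <- function(mu, sigma, coverage = 0.95,
                                  kind = c("intercept", "coefficient")) {
  kind <- match.arg(kind)
  out <- list(mu = mu, sigma = sigma, mor = median_odds_ratio(sigma),
              coverage = coverage, kind = kind)
  if (kind == "intercept")
    out$range_prob <- reference_probability_range(mu, sigma, coverage)
  else
    out$range_or <- odds_ratio_range(mu, sigma, coverage)
  structure(out, class = "heterogeneity_summary")
}

#' @export
print.heterogeneity_summary <- function(x, ...) {
  cat(sprintf("Random %s ~ N(mu = %.4g, sigma = %.4g); MOR = %.2f\n",
              x$kind, x$mu, x$sigma, x$mor))
  if (x$kind == "intercept")
    cat(sprintf("  reference-patient probability in (%.3f, %.3f) for %g%% of hospitals\n",
                x$range_prob[1], x$range_prob[2], 100 * x$coverage))
  else
    cat(sprintf("  hospital-specific OR in (%.2f, %.2f) for %g%% of hospitals\n",
                x$range_or[1], x$range_or[2], 100 * x$coverage))
  invisible(x)
}

#' Summarise the temporal-period effect of a fitted model
#'
#' Extracts the period coefficient, its odds ratio and Wald 95% CI, and a
#' plain-language relative-odds statement ("x% lower in the second phase").
#'
#' @param fit A `glmm_fit` whose fixed effects include `period`.
#' @return List with `log_or`, `or`, `ci` (OR scale), `p_value` and
#'   `percent_lower` (rounded to integer; negative when odds increased).
#' @export
period_effect_summary <- function(fit) {
  b <- fit$beta
  i <- match("period", b$term)
  if (is.na(i)) stop("fit has no 'period' fixed effect", call. = FALSE)
  est <- b$estimate[i]
  se <- b$se[i]
  list(
    log_or = est,
    or = exp(est),
    ci = c(lower = exp(b$ci_lo[i]), upper = exp(b$ci_hi[i])),
    p_value = 2 * stats::pnorm(-abs(est / se)),
    percent_lower = round(100 * (1 - exp(est))),
    statement = sprintf("adjusted odds of the outcome were %d%% %s in the second phase",
                        abs(round(100 * (1 - exp(est)))),
                        if (est <= 0) "lower" else "higher")
  )
}
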