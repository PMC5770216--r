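#' Configuration of the clustered two-period cohort generator
#'
#' Defaults emulate the structure of the EFFECT heart-failure registry
#' analyses: 90 hospitals, 14,857 patients split 7549/7308 across two
#' phases, hospital random intercepts N(-1.25, 0.18^2) on the log-odds
#' scale, covariate effects equal to the published random-intercept-model
#' odds ratios of the 11-predictor mortality model, and a phase-2 log-odds
#' shift of -0.111. Covariate marginal distributions are not published;
#' the defaults use independent normals with plausible clinical SDs for
#' the continuous predictors (age 12 y, systolic blood pressure 30 mmHg,
#' respiratory rate 8 breaths/min, serum urea nitrogen 10 units on its
#' recorded scale, whose units the source model leaves unstated) and fixed
#' prevalences for the binary ones, chosen once so the marginal event rate
#' lands near 0.32.
#'
#' @param n_clusters Number of hospitals.
#' @param n_total Total patients (split across clusters near-equally).
#' @param period1_fraction Share of each hospital's patients in phase 1.
#' @param beta Named log-odds ratios for the 11 covariates.
#' @param intercept_mu Mean hospital log-odds for the reference patient.
#' @param sigma_intercept SD of the hospital random intercept.
#' @param sigma_lp_slope SD of a hospital-level random slope multiplying
#'   the (centred) true linear predictor; 0 disables slope heterogeneity.
#' @param sigma_period SD of a hospital-level random temporal effect.
#' @param sigma_period_lp SD of a hospital-level random period-by-linear-
#'   predictor interaction.
#' @param covariate_random_sd Optional named vector: SD of a hospital-level
#'   random add-on coefficient per covariate (e.g. `c(low_sodium = 0.29)`).
#' @param period_log_or Fixed phase-2 log-odds ratio.
#' @param period_interactions Optional named vector of fixed
#'   period-by-covariate interaction log-odds ratios.
#' @param continuous_sd Named SDs of the four continuous covariates
#'   (generated mean-zero, i.e. pre-centred).
#' @param binary_prevalence Named prevalences of the seven binary
#'   covariates.
#' @param seed Integer seed; one seed fully determines the cohort.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_clusters = 90L,
                             n_total = 14857L,
                             period1_fraction = 7549 / 14857,
                             beta = default_generating_beta(),
                             intercept_mu = -1.25,
                             sigma_intercept = 0.18,
                             sigma_lp_slope = 0,
                             sigma_period = 0,
                             sigma_period_lp = 0,
                             covariate_random_sd = NULL,
                             period_log_or = -0.111,
                             period_interactions = NULL,
                             continuous_sd = c(age = 12, sbp = 30,
                                               resp_rate = 8, urea = 10),
                             binary_prevalence = c(low_sodium = 0.15,
                                                   low_hemoglobin = 0.10,
                                                   cancer = 0.12, copd = 0.20,
                                                   cvd = 0.15,
                                                   cirrhosis = 0.01,
                                                   dementia = 0.10),
                             seed = 20170413L) {
  cfg <- list(n_clusters = as.integer(n_clusters),
              n_total = as.integer(n_total),
              period1_fraction = period1_fraction,
              beta = beta, intercept_mu = intercept_mu,
              sigma_intercept = sigma_intercept,
              sigma_lp_slope = sigma_lp_slope,
              sigma_period = sigma_period,
              sigma_period_lp = sigma_period_lp,
              covariate_random_sd = covariate_random_sd,
              period_log_or = period_log_or,
              period_interactions = period_interactions,
              continuous_sd = continuous_sd,
              binary_prevalence = binary_prevalence,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

#' Generating log-odds ratios of the 11-predictor mortality model
#'
#' Log odds ratios of the published random-intercept fit, used as the
#' generator's default truth.
#'
#' @return Named numeric vector of length 11.
#' @export
default_generating_beta <- function() {
  log(c(age = 1.043, sbp = 0.987, resp_rate = 1.025, urea = 1.106,
        low_sodium = 1.364, low_hemoglobin = 1.172, cancer = 1.682,
        copd = 1.329, cvd = 1.326, cirrhosis = 1.914, dementia = 2.136))
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_clusters >= 1L, cfg$n_total >= cfg$n_clusters)
  if (cfg$period1_fraction <= 0 || cfg$period1_fraction >= 1)
    stop("period1_fraction must lie in (0, 1)", call. = FALSE)
  sds <- c(cfg$sigma_intercept, cfg$sigma_lp_slope, cfg$sigma_period,
           cfg$sigma_period_lp, cfg$covariate_random_sd, cfg$continuous_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (any(cfg$binary_prevalence <= 0 | cfg$binary_prevalence >= 1))
    stop("binary prevalences must lie in (0, 1)", call. = FALSE)
  covs <- c(names(cfg$continuous_sd), names(cfg$binary_prevalence))
  if (!setequal(names(cfg$beta), covs))
    stop("beta must name exactly the covariates with declared marginals",
         call. = FALSE)
  extra <- setdiff(c(names(cfg$covariate_random_sd),
                     names(cfg$period_interactions)), covs)
  if (length(extra))
    stop("unknown covariate(s) in random-SD / interaction maps: ",
         paste(extra, collapse = ", "), call. = FALSE)
  invisible(cfg)
}

# deterministic per-cluster substream seed, stable under changes to
# n_clusters so earlier clusters never reshuffle
cluster_seed <- function(seed, h) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(h) * 7919) %% 2147483629)
}

#' Generate one clustered two-period cohort
#'
#' Per hospital, draws independent Gaussian random effects for each
#' configured heterogeneity source; per patient, draws covariates from
#' their marginals (continuous ones pre-centred), assigns the phase by the
#' configured split, and draws the binary outcome from the logistic model
#' \deqn{logit P(y=1) = \mu + b_{0h} + x'\beta + u_h \tilde{x}'\beta +
#'   t(\gamma + v_h + w_h \tilde{x}'\beta) + \sum_j c_{jh} x_j,}
#' where \eqn{\tilde{x}'\beta} is the true linear predictor centred at its
#' expectation. Each hospital draws from its own seeded substream, so the
#' same seed reproduces the cohort exactly and growing `n_clusters` leaves
#' earlier hospitals unchanged.
#'
#' @param config A [generator_config()].
#' @return A raw cohort data frame (columns `outcome`, `cluster_id`,
#'   `period`, and the 11 covariates) ready for [prepare_cohort()].
#' @export
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  H <- config$n_clusters
  sizes <- rep(config$n_total %/% H, H)
  rem <- config$n_total %% H
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L

  covs <- names(config$beta)
  beta <- config$beta
  # expected true LP over the covariate marginals (continuous are mean 0)
  lp_mean <- sum(beta[names(config$binary_prevalence)] *
                   config$binary_prevalence)

  out <- vector("list", H)
  for (h in seq_len(H)) {
    set.seed(cluster_seed(config$seed, h))
    b0 <- stats::rnorm(1, 0, config$sigma_intercept)
    u_lp <- stats::rnorm(1, 0, config$sigma_lp_slope)
    v_per <- stats::rnorm(1, 0, config$sigma_period)
    w_perlp <- stats::rnorm(1, 0, config$sigma_period_lp)
    c_cov <- numeric(length(covs))
    names(c_cov) <- covs
    if (!is.null(config$covariate_random_sd))
      for (nm in names(config$covariate_random_sd))
        c_cov[nm] <- stats::rnorm(1, 0, config$covariate_random_sd[[nm]])

    n <- sizes[h]
    x <- matrix(0, n, length(covs), dimnames = list(NULL, covs))
    for (nm in names(config$continuous_sd))
      x[, nm] <- stats::rnorm(n, 0, config$continuous_sd[[nm]])
    for (nm in names(config$binary_prevalence))
      x[, nm] <- stats::rbinom(n, 1, config$binary_prevalence[[nm]])

    n1 <- round(n * config$period1_fraction)
    per <- c(rep(0L, n1), rep(1L, n - n1))

    lp_true <- drop(x %*% beta)
    lp_c <- lp_true - lp_mean
    gamma_int <- numeric(n)
    if (!is.null(config$period_interactions))
      for (nm in names(config$period_interactions))
        gamma_int <- gamma_int + config$period_interactions[[nm]] * x[, nm]

    # the temporal contrast is applied centred at the pooled phase-2 share,
    # so intercept_mu stays the pooled-sample baseline (what the pooled
    # random-intercept model's intercept estimates); the 0/1 period column
    # handed to the models is unaffected, as are all period slopes
    per_c <- per - (1 - config$period1_fraction)
    eta <- config$intercept_mu + b0 + lp_true + u_lp * lp_c +
      per_c * (config$period_log_or + v_per + w_perlp * lp_c + gamma_int) +
      drop(x %*% c_cov)
    y <- stats::rbinom(n, 1, stats::plogis(eta))

    out[[h]] <- data.frame(outcome = y, cluster_id = h, period = per, x,
                           check.names = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a series of independent replicate cohorts
#'
#' Replicate seeds are derived deterministically from `base_seed`, so the
#' same base seed reproduces the same series and different replicates are
#' independent.
#'
#' @param config A [generator_config()] (its own `seed` is overridden).
#' @param n_reps Number of replicates; 0 yields an empty list.
#' @param base_seed Integer base seed.
#' @return List of `n_reps` raw cohort data frames.
#' @export
generate_replicates <- function(config, n_reps, base_seed) {
  lapply(seq_len(n_reps), function(i) {
    config$seed <- replicate_seed(base_seed, i)
    generate_cohort(config)
  })
}

replicate_seed <- function(base_seed, i) {
  as.integer((as.numeric(base_seed) * 69069 + as.numeric(i) * 104729) %%
               2147483629)
}

#' Read / write a generator configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_generator_config()` returns a `generator_config`;
#'   `write_generator_config()` returns `path` invisibly.
#' @export
read_generator_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- generator_config()
  for (nm in names(raw)) {
    if (!nm %in% names(defaults))
      stop("unknown generator config key '", nm, "'", call. = FALSE)
    defaults[[nm]] <- if (is.list(raw[[nm]])) unlist(raw[[nm]]) else raw[[nm]]
  }
  do.call(generator_config, unclass(defaults))
}

#' @rdname read_generator_config
#' @param config A `generator_config`.
#' @export
write_generator_config <- function(config, path) {
  payload <- lapply(unclass(config), function(x)
    if (!is.null(names(x))) as.list(x) else x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
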