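#' Tabular report of a fitted suite
#'
#' One row per fitted model (log-likelihood, integration method, key fixed
#' effects, random-effect SDs, MOR and reference-patient range for
#' random-intercept models) plus one row per variance-component test, and a
#' min/max-p summary for each test family (the 11 Model 5 tests, the Model
#' 8 interaction tests). No multiplicity correction is applied across a
#' family; p values are reported as computed.
#'
#' @param result A `suite_result`.
#' @param coverage Central mass for the reported ranges.
#' @return List of data frames `models`, `tests`, `families`.
#' @export
summarize_suite <- function(result, coverage = 0.95) {
  rows <- lapply(names(result$fits), function(lab) {
    f <- result$fits[[lab]]
    b <- f$beta
    sds <- re_sd(f)
    has_rint <- length(sds) > 0 && "1" %in% f$spec$random
    mu0 <- b$estimate[match("(Intercept)", b$term)]
    sigma0 <- if (has_rint) sds[match("1", f$spec$random)] else NA_real_
    rng <- if (has_rint && is.finite(mu0))
      reference_probability_range(mu0, sigma0, coverage)
    else c(NA_real_, NA_real_)
    data.frame(
      model = lab,
      loglik = f$loglik,
      method = f$method,
      converged = f$converged,
      boundary = f$boundary,
      intercept = if (is.na(match("(Intercept)", b$term))) NA_real_ else mu0,
      lp_slope = b$estimate[match("linear_predictor", b$term)],
      period = b$estimate[match("period", b$term)],
      sigma_intercept = if (has_rint) sigma0 else NA_real_,
      mor = if (has_rint) median_odds_ratio(sigma0) else NA_real_,
      ref_prob_lo = rng[1],
      ref_prob_hi = rng[2],
      random_sds = paste(sprintf("%s=%.4g", f$spec$random, sds),
                         collapse = ", "),
      stringsAsFactors = FALSE
    )
  })
  models <- do.call(rbind, rows)
  rownames(models) <- NULL

  tests <- if (length(result$tests)) do.call(rbind, lapply(
    names(result$tests), function(lab) {
      t <- result$tests[[lab]]
      data.frame(test = lab, chi2 = t$chi2, df = t$df, p_value = t$p_value,
                 reliable = t$reliable, stringsAsFactors = FALSE)
    })) else data.frame(test = character(), chi2 = numeric(),
                        df = integer(), p_value = numeric(),
                        reliable = logical())

  fam_of <- ifelse(grepl("^M5\\[", tests$test), "M5_covariates",
                   ifelse(grepl("^M9", tests$test), "M9", tests$test))
  families <- if (nrow(tests)) do.call(rbind, lapply(
    split(tests, fam_of), function(d)
      data.frame(family = fam_of[match(d$test[1], tests$test)],
                 n_tests = nrow(d), min_p = min(d$p_value),
                 max_p = max(d$p_value), stringsAsFactors = FALSE)))
  else data.frame(family = character(), n_tests = integer(),
                  min_p = numeric(), max_p = numeric())
  rownames(families) <- NULL

  list(models = models, tests = tests, families = families)
}

#' Write a suite result to disk
#'
#' Emits `suite.json` (full-precision fits and tests), `models.tsv` and
#' `tests.tsv` (report tables; MOR and odds ratios displayed to 2 decimals,
#' probabilities to 3), and `narrative.txt` (plain-language summary).
#'
#' @param result A `suite_result`.
#' @param dir Output directory (created if needed).
#' @param coverage Central mass for ranges.
#' @return Invisible character vector of the files written.
#' @export
write_suite_report <- function(result, dir, coverage = 0.95) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rep <- summarize_suite(result, coverage)

  json_path <- file.path(dir, "suite.json")
  payload <- list(
    fits = lapply(result$fits, function(f)
      jsonlite::parse_json(fit_to_json(f))),
    tests = lapply(result$tests, unclass),
    lp_offset = result$lp_offset,
    notes = result$notes
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), json_path)

  disp <- rep$models
  for (nm in c("mor")) disp[[nm]] <- round(disp[[nm]], 2)
  for (nm in c("ref_prob_lo", "ref_prob_hi"))
    disp[[nm]] <- round(disp[[nm]], 3)
  models_path <- file.path(dir, "models.tsv")
  utils::write.table(disp, models_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  tests_path <- file.path(dir, "tests.tsv")
  utils::write.table(rep$tests, tests_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)

  narr_path <- file.path(dir, "narrative.txt")
  writeLines(suite_narrative(result, rep, coverage), narr_path)
  invisible(c(json_path, models_path, tests_path, narr_path))
}

suite_narrative <- function(result, rep = summarize_suite(result),
                            coverage = 0.95) {
  out <- character(0)
  m2 <- result$fits$M2
  if (!is.null(m2)) {
    mu <- m2$beta$estimate[match("(Intercept)", m2$beta$term)]
    s <- re_sd(m2)[match("1", m2$spec$random)]
    hs <- heterogeneity_summary(mu, s, coverage, "intercept")
    out <- c(out, sprintf(
      paste0("Hospital random intercepts: N(mu = %.2f, sigma = %.2f); the ",
             "reference-patient outcome probability lies between %.3f and ",
             "%.3f for %g%% of hospitals; median odds ratio %.2f."),
      mu, s, hs$range_prob[1], hs$range_prob[2], 100 * coverage, hs$mor))
  }
  m6 <- result$fits$M6
  if (!is.null(m6) && !is.na(match("period", m6$beta$term))) {
    pe <- period_effect_summary(m6)
    out <- c(out, sprintf(
      "Temporal period: log-OR %.3f (OR %.2f, 95%% CI %.2f-%.2f); %s.",
      pe$log_or, pe$or, pe$ci[1], pe$ci[2], pe$statement))
  }
  for (lab in names(result$tests)) {
    t <- result$tests[[lab]]
    out <- c(out, sprintf("%s: chi2 = %.2f (df = %d), P = %.4f%s.", lab,
                          t$chi2, t$df, t$p_value,
                          if (!t$reliable) " [unreliable]" else ""))
  }
  if (nrow(rep$families))
    out <- c(out, apply(rep$families, 1, function(r) sprintf(
      "Family %s: %s tests, smallest P = %s (all P > %.4f reported without multiplicity correction).",
      r[["family"]], r[["n_tests"]],
      format(as.numeric(r[["min_p"]]), digits = 3),
      as.numeric(r[["min_p"]]))))
  if (length(result$notes))
    out <- c(out, paste("Note:", result$notes))
  out <- c(out, "No multiplicity correction was applied across test families.")
  out
}
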