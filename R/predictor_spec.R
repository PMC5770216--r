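#' Predictor specification for a prediction model
#'
#' Declares which cohort columns are the model's continuous and binary
#' predictors, and (optionally) the constants used to centre the continuous
#' ones. Centring constants default to the pooled sample means, so that the
#' model intercept refers to a patient who is average on every continuous
#' predictor and has none of the binary risk factors.
#'
#' @param continuous Character vector of continuous predictor column names.
#' @param binary Character vector of binary (0/1) predictor column names.
#' @param centering Optional named numeric vector of centring constants, one
#'   per continuous predictor. When omitted, [prepare_cohort()] computes them
#'   from the pooled two-period sample.
#' @return An object of class `predictor_spec`.
#' @seealso [effect_hf_spec()] for the 11-predictor heart-failure mortality
#'   model specification used throughout the package examples.
#' @export
predictor_spec <- function(continuous, binary, centering = NULL) {
  continuous <- as.character(continuous)
  binary <- as.character(binary)
  if (length(continuous) == 0L || length(binary) == 0L)
    stop("'continuous' and 'binary' must both be non-empty", call. = FALSE)
  if (anyDuplicated(c(continuous, binary)))
    stop("continuous and binary predictor names must be disjoint and unique",
         call. = FALSE)
  if (!is.null(centering)) {
    if (!all(continuous %in% names(centering)))
      stop("'centering' must name every continuous predictor", call. = FALSE)
    centering <- centering[continuous]
    if (!all(is.finite(centering)))
      stop("centring constants must be finite", call. = FALSE)
  }
  structure(
    list(continuous = continuous, binary = binary, centering = centering),
    class = "predictor_spec"
  )
}

#' The 11-predictor EFFECT-HF mortality model specification
#'
#' Four continuous predictors (age, systolic blood pressure, respiratory
#' rate, serum urea nitrogen) and seven binary ones (low serum sodium
#' < 136 mEq/L, low hemoglobin < 10 g/dL, cancer, chronic obstructive
#' pulmonary disease, cerebrovascular disease, hepatic cirrhosis, dementia).
#'
#' @return A `predictor_spec` with the standard column names used by
#'   [generate_cohort()].
#' @export
effect_hf_spec <- function() {
  predictor_spec(
    continuous = c("age", "sbp", "resp_rate", "urea"),
    binary = c("low_sodium", "low_hemoglobin", "cancer", "copd",
               "cvd", "cirrhosis", "dementia")
  )
}

#' @export
print.predictor_spec <- function(x, ...) {
  cat("Predictor specification\n")
  cat("  continuous:", paste(x$continuous, collapse = ", "), "\n")
  cat("  binary:    ", paste(x$binary, collapse = ", "), "\n")
  if (!is.null(x$centering)) {
    cat("  centring constants:\n")
    for (nm in names(x$centering))
      cat(sprintf("    %-12s %.6g\n", nm, x$centering[[nm]]))
  } else {
    cat("  centring constants: to be computed from the pooled sample\n")
  }
  invisible(x)
}

all_predictors <- function(spec) c(spec$continuous, spec$binary)
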