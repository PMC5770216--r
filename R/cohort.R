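#' Prepare a patient-level cohort table for the model suite
#'
#' Validates a raw table (one row per patient), centres the continuous
#' predictors, relabels hospital identifiers to consecutive integers
#' `1..H`, and attaches the predictor specification. All downstream fitting
#' functions require a prepared cohort.
#'
#' Centring constants are the pooled two-period sample means unless the
#' specification already carries them, in which case the stored constants are
#' applied unchanged — so preparing twice is a no-op.
#'
#' @param raw A data frame with columns `outcome` (0/1, 1 = death within one
#'   year), `cluster_id` (hospital label), `period` (0 = first phase,
#'   1 = second phase), plus every predictor named in `spec`.
#' @param spec A [predictor_spec()]; defaults to [effect_hf_spec()].
#' @return A `cohort_table`: a data frame with attributes `spec` (the
#'   specification including the centring constants actually applied),
#'   `cluster_levels` (original hospital labels, indexed by new id), and
#'   `lp_offset` (linear-predictor centring constant, see
#'   [center_linear_predictor()]).
#' @export
prepare_cohort <- function(raw, spec = effect_hf_spec()) {
  raw <- as.data.frame(raw)
  needed <- c("outcome", "cluster_id", "period", all_predictors(spec))
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  use <- raw[, c(needed, intersect("linear_predictor", names(raw))), drop = FALSE]
  bad <- which(!stats::complete.cases(use))
  if (length(bad))
    stop("cohort has missing values in ", length(bad), " row(s): rows ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) ", ..." else "", call. = FALSE)

  if (!all(use$outcome %in% c(0, 1)))
    stop("'outcome' must be coded 0/1", call. = FALSE)
  if (!all(use$period %in% c(0, 1)))
    stop("'period' must be coded 0 (first phase) / 1 (second phase)",
         call. = FALSE)
  for (nm in spec$binary)
    if (!all(use[[nm]] %in% c(0, 1)))
      stop("binary predictor '", nm, "' must be coded 0/1", call. = FALSE)

  # relabel hospitals to 1..H, keeping the original labels for reporting
  lev <- unique(use$cluster_id)
  use$cluster_id <- match(use$cluster_id, lev)
  if (length(lev) < 1L) stop("no clusters found", call. = FALSE)

  centering <- spec$centering
  if (is.null(centering)) {
    centering <- vapply(use[spec$continuous], mean, numeric(1))
  }
  for (nm in spec$continuous)
    use[[nm]] <- use[[nm]] - centering[[nm]]
  spec$centering <- centering

  structure(use,
            spec = spec,
            cluster_levels = lev,
            lp_offset = attr(raw, "lp_offset", exact = TRUE) %||% 0,
            class = c("cohort_table", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Centre the fitted linear predictor of a cohort
#'
#' Subtracts the mean of the `linear_predictor` column and records the
#' offset, so that models with a random coefficient on the linear predictor
#' remain numerically well-behaved while the subtracted constant stays
#' available for report traceability.
#'
#' @param table A `cohort_table` carrying a `linear_predictor` column
#'   (filled in by [run_model1()]).
#' @return The cohort with a mean-zero `linear_predictor` and attribute
#'   `lp_offset` set to the subtracted constant.
#' @export
center_linear_predictor <- function(table) {
  if (is.null(table[["linear_predictor"]]))
    stop("no 'linear_predictor' column; run the fixed-effects model first",
         call. = FALSE)
  offset <- mean(table$linear_predictor)
  table$linear_predictor <- table$linear_predictor - offset
  attr(table, "lp_offset") <- attr(table, "lp_offset", exact = TRUE) %||% 0
  attr(table, "lp_offset") <- attr(table, "lp_offset") + offset
  table
}

#' Read a cohort from delimited text
#'
#' Reads a CSV/TSV file with a header row and maps its columns onto the
#' roles the model suite expects, optionally via a JSON configuration file
#' with keys `outcome_col`, `cluster_col`, `period_col`, `continuous`
#' (name list) and `binary` (name list).
#'
#' @param path Path to the CSV or TSV file (delimiter inferred from the
#'   extension, `.tsv`/`.txt` meaning tab).
#' @param column_map Either `NULL` (columns already use the standard names of
#'   [effect_hf_spec()]), a path to a JSON mapping file, or an equivalent
#'   named list.
#' @return A prepared `cohort_table` (see [prepare_cohort()]).
#' @export
read_cohort <- function(path, column_map = NULL) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(column_map))
    return(prepare_cohort(raw, effect_hf_spec()))

  map <- if (is.character(column_map)) jsonlite::read_json(column_map,
                                                           simplifyVector = TRUE)
         else column_map
  for (key in c("outcome_col", "cluster_col", "period_col", "continuous", "binary"))
    if (is.null(map[[key]]))
      stop("column map is missing key '", key, "'", call. = FALSE)
  ren <- c(outcome = map$outcome_col, cluster_id = map$cluster_col,
           period = map$period_col)
  for (std in names(ren)) {
    src <- ren[[std]]
    if (!src %in% names(raw))
      stop("mapped column '", src, "' not found in ", path, call. = FALSE)
    names(raw)[names(raw) == src] <- std
  }
  prepare_cohort(raw, predictor_spec(map$continuous, map$binary))
}

#' Write a prepared cohort to CSV for audit
#'
#' @param table A `cohort_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  spec <- attr(x, "spec", exact = TRUE)
  cat(sprintf("Cohort: %d patients, %d hospitals, periods %d/%d, %d events\n",
              nrow(x), length(unique(x$cluster_id)),
              sum(x$period == 0), sum(x$period == 1), sum(x$outcome)))
  cat("  predictors:", paste(all_predictors(spec), collapse = ", "), "\n")
  if (!is.null(x[["linear_predictor"]]))
    cat(sprintf("  linear predictor present (offset %.6g)\n",
                attr(x, "lp_offset", exact = TRUE) %||% 0))
  invisible(x)
}
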