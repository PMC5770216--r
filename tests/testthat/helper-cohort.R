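# Shared fixtures: all cohorts are generated in code at test time.

# small clustered cohort, fast enough for repeated GLMM fits
small_config <- function(seed = 1L, H = 30L, size = 100L, ...) {
  generator_config(n_clusters = H, n_total = H * size, seed = seed, ...)
}

small_cohort <- function(seed = 1L, H = 30L, size = 100L, ...) {
  prepare_cohort(generate_cohort(small_config(seed, H, size, ...)))
}

# deterministic 3-predictor raw table for data-model tests (no RNG)
tiny_raw_table <- function(n = 40L) {
  data.frame(
    outcome = rep(c(0L, 1L), length.out = n),
    cluster_id = rep(c(101L, 205L, 307L, 410L), length.out = n),
    period = rep(c(0L, 0L, 1L, 1L), length.out = n),
    age = seq(60, 90, length.out = n),
    sbp = seq(100, 180, length.out = n),
    resp_rate = seq(12, 30, length.out = n),
    urea = seq(3, 20, length.out = n),
    low_sodium = rep(c(0L, 1L, 0L, 0L), length.out = n),
    low_hemoglobin = rep(c(0L, 0L, 1L, 0L), length.out = n),
    cancer = rep(c(1L, 0L, 0L, 0L), length.out = n),
    copd = rep(c(0L, 1L, 1L, 0L), length.out = n),
    cvd = rep(c(0L, 0L, 0L, 1L), length.out = n),
    cirrhosis = rep(c(0L, 0L, 1L, 1L), length.out = n),
    dementia = rep(c(1L, 1L, 0L, 0L), length.out = n)
  )
}

# cohort with a fitted linear predictor attached
cohort_with_lp <- function(seed = 1L, H = 30L, size = 100L, ...) {
  run_model1(small_cohort(seed, H, size, ...))$table
}
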