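#' Paired comparison of per-block values from two pipelines
#'
#' Two-sided paired t-test on the block-wise differences `b - a`.
#' Degenerate inputs are handled by convention: identical series report
#' `p = 1` (exact tie); a constant nonzero shift (zero variance of the
#' differences but nonzero mean) reports `p = 0` with a `degenerate` flag,
#' as the t statistic is unbounded.
#'
#' @param values_a,values_b numeric vectors of equal length >= 3, paired by
#'   block.
#' @return list `mean_diff`, `t`, `p`, `df`, `degenerate`.
#' @export
paired_comparison <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 3)
  d <- values_b - values_a
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(mean_diff = 0, t = 0, p = 1, df = length(d) - 1,
                  degenerate = TRUE))
    }
    return(list(mean_diff = mean(d), t = sign(mean(d)) * Inf, p = 0,
                df = length(d) - 1, degenerate = TRUE))
  }
  tt <- stats::t.test(d)
  list(mean_diff = mean(d), t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Summary statistics of MNP over blocks
#'
#' Mean and SD rounded to the nearest whole pulse, the smallest observed
#' MNP value covering at least 80% of blocks, and the maximum.
#'
#' @param table cohort table with an `mnp` column.
#' @param measure,window optional filters.
#' @return named numeric `c(mean, sd, q80, max)`.
#' @export
summarize_mnp <- function(table, measure = NULL, window = NULL) {
  if (!is.null(measure)) table <- table[table$measure == measure, , drop = FALSE]
  if (!is.null(window)) table <- table[table$window == window, , drop = FALSE]
  v <- table$mnp[!is.na(table$mnp)]
  if (!length(v)) stop("no MNP values to summarize")
  cand <- sort(unique(v))
  cov <- vapply(cand, function(q) mean(v <= q), numeric(1))
  q80 <- cand[which(cov >= 0.8)[1]]
  c(mean = round(mean(v)), sd = if (length(v) > 1) round(stats::sd(v)) else 0,
    q80 = q80, max = max(v))
}

#' Simulate a cohort MNP table with known covariate effects
#'
#' Generates a long-format table of MNP outcomes directly from a linear
#' marginal model with exchangeable within-subject correlation -
#' `mnp = intercept + age_slope * (age - age0) + noise`, where `noise` has
#' SD `sigma` and correlation `rho` between rows of the same subject.
#' Useful for calibration studies of the [fit_gee()] estimator without
#' simulating any EEG.
#'
#' @param n_subjects number of subjects.
#' @param rows_per_subject outcome rows contributed by each subject.
#' @param intercept expected MNP at `age0`.
#' @param age_slope change in MNP per year of age.
#' @param age0 reference age (years).
#' @param age_range uniform age range.
#' @param rho exchangeable correlation of the noise within subject.
#' @param sigma total noise SD (pulses).
#' @param seed integer seed.
#' @return data.frame `subject_id`, `age_years`, `mnp`, plus `measure` and
#'   `window` columns set to `"local"`/`"early"` for interface uniformity.
#' @export
simulate_mnp_table <- function(n_subjects = 18, rows_per_subject = 7,
                               intercept = 37, age_slope = -4.6, age0 = 7,
                               age_range = c(7, 13), rho = 0.3, sigma = 10,
                               seed = 1L) {
  stopifnot(rho >= 0, rho < 1, sigma >= 0)
  with_seed(seed, {
    age <- stats::runif(n_subjects, age_range[1], age_range[2])
    u <- stats::rnorm(n_subjects, 0, sigma * sqrt(rho))
    rows <- lapply(seq_len(n_subjects), function(s) {
      eps <- stats::rnorm(rows_per_subject, 0, sigma * sqrt(1 - rho))
      data.frame(
        subject_id = sprintf("S%02d", s), age_years = age[s],
        mnp = intercept + age_slope * (age[s] - age0) + u[s] + eps,
        measure = "local", window = "early", stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' The four standard multivariable clinical models
#'
#' Term sets of the multivariable MNP models: age adjusted for ASM use,
#' age adjusted for stimulation intensity, ASM use with intensity, and all
#' three clinical factors together.
#'
#' @return named list of character vectors of covariate names.
#' @export
clinical_models <- function() {
  list(model1 = c("age_years", "asm_use"),
       model2 = c("age_years", "suprathreshold"),
       model3 = c("asm_use", "suprathreshold"),
       model4 = c("age_years", "asm_use", "suprathreshold"))
}
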