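#' Configuration of a simulated study cohort
#'
#' Describes a cohort of children undergoing repeated 100-pulse TMS blocks
#' over up to two days, with covariate-dependent signal-to-noise: evoked
#' amplitude grows with age (`age_snr_slope`), with suprathreshold
#' stimulation (`supra_amp_factor`) and is modulated by antiseizure
#' medication use (`asm_effect`); a shared subject-level random effect
#' induces within-subject correlation of downstream stability outcomes.
#'
#' @param n_subjects number of subjects (>= 2). The default schedule (18
#'   subjects, 15 attending two days of 4 blocks and 3 attending a single
#'   day) emits 132 blocks.
#' @param age_range years, `c(min, max)`; ages are uniform over this range.
#' @param blocks_per_day blocks scheduled per day, one entry per day (up to
#'   2 days).
#' @param single_day_subjects how many subjects attend day 1 only.
#' @param age_snr_slope per-year multiplier on evoked amplitude: amplitude
#'   scale `1 + slope * (age - min(age_range))`.
#' @param supra_amp_factor amplitude multiplier applied when the block's
#'   stimulation is suprathreshold.
#' @param asm_effect amplitude multiplier for subjects on antiseizure
#'   medication (1 = no effect).
#' @param within_subject_corr target exchangeable correlation of block-level
#'   log amplitude scale within subject, in [0, 1).
#' @param block_log_sd total SD of the log-normal block amplitude
#'   perturbation (split between subject and block level by
#'   `within_subject_corr`).
#' @param base_cfg [synthetic_config()] template shared by all blocks.
#' @param seed integer cohort seed.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 18, age_range = c(7, 13),
                          blocks_per_day = c(4, 4), single_day_subjects = 3,
                          age_snr_slope = 0.15, supra_amp_factor = 1.3,
                          asm_effect = 1.0, within_subject_corr = 0.3,
                          block_log_sd = 0.2,
                          base_cfg = synthetic_config(), seed = 1L) {
  stopifnot(n_subjects >= 2, length(age_range) == 2, age_range[1] < age_range[2],
            length(blocks_per_day) %in% 1:2, all(blocks_per_day >= 1),
            single_day_subjects >= 0, single_day_subjects <= n_subjects)
  if (supra_amp_factor <= 0 || asm_effect <= 0) stop("multipliers must be > 0")
  if (within_subject_corr < 0 || within_subject_corr >= 1) {
    stop("within_subject_corr must be in [0, 1)")
  }
  stopifnot(inherits(base_cfg, "synthetic_config"))
  structure(list(
    n_subjects = as.integer(n_subjects), age_range = age_range,
    blocks_per_day = as.integer(blocks_per_day),
    single_day_subjects = as.integer(single_day_subjects),
    age_snr_slope = age_snr_slope, supra_amp_factor = supra_amp_factor,
    asm_effect = asm_effect, within_subject_corr = within_subject_corr,
    block_log_sd = block_log_sd, base_cfg = base_cfg, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Generate a simulated cohort of TMS-EEG blocks
#'
#' Draws subject covariates (age, per-hemisphere resting motor threshold,
#' antiseizure-medication use) and the block schedule, and prepares one
#' seeded [synthetic_config()] per block with the evoked amplitudes scaled
#' by the covariate effects. Block data are materialized lazily through
#' [cohort_block()] so that full-size cohorts (hundreds of 100-trial,
#' 64-channel blocks) never need to fit in memory at once.
#'
#' @param cfg a [cohort_config()].
#' @return A `tep_cohort` object: `$table` (one metadata row per block,
#'   including the ground-truth `amp_scale`) and `$block_cfgs` /
#'   `$block_meta` lists.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  ns <- cfg$n_subjects
  icc <- cfg$within_subject_corr
  sd_u <- cfg$block_log_sd * sqrt(icc)
  sd_e <- cfg$block_log_sd * sqrt(1 - icc)

  subj <- with_seed(derive_seed(cfg$seed, 11L), {
    age <- stats::runif(ns, cfg$age_range[1], cfg$age_range[2])
    asm <- stats::runif(ns) < 0.444
    # rMT falls with age and often exceeds maximum stimulator output in
    # children; recorded value is capped at 100% MSO.
    rmt_left <- 88 - 3 * (age - mean(cfg$age_range)) + stats::rnorm(ns, 0, 12)
    rmt_right <- rmt_left + stats::rnorm(ns, 0, 4)
    u <- stats::rnorm(ns, 0, sd_u)
    list(age = age, asm = asm,
         rmt = cbind(left = pmin(pmax(round(rmt_left), 40), 100),
                     right = pmin(pmax(round(rmt_right), 40), 100)),
         u = u)
  })

  two_day <- length(cfg$blocks_per_day) == 2
  rows <- list(); block_cfgs <- list(); block_meta <- list()
  k <- 0L
  for (s in seq_len(ns)) {
    days <- if (two_day && s > cfg$single_day_subjects) 1:2 else 1L
    start_left <- with_seed(derive_seed(cfg$seed, 20L + s), stats::runif(1) < 0.5)
    for (d in days) {
      nb <- cfg$blocks_per_day[d]
      for (b in seq_len(nb)) {
        k <- k + 1L
        hemi <- if (xor(b %% 2 == 1, !start_left)) "left" else "right"
        rmt <- subj$rmt[s, hemi]
        meta <- block_metadata(
          subject_id = sprintf("S%02d", s), age_years = subj$age[s],
          hemisphere = hemi, day = d, block_order = b,
          rmt_pct_mso = rmt, asm_use = subj$asm[s],
          n_pulses = cfg$base_cfg$n_trials, blocks_per_day = nb)
        e_b <- with_seed(derive_seed(cfg$seed, 1000L + k), stats::rnorm(1, 0, sd_e))
        amp_scale <- (1 + cfg$age_snr_slope * (subj$age[s] - cfg$age_range[1])) *
          (if (meta$suprathreshold) cfg$supra_amp_factor else 1) *
          (if (meta$asm_use) cfg$asm_effect else 1) *
          exp(subj$u[s] + e_b)
        bcfg <- cfg$base_cfg
        bcfg$peaks <- lapply(bcfg$peaks, function(pk) {
          pk$amplitude_uV <- pk$amplitude_uV * amp_scale
          pk
        })
        bcfg$seed <- derive_seed(cfg$seed, 5000L + k)
        rows[[k]] <- data.frame(
          block_id = sprintf("B%03d", k), subject_id = meta$subject_id,
          age_years = meta$age_years, hemisphere = meta$hemisphere,
          day = meta$day, block_order = meta$block_order,
          rmt_pct_mso = meta$rmt_pct_mso, suprathreshold = meta$suprathreshold,
          asm_use = meta$asm_use, n_pulses = meta$n_pulses,
          amp_scale = amp_scale, noise_sd = bcfg$noise_sd,
          stringsAsFactors = FALSE)
        block_cfgs[[k]] <- bcfg
        block_meta[[k]] <- meta
      }
    }
  }
  structure(list(table = do.call(rbind, rows), block_cfgs = block_cfgs,
                 block_meta = block_meta, config = cfg),
            class = "tep_cohort")
}

#' Materialize one block of a simulated cohort
#' @param cohort a `tep_cohort` from [generate_cohort()].
#' @param i block index (row of `cohort$table`).
#' @return list with elements `epochs` ([epoched_eeg()]) and `meta`.
#' @export
cohort_block <- function(cohort, i) {
  stopifnot(inherits(cohort, "tep_cohort"), i >= 1, i <= nrow(cohort$table))
  list(epochs = generate_block(cohort$block_cfgs[[i]], cohort$block_meta[[i]]),
       meta = cohort$block_meta[[i]])
}

#' @export
print.tep_cohort <- function(x, ...) {
  cat(sprintf("<tep_cohort> %d blocks, %d subjects\n",
              nrow(x$table), length(unique(x$table$subject_id))))
  invisible(x)
}
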