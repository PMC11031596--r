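#' Evoked-peak specification
#'
#' One Gaussian component of the evoked template: a peak of given latency,
#' signed amplitude (negative = N-peak), temporal width (FWHM) and a spatial
#' topography that decays with scalp distance from a center electrode.
#'
#' @param latency_ms peak latency, ms post-pulse.
#' @param amplitude_uV signed peak amplitude at the topography center, uV.
#' @param width_ms temporal full width at half maximum, ms (> 0).
#' @param topo_center montage channel label at the topography maximum.
#' @param topo_spread spatial Gaussian decay constant over schematic scalp
#'   distance (head radius = 1).
#' @return A `peak_spec` list.
#' @export
peak_spec <- function(latency_ms, amplitude_uV, width_ms,
                      topo_center = "C3", topo_spread = 0.35) {
  stopifnot(width_ms > 0, topo_spread > 0)
  channel_positions(topo_center)  # errors on unknown label
  structure(list(latency_ms = latency_ms, amplitude_uV = amplitude_uV,
                 width_ms = width_ms, topo_center = topo_center,
                 topo_spread = topo_spread),
            class = "peak_spec")
}

#' Default pediatric motor-cortex evoked template
#'
#' Four Gaussian peaks centered over the left motor hotspot: P30-like
#' (+3 uV), N45-like (-4 uV), a dominant lateralized N100-like (-12 uV) and a
#' P180-like (+6 uV). The N100 dominance mirrors pediatric TEP morphology;
#' the magnitudes themselves are free parameters of the generator.
#'
#' @param center montage label of the stimulated site (default left motor).
#' @param scale multiplier applied to every amplitude.
#' @return list of [peak_spec()] objects.
#' @export
default_peaks <- function(center = "C3", scale = 1) {
  list(
    peak_spec(30, 3 * scale, 18, center),
    peak_spec(45, -4 * scale, 22, center),
    peak_spec(100, -12 * scale, 48, center, topo_spread = 0.45),
    peak_spec(180, 6 * scale, 70, center, topo_spread = 0.5)
  )
}

#' Configuration of the synthetic TMS-EEG block generator
#'
#' Defaults emulate the recording conditions of a pediatric motor-cortex
#' TMS-EEG study: 100-pulse blocks, epochs spanning -1000..1500 ms around the
#' pulse, a 64-channel cap, 1/f background EEG, 60 Hz line noise, a large
#' pulse artifact within -2..12 ms, a muscle transient within 11..30 ms, and
#' occasional movement-contaminated trials. `fs_raw` defaults to 2 kHz (the
#' minimum supported acquisition rate) rather than hardware rates of 25 kHz,
#' keeping desk-scale simulation tractable; every operation is rate-agnostic.
#'
#' @param n_trials pulses per block.
#' @param fs_raw acquisition sampling rate, Hz (>= 2000).
#' @param epoch_span `c(start, end)` of the epoch, ms relative to the pulse.
#' @param peaks list of [peak_spec()]s; must lie within `epoch_span`.
#' @param noise_sd time-domain SD of the 1/f background per channel, uV.
#' @param noise_exponent spectral slope alpha of the 1/f^alpha background.
#' @param line_amp 60 Hz line-noise amplitude, uV.
#' @param pulse_artifact_amp residual pulse-artifact amplitude inside
#'   -2..12 ms, uV.
#' @param muscle_artifact_amp TMS-evoked muscle transient amplitude inside
#'   11..30 ms, uV.
#' @param p_movement_trial probability that a trial carries a large
#'   low-frequency movement excursion.
#' @param movement_amp amplitude of the movement excursion, uV.
#' @param trial_amp_jitter_sd SD of the multiplicative per-trial evoked
#'   amplitude jitter.
#' @param distal_noise_gain noise multiplier reached at the channel farthest
#'   from the stimulation site (linear in distance; 1 at the site). Values
#'   above 1 make the all-channel GMFA noisier than the local 5-channel
#'   average by construction.
#' @param channels montage labels used (subset of [std_montage()]).
#' @param seed integer seed; identical configs + seeds give bit-identical
#'   blocks.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_trials = 100, fs_raw = 2000,
                             epoch_span = c(-1000, 1500),
                             peaks = default_peaks(),
                             noise_sd = 6, noise_exponent = 1,
                             line_amp = 2, pulse_artifact_amp = 500,
                             muscle_artifact_amp = 30,
                             p_movement_trial = 0.04, movement_amp = 1000,
                             trial_amp_jitter_sd = 0.2,
                             distal_noise_gain = 1.5,
                             channels = std_montage()$label,
                             seed = 1L) {
  if (inherits(peaks, "peak_spec")) peaks <- list(peaks)
  stopifnot(n_trials >= 1, length(epoch_span) == 2, epoch_span[1] < epoch_span[2])
  if (fs_raw < 2000) stop("fs_raw must be at least 2000 Hz")
  lat <- vapply(peaks, `[[`, numeric(1), "latency_ms")
  if (any(lat <= epoch_span[1] | lat >= epoch_span[2])) {
    stop("configuration error: peak latency outside epoch_span")
  }
  for (a in c(noise_sd, line_amp, pulse_artifact_amp, muscle_artifact_amp,
              movement_amp, trial_amp_jitter_sd)) {
    if (a < 0) stop("amplitudes and jitter SD must be >= 0")
  }
  if (p_movement_trial < 0 || p_movement_trial > 1) {
    stop("p_movement_trial must be in [0, 1]")
  }
  if (distal_noise_gain <= 0) stop("distal_noise_gain must be > 0")
  channel_positions(channels)
  structure(list(
    n_trials = as.integer(n_trials), fs_raw = fs_raw, epoch_span = epoch_span,
    peaks = peaks, noise_sd = noise_sd, noise_exponent = noise_exponent,
    line_amp = line_amp, pulse_artifact_amp = pulse_artifact_amp,
    muscle_artifact_amp = muscle_artifact_amp,
    p_movement_trial = p_movement_trial, movement_amp = movement_amp,
    trial_amp_jitter_sd = trial_amp_jitter_sd,
    distal_noise_gain = distal_noise_gain,
    channels = as.character(channels), seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Per-block subject and covariate record
#'
#' @param subject_id subject identifier.
#' @param age_years age in years.
#' @param hemisphere stimulated hemisphere, `"left"` or `"right"`.
#' @param day stimulation day, 1 or 2.
#' @param block_order order of the block within the day (1-based).
#' @param rmt_pct_mso resting motor threshold as % of maximum stimulator
#'   output, capped at 100.
#' @param asm_use whether the subject takes daily antiseizure medication.
#' @param n_pulses pulses delivered in the block.
#' @param blocks_per_day number of blocks scheduled on `day` (validates
#'   `block_order`).
#' @return A `block_metadata` list. `suprathreshold` is derived: `TRUE` iff
#'   `rmt_pct_mso < 100` (stimulation at 120% rMT is only above threshold
#'   when rMT is below maximum stimulator output).
#' @export
block_metadata <- function(subject_id, age_years, hemisphere, day, block_order,
                           rmt_pct_mso, asm_use, n_pulses = 100,
                           blocks_per_day = 4) {
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  stopifnot(day %in% c(1L, 2L), block_order >= 1, block_order <= blocks_per_day,
            rmt_pct_mso > 0, rmt_pct_mso <= 100, n_pulses >= 1)
  structure(list(
    subject_id = as.character(subject_id), age_years = age_years,
    hemisphere = hemisphere, day = as.integer(day),
    block_order = as.integer(block_order), rmt_pct_mso = rmt_pct_mso,
    suprathreshold = rmt_pct_mso < 100, asm_use = isTRUE(asm_use),
    n_pulses = as.integer(n_pulses)
  ), class = "block_metadata")
}

# Noise-free evoked template: [channels x samples] matrix. The topography is
# mirrored to the right hemisphere when the block metadata says so.
evoked_template <- function(cfg, t_ms, hemisphere = "left") {
  C <- length(cfg$channels)
  E <- matrix(0, C, length(t_ms))
  for (pk in cfg$peaks) {
    center <- pk$topo_center
    if (identical(hemisphere, "right")) center <- mirror_channels(center)
    d <- channel_distances(cfg$channels, center)
    gain <- exp(-d^2 / (2 * pk$topo_spread^2))
    shape <- pk$amplitude_uV *
      exp(-4 * log(2) * ((t_ms - pk$latency_ms) / pk$width_ms)^2)
    E <- E + outer(gain, shape)
  }
  E
}

#' Generate one synthetic TMS-EEG block
#'
#' Builds `cfg$n_trials` epochs as evoked template x spatial topography x
#' per-trial amplitude jitter, plus additive band-limited 1/f background
#' noise (spatially independent, scaled up with distance from the stimulation
#' site by `distal_noise_gain`), 60 Hz line noise, a decaying pulse artifact
#' inside -2..12 ms, a damped high-frequency muscle transient inside
#' 11..30 ms, and - on randomly selected trials - a large slow movement
#' excursion. All components draw from seeds derived from `cfg$seed`, so
#' disabling one component (e.g. `noise_sd = 0`) leaves the others
#' bit-identical.
#'
#' @param cfg a [synthetic_config()].
#' @param meta a [block_metadata()]; the evoked topography follows
#'   `meta$hemisphere`.
#' @return An [epoched_eeg()] with attribute `"truth"`: the noise-free evoked
#'   template (`channels x samples`), per-trial jitter factors, the indices of
#'   movement trials, and the per-channel noise gains.
#' @export
generate_block <- function(cfg, meta) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(meta, "block_metadata"))
  fs <- cfg$fs_raw
  S <- round(diff(cfg$epoch_span) / 1000 * fs) + 1L
  t_ms <- cfg$epoch_span[1] + (seq_len(S) - 1) * 1000 / fs
  n <- cfg$n_trials
  C <- length(cfg$channels)

  site <- if (identical(meta$hemisphere, "right")) "C4" else "C3"
  d_site <- channel_distances(cfg$channels, site)
  noise_gain <- 1 + (cfg$distal_noise_gain - 1) * d_site / max(d_site)

  E <- evoked_template(cfg, t_ms, meta$hemisphere)

  # Per-component parameter draws, each under its own derived seed, so that
  # zeroing one component's amplitude leaves every other component's draws
  # (hence the data) bit-identical.
  jitter <- with_seed(derive_seed(cfg$seed, 1L), {
    if (cfg$trial_amp_jitter_sd > 0) {
      pmax(1 + stats::rnorm(n, 0, cfg$trial_amp_jitter_sd), 0.05)
    } else rep(1, n)
  })
  movement_trials <- with_seed(derive_seed(cfg$seed, 5L), {
    which(stats::runif(n) < cfg$p_movement_trial)
  })
  line <- if (cfg$line_amp > 0) {
    with_seed(derive_seed(cfg$seed, 3L), {
      list(ch_amp = stats::runif(C, 0.5, 1.5),
           phase = stats::runif(n, 0, 2 * pi))
    })
  }
  art <- if (cfg$pulse_artifact_amp > 0 || cfg$muscle_artifact_amp > 0) {
    with_seed(derive_seed(cfg$seed, 4L), {
      list(a_p = cfg$pulse_artifact_amp * stats::runif(n, 0.9, 1.1),
           a_m = cfg$muscle_artifact_amp * stats::runif(n, 0.5, 1.5))
    })
  }
  mov <- if (length(movement_trials) && cfg$movement_amp > 0) {
    with_seed(derive_seed(cfg$seed, 6L), {
      nm <- length(movement_trials)
      # keep the burst center inside the epoch, margins permitting
      lo <- t_ms[1] + 300; hi <- t_ms[S] - 300
      if (lo >= hi) { lo <- t_ms[1]; hi <- t_ms[S] }
      list(tc = stats::runif(nm, lo, hi),
           phase = stats::runif(nm, 0, 2 * pi),
           ch_scale = matrix(stats::runif(nm * C, 0.6, 1), nm, C))
    })
  }

  # Fixed temporal shapes shared by all trials.
  sin60 <- sin(2 * pi * 60 * t_ms / 1000); cos60 <- cos(2 * pi * 60 * t_ms / 1000)
  pulse_shape <- ifelse(t_ms >= -2 & t_ms < 12, exp(-(t_ms + 2) / 4), 0)
  pulse_gain <- 0.5 + 0.5 * exp(-d_site^2 / (2 * 0.45^2))
  mus_shape <- ifelse(t_ms >= 11 & t_ms <= 30,
                      exp(-(t_ms - 11) / 7) * sin(2 * pi * 90 * (t_ms - 11) / 1000),
                      0)
  mus_gain <- exp(-d_site^2 / (2 * 0.35^2))

  # Assemble each trial as a contiguous [channels x samples] slab.
  noise_scale <- cfg$noise_sd * noise_gain
  assemble <- function() {
    arr <- array(0, c(C, S, n))
    # batch the background-noise FFTs over groups of trials
    nz_chunk <- 8L
    nz_buf <- NULL
    for (i in seq_len(n)) {
      M <- jitter[i] * E
      if (cfg$noise_sd > 0) {
        j <- (i - 1L) %% nz_chunk
        if (j == 0L) {
          nt <- min(nz_chunk, n - i + 1L)
          nz_buf <- pink_noise(S, C * nt, fs, cfg$noise_exponent)
        }
        M <- M + t(nz_buf[, j * C + seq_len(C), drop = FALSE]) * noise_scale
      }
      if (!is.null(line)) {
        lv <- cos(line$phase[i]) * sin60 + sin(line$phase[i]) * cos60
        M <- M + cfg$line_amp * outer(line$ch_amp, lv)
      }
      if (!is.null(art)) {
        M <- M + art$a_p[i] * outer(pulse_gain, pulse_shape) +
          art$a_m[i] * outer(mus_gain, mus_shape)
      }
      j <- match(i, movement_trials)
      if (!is.na(j) && !is.null(mov)) {
        # Gaussian-windowed 3 Hz burst: low-frequency but inside the 1 Hz
        # high-pass band, as real movement transients are.
        burst <- exp(-((t_ms - mov$tc[j]) / 300)^2) *
          sin(2 * pi * 3 * (t_ms - mov$tc[j]) / 1000 + mov$phase[j])
        M <- M + cfg$movement_amp * outer(mov$ch_scale[j, ], burst)
      }
      arr[, , i] <- M
    }
    arr
  }
  arr <- if (cfg$noise_sd > 0) {
    with_seed(derive_seed(cfg$seed, 2L), assemble())
  } else {
    assemble()
  }
  data <- aperm(arr, c(3, 1, 2))

  ep <- epoched_eeg(data, fs, cfg$epoch_span[1], cfg$channels, meta = meta)
  attr(ep, "truth") <- list(evoked = E, jitter = jitter,
                            movement_trials = movement_trials,
                            noise_gain = noise_gain, site = site)
  ep
}
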