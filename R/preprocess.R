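#' Preprocessing configuration
#'
#' Parameters of the epoch cleaning chain. Defaults follow a
#' pulse-artifact-interpolation pipeline for TMS-EEG: interpolate -2..12 ms
#' around the pulse using autoregressive extrapolation fitted on 20 ms of
#' data on each side, downsample to 1 kHz, baseline-correct on -500..-10 ms,
#' high-pass above 1 Hz, detect bad channels by robust statistics, notch
#' 58-62 Hz, reject trials exceeding an absolute amplitude criterion,
#' low-pass below 200 Hz and re-reference to the common average.
#'
#' @param interp_window ms pair; samples with `t >= interp_window[1]` and
#'   `t < interp_window[2]` are replaced (half-open on the right: the sample
#'   at exactly 12 ms is real data).
#' @param ar_fit_span ms of data fitted on each side of the window.
#' @param ar_order autoregressive model order (clipped so the fit stays
#'   overdetermined at low sampling rates).
#' @param target_fs resampling target, Hz; must divide the raw rate.
#' @param baseline_window ms pair for mean subtraction.
#' @param hp_cutoff,lp_cutoff high/low-pass cutoffs, Hz.
#' @param bandstop Hz pair of the line-noise notch.
#' @param bad_channel_z robust z-score threshold of the channel detector.
#' @param bad_trial_abs_uV absolute amplitude threshold of trial rejection.
#' @param mode `"per_subset"` (each candidate pulse subset is preprocessed
#'   independently, mimicking a shorter experiment) or `"subset_only"`
#'   (candidates are sub-averages of the one fully-preprocessed block).
#' @param artifact_hook optional `function(ep) ep` occupying the pipeline
#'   slot where published artifact-attenuation algorithms (SOUND, ICA
#'   component classification) would run; default no-op.
#' @param filter_order Butterworth order of each one-pass filter (applied
#'   zero-phase, so the realized magnitude is its square).
#' @return A validated `preproc_config` list.
#' @export
preproc_config <- function(interp_window = c(-2, 12), ar_fit_span = 20,
                           ar_order = 30, target_fs = 1000,
                           baseline_window = c(-500, -10), hp_cutoff = 1,
                           bandstop = c(58, 62), lp_cutoff = 200,
                           bad_channel_z = 5, bad_trial_abs_uV = 300,
                           mode = c("per_subset", "subset_only"),
                           artifact_hook = NULL, filter_order = 4) {
  mode <- match.arg(mode)
  stopifnot(length(interp_window) == 2, interp_window[1] < interp_window[2],
            ar_fit_span > 0, ar_order >= 1, target_fs > 0,
            length(baseline_window) == 2, baseline_window[1] < baseline_window[2],
            length(bandstop) == 2, bandstop[1] < bandstop[2])
  if (hp_cutoff >= lp_cutoff) stop("hp_cutoff must be below lp_cutoff")
  if (bad_channel_z <= 0 || bad_trial_abs_uV <= 0) stop("thresholds must be > 0")
  if (!is.null(artifact_hook)) stopifnot(is.function(artifact_hook))
  structure(list(
    interp_window = interp_window, ar_fit_span = ar_fit_span,
    ar_order = as.integer(ar_order), target_fs = target_fs,
    baseline_window = baseline_window, hp_cutoff = hp_cutoff,
    bandstop = bandstop, lp_cutoff = lp_cutoff,
    bad_channel_z = bad_channel_z, bad_trial_abs_uV = bad_trial_abs_uV,
    mode = mode, artifact_hook = artifact_hook,
    filter_order = filter_order
  ), class = "preproc_config")
}

# Least-squares AR fit (with intercept) of one segment and m-step forward
# extrapolation. Rank-deficient designs (constants, ramps, pure sinusoids)
# are handled by pivoted QR with unused coefficients set to zero, which
# reproduces exact linear recurrences exactly.
ar_extrapolate <- function(seg, p, m) {
  n <- length(seg)
  # keep the regression comfortably overdetermined; near-square AR fits
  # extrapolate explosively on noisy segments
  p <- max(2L, min(p, floor(n / 3)))
  if (p >= n) p <- n - 1L
  emb <- stats::embed(seg, p + 1)
  X <- cbind(1, emb[, -1, drop = FALSE])
  y <- emb[, 1]
  fit <- stats::.lm.fit(X, y)
  beta <- numeric(p + 1)
  r <- fit$rank
  beta[fit$pivot[seq_len(r)]] <- fit$coefficients[seq_len(r)]
  buf <- seg[n - seq_len(p) + 1]  # most recent first
  phi <- beta[-1]
  out <- numeric(m)
  for (j in seq_len(m)) {
    v <- beta[1] + sum(phi * buf)
    out[j] <- v
    buf <- c(v, buf[seq_len(p - 1)])
  }
  out
}

#' Interpolate the residual TMS pulse artifact
#'
#' Per trial and channel, replaces the samples inside `cfg$interp_window`
#' with a linear cross-fade between a forward autoregressive extrapolation
#' (model fitted on `ar_fit_span` ms before the window) and a backward
#' extrapolation (fitted on `ar_fit_span` ms after it). If either
#' extrapolation is non-finite or implausibly large the trace falls back to
#' a linear bridge across the window, with a warning.
#'
#' @param ep an [epoched_eeg()] at the raw sampling rate.
#' @param cfg a [preproc_config()].
#' @return A new `epoched_eeg` with the window replaced.
#' @export
interpolate_pulse_artifact <- function(ep, cfg) {
  t_ms <- time_axis(ep)
  w <- cfg$interp_window
  win <- which(t_ms >= w[1] & t_ms < w[2])
  if (!length(win)) return(ep)
  span_n <- round(cfg$ar_fit_span / 1000 * ep$fs)
  pre <- seq(min(win) - span_n, min(win) - 1)
  post <- seq(max(win) + 1, max(win) + span_n)
  if (min(pre) < 1 || max(post) > length(t_ms)) {
    stop("epoch too short: need ", cfg$ar_fit_span,
         " ms of data on both sides of the interpolation window")
  }
  m <- length(win)
  fade <- if (m == 1) 0.5 else seq(0, 1, length.out = m)
  d <- ep$data
  n_fallback <- 0L
  for (i in seq_len(dim(d)[1])) {
    for (k in seq_len(dim(d)[2])) {
      x_pre <- d[i, k, pre]
      x_post <- d[i, k, post]
      fwd <- ar_extrapolate(x_pre, cfg$ar_order, m)
      bwd <- rev(ar_extrapolate(rev(x_post), cfg$ar_order, m))
      est <- (1 - fade) * fwd + fade * bwd
      lim <- 10 * (max(abs(c(x_pre, x_post))) + 1)
      if (!all(is.finite(est)) || any(abs(est) > lim)) {
        est <- x_pre[length(x_pre)] +
          (x_post[1] - x_pre[length(x_pre)]) * seq_len(m) / (m + 1)
        n_fallback <- n_fallback + 1L
      }
      d[i, k, win] <- est
    }
  }
  if (n_fallback > 0) {
    warning("pulse interpolation fell back to a linear bridge on ",
            n_fallback, " trial-channel trace(s)")
  }
  out <- ep
  out$data <- d
  out
}

#' Resample epochs to a lower rate
#'
#' Anti-aliased integer-factor decimation: a zero-phase (forward-backward)
#' order-8 Butterworth low-pass at 0.4 x the target rate followed by sample
#' picking. The raw rate must be an integer multiple of `target_fs`.
#'
#' @param ep an [epoched_eeg()].
#' @param target_fs target sampling rate, Hz.
#' @return resampled `epoched_eeg` (identity when `target_fs == ep$fs`).
#' @export
resample_epochs <- function(ep, target_fs) {
  if (target_fs > ep$fs) stop("target_fs must not exceed the current rate")
  if (target_fs == ep$fs) return(ep)
  k <- ep$fs / target_fs
  if (abs(k - round(k)) > 1e-9) {
    stop("resampling requires an integer decimation factor (fs = ", ep$fs,
         ", target = ", target_fs, ")")
  }
  k <- round(k)
  d <- dim(ep$data)
  mat <- flatten_ts(ep$data)
  mat <- sos_filtfilt(mat, ep$fs, "lowpass", 0.4 * target_fs, order = 8)
  keep <- seq(1, d[3], by = k)
  out <- ep
  out$data <- unflatten_ts(mat[keep, , drop = FALSE], d[1], d[2])
  out$fs <- target_fs
  out
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window from
#' every sample.
#'
#' @param ep an [epoched_eeg()].
#' @param window ms pair, closed interval; default `c(-500, -10)`.
#' @return baseline-corrected `epoched_eeg`.
#' @export
baseline_correct <- function(ep, window = c(-500, -10)) {
  t_ms <- time_axis(ep)
  idx <- which(t_ms >= window[1] & t_ms <= window[2])
  if (!length(idx)) stop("baseline window contains no samples")
  m <- rowMeans(ep$data[, , idx, drop = FALSE], dims = 2)
  out <- ep
  out$data <- ep$data - array(m, dim(ep$data))
  out
}

#' Zero-phase filter epochs
#'
#' Butterworth filtering applied forward and backward (so the realized
#' magnitude response is the square of the one-pass design and the phase is
#' zero), as cascaded second-order sections with odd-reflection padding and
#' steady-state initial conditions, so that post-stimulus response does not
#' smear into the pre-stimulus period through startup transients.
#'
#' @param ep an [epoched_eeg()].
#' @param kind `"highpass"`, `"lowpass"` or `"bandstop"`.
#' @param params cutoff Hz (scalar) or band edges (pair for bandstop).
#' @param order one-pass Butterworth order (default 4).
#' @return filtered `epoched_eeg`.
#' @export
filter_epochs <- function(ep, kind = c("highpass", "lowpass", "bandstop"),
                          params, order = 4) {
  kind <- match.arg(kind)
  nyq <- ep$fs / 2
  if (any(params <= 0) || any(params >= nyq)) {
    stop("filter cutoffs must lie strictly between 0 and the Nyquist rate")
  }
  if (kind == "bandstop" && (length(params) != 2 || params[1] >= params[2])) {
    stop("bandstop requires an increasing Hz pair")
  }
  d <- dim(ep$data)
  mat <- flatten_ts(ep$data)
  mat <- sos_filtfilt(mat, ep$fs, kind, params, order = order)
  out <- ep
  out$data <- unflatten_ts(mat, d[1], d[2])
  out
}

#' Detect bad channels by robust statistics
#'
#' Flags channels whose robust z-score of log noise power exceeds
#' `cfg$bad_channel_z`, channels whose `1 - median` correlation with the
#' other channels' average waveforms is a robust-z outlier, and flat
#' (near-zero-variance) channels. Both statistics are measured over the
#' pre-stimulus baseline window so that a strong, spatially decaying evoked
#' topography does not masquerade as channel noise (nor evoked-poor distal
#' channels as "uncorrelated"); only excess power is flagged. A simplified, reproducible substitute for data-driven
#' noise-estimation channel rejection. Does not mutate the data.
#'
#' @param ep an [epoched_eeg()] (>= 8 channels).
#' @param cfg a [preproc_config()].
#' @return character vector of flagged labels. Raises a data-quality error
#'   when more than 20% of channels are flagged.
#' @export
detect_bad_channels <- function(ep, cfg) {
  C <- n_channels(ep)
  if (C < 8) stop("bad-channel detection needs at least 8 channels")
  dat <- ep$data
  t_ms <- time_axis(ep)
  pre <- t_ms >= cfg$baseline_window[1] & t_ms <= cfg$baseline_window[2]
  if (!any(pre)) pre <- rep(TRUE, length(t_ms))
  pw <- rowMeans(colMeans(dat[, , pre, drop = FALSE]^2, dims = 1))
  if (max(pw) < 1e-18) {
    return(character())   # degenerate noiseless input: nothing to flag
  }
  # flat = dead channel: whole-epoch variation at machine scale (absolute,
  # or relative to the liveliest channel); legitimately tiny distal signal
  # is not flatness
  ch_sd <- sqrt(pmax(rowMeans(colMeans(dat^2, dims = 1)) -
                       rowMeans(colMeans(dat, dims = 1))^2, 0))
  flat <- ch_sd <= max(1e-12, 1e-9 * max(ch_sd))
  robust_z <- function(v, floor_scale) {
    med <- stats::median(v[is.finite(v)])
    sc <- max(stats::mad(v[is.finite(v)], center = med), floor_scale)
    (v - med) / sc
  }
  z_pow <- robust_z(log(pw + 1e-300), 0.05)
  # correlations likewise on the pre-stimulus segment: channels far from
  # the stimulation site legitimately carry little evoked signal and would
  # otherwise look "uncorrelated" whenever the SNR is high
  avg <- colMeans(dat[, , pre, drop = FALSE], dims = 1)   # [channels x samples]
  cmat <- suppressWarnings(stats::cor(t(avg)))
  med_cor <- vapply(seq_len(C), function(k) {
    v <- cmat[k, -k]
    v <- v[is.finite(v)]
    if (!length(v)) NA_real_ else stats::median(v)
  }, numeric(1))
  stat <- 1 - med_cor
  ok <- is.finite(stat)
  z_cor <- rep(0, C)
  z_cor[ok] <- robust_z(stat[ok], 0.02)
  z_cor[!ok & !flat] <- Inf                        # uncorrelatable, not flat
  # an uncorrelated channel is only a bad-contact signature when it carries
  # non-negligible energy; near-silent channels are harmless
  logp <- log(pw + 1e-300)
  cor_eligible <- logp > stats::median(logp) - log(4)
  bad <- flat | z_pow > cfg$bad_channel_z |
    (z_cor > cfg$bad_channel_z & cor_eligible)
  bad[is.na(bad)] <- TRUE
  if (sum(bad) > 0.2 * C) {
    stop("data-quality error: ", sum(bad), " of ", C,
         " channels flagged bad (> 20%); block unusable")
  }
  ep$channels[bad]
}

#' Flag trials with large artifacts
#'
#' Adds to `bad_trials` every trial whose peak absolute amplitude on any
#' good channel, outside the pulse interpolation window, exceeds
#' `cfg$bad_trial_abs_uV`. An automated, reproducible stand-in for visual
#' rejection of movement/muscle-contaminated trials. Data are unchanged;
#' averaging operations skip flagged trials.
#'
#' @param ep an [epoched_eeg()].
#' @param cfg a [preproc_config()].
#' @return `epoched_eeg` with updated `bad_trials`. Errors if every trial
#'   would be rejected.
#' @export
reject_bad_trials <- function(ep, cfg) {
  t_ms <- time_axis(ep)
  keep_t <- !(t_ms >= cfg$interp_window[1] & t_ms < cfg$interp_window[2])
  gi <- match(good_channels(ep), ep$channels)
  if (!length(gi)) stop("no good channels available for trial rejection")
  peak <- trial_peak_abs(ep$data, dim(ep$data), as.integer(gi), keep_t)
  bad <- which(peak > cfg$bad_trial_abs_uV)
  out <- ep
  out$bad_trials <- sort(union(ep$bad_trials, bad))
  if (length(out$bad_trials) >= n_trials(ep)) {
    stop("all trials rejected (threshold ", cfg$bad_trial_abs_uV, " uV)")
  }
  out
}

#' Re-reference to the common average
#'
#' Subtracts, at every trial and sample, the instantaneous mean over good
#' channels from every good channel; flagged channels are left untouched
#' and excluded from the average. After the operation the good-channel sum
#' is zero at every sample.
#'
#' @param ep an [epoched_eeg()] with >= 2 good channels.
#' @return re-referenced `epoched_eeg`.
#' @export
rereference_common_average <- function(ep) {
  gi <- match(good_channels(ep), ep$channels)
  if (length(gi) < 2) stop("common average needs at least 2 good channels")
  d <- dim(ep$data)
  sub <- ep$data[, gi, , drop = FALSE]
  gm <- colMeans(aperm(sub, c(2, 1, 3)), dims = 1)   # [trials x samples]
  out <- ep
  out$data[, gi, ] <- sub - aperm(array(gm, c(d[1], d[3], length(gi))), c(1, 3, 2))
  out
}

#' Run the full preprocessing chain on a block (or a pulse subset)
#'
#' Restricts the raw block to `pulse_subset`, then applies, in order:
#' pulse-artifact interpolation, resampling to `cfg$target_fs`, baseline
#' correction, high-pass, bad-channel detection, the optional
#' artifact-attenuation hook, the line-noise bandstop, bad-trial rejection,
#' low-pass, and common-average re-referencing. Each stage is pure; a log of
#' stage lines is attached as attribute `"stages"` and provenance (pulse
#' indices, mode) as attribute `"provenance"`.
#'
#' @param ep_raw raw-rate [epoched_eeg()].
#' @param cfg a [preproc_config()].
#' @param pulse_subset `"all"` or an integer vector of trial indices.
#' @return preprocessed `epoched_eeg`.
#' @export
preprocess_block <- function(ep_raw, cfg, pulse_subset = "all") {
  stopifnot(inherits(ep_raw, "epoched_eeg"), inherits(cfg, "preproc_config"))
  if (identical(pulse_subset, "all")) {
    pulse_subset <- seq_len(n_trials(ep_raw))
  }
  pulse_subset <- as.integer(pulse_subset)
  if (length(pulse_subset) == 0 || min(pulse_subset) < 1 ||
      max(pulse_subset) > n_trials(ep_raw)) {
    stop("pulse_subset must be a non-empty subset of trial indices")
  }
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  ep <- ep_raw
  ep$data <- ep_raw$data[pulse_subset, , , drop = FALSE]
  ep$bad_trials <- integer()
  note("subset: %d of %d pulses", length(pulse_subset), n_trials(ep_raw))

  ep <- withCallingHandlers(
    interpolate_pulse_artifact(ep, cfg),
    warning = function(w) {
      note("interpolate warning: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  note("interpolate: [%g, %g) ms, AR span %g ms, order %d",
       cfg$interp_window[1], cfg$interp_window[2], cfg$ar_fit_span, cfg$ar_order)
  ep <- resample_epochs(ep, cfg$target_fs)
  note("resample: %g Hz", cfg$target_fs)
  ep <- baseline_correct(ep, cfg$baseline_window)
  note("baseline: [%g, %g] ms", cfg$baseline_window[1], cfg$baseline_window[2])
  ep <- filter_epochs(ep, "highpass", cfg$hp_cutoff, cfg$filter_order)
  note("highpass: %g Hz", cfg$hp_cutoff)
  bad <- detect_bad_channels(ep, cfg)
  ep$bad_channels <- sort(union(ep$bad_channels, bad))
  note("bad channels: %s", if (length(bad)) paste(bad, collapse = ",") else "none")
  if (!is.null(cfg$artifact_hook)) {
    ep <- cfg$artifact_hook(ep)
    stopifnot(inherits(ep, "epoched_eeg"))
    note("artifact hook: applied")
  }
  ep <- filter_epochs(ep, "bandstop", cfg$bandstop, cfg$filter_order)
  note("bandstop: [%g, %g] Hz", cfg$bandstop[1], cfg$bandstop[2])
  ep <- reject_bad_trials(ep, cfg)
  note("bad trials: %d", length(ep$bad_trials))
  ep <- filter_epochs(ep, "lowpass", cfg$lp_cutoff, cfg$filter_order)
  note("lowpass: %g Hz", cfg$lp_cutoff)
  ep <- rereference_common_average(ep)
  note("rereference: common average over %d channels", length(good_channels(ep)))

  attr(ep, "stages") <- log
  attr(ep, "provenance") <- list(pulses = pulse_subset, mode = cfg$mode)
  ep
}
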