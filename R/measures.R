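#' Stability-analysis configuration
#'
#' Parameters of the stability analysis: the concordance threshold, the
#' pulse-inclusion grid, the early/late scoring windows and the two
#' hemisphere-specific 5-channel sets overlying the motor hotspots.
#'
#' @param ccc_threshold concordance correlation threshold defining
#'   stability (a candidate is stable when its CCC with the gold standard
#'   is strictly greater than this).
#' @param start_pulses first pulse count of the inclusion grid.
#' @param step_pulses grid increment.
#' @param early_window ms pair; scored half-open `[15, 80)`.
#' @param late_window ms pair; scored closed `[80, 350]`.
#' @param left_channels,right_channels 5-channel sets for local TEPs.
#' @return A validated `analysis_config` list.
#' @export
analysis_config <- function(ccc_threshold = 0.8, start_pulses = 10,
                            step_pulses = 5, early_window = c(15, 80),
                            late_window = c(80, 350),
                            left_channels = c("C3", "C1", "C5", "FC3", "CP3"),
                            right_channels = c("C4", "C2", "C6", "FC4", "CP4")) {
  stopifnot(ccc_threshold > -1, ccc_threshold < 1, start_pulses >= 1,
            step_pulses >= 1, length(early_window) == 2, length(late_window) == 2,
            early_window[1] < early_window[2], late_window[1] < late_window[2],
            early_window[2] == late_window[1],
            length(left_channels) == 5, length(right_channels) == 5)
  structure(list(ccc_threshold = ccc_threshold,
                 start_pulses = as.integer(start_pulses),
                 step_pulses = as.integer(step_pulses),
                 early_window = early_window, late_window = late_window,
                 left_channels = left_channels, right_channels = right_channels),
            class = "analysis_config")
}

#' Average epochs into a TEP
#'
#' Arithmetic mean over the requested trials, skipping flagged bad trials;
#' flagged bad channels are dropped from the result. Provenance (requested
#' and retained pulse indices) is recorded.
#'
#' @param ep a preprocessed [epoched_eeg()].
#' @param pulses `"all"` or integer trial indices (pulses delivered).
#' @return A `tep` object: `data` (`channels x samples`), `fs`, `t0`,
#'   `channels`, `n_pulses_used` (retained count), `provenance`.
#' @export
average_tep <- function(ep, pulses = "all") {
  if (identical(pulses, "all")) pulses <- seq_len(n_trials(ep))
  pulses <- as.integer(pulses)
  stopifnot(length(pulses) >= 1, min(pulses) >= 1, max(pulses) <= n_trials(ep))
  keep <- setdiff(pulses, ep$bad_trials)
  if (!length(keep)) stop("all requested pulses are flagged bad trials")
  gi <- match(good_channels(ep), ep$channels)
  avg <- colMeans(ep$data[keep, gi, , drop = FALSE], dims = 1)
  structure(list(
    data = avg, fs = ep$fs, t0 = ep$t0, channels = ep$channels[gi],
    n_pulses_used = length(keep),
    provenance = list(requested = pulses, retained = keep,
                      meta = ep$meta,
                      mode = attr(ep, "provenance")$mode)
  ), class = "tep")
}

#' @export
print.tep <- function(x, ...) {
  cat(sprintf("<tep> %d channels x %d samples @ %g Hz (%d pulses averaged)\n",
              nrow(x$data), ncol(x$data), x$fs, x$n_pulses_used))
  invisible(x)
}

new_waveform <- function(values, fs, t0, kind, channels_used = NULL,
                         hemisphere = NULL) {
  structure(list(values = as.numeric(values), fs = fs, t0 = t0, kind = kind,
                 channels_used = channels_used, hemisphere = hemisphere),
            class = "scalar_waveform")
}

#' Local TEP waveform over the stimulated site
#'
#' Pointwise mean of the hemisphere's 5-channel set overlying the motor
#' hotspot; channels flagged bad (hence absent from the TEP) are skipped and
#' the channels actually used are recorded.
#'
#' @param tep a [average_tep()] result.
#' @param hemisphere `"left"` or `"right"` (defaults to the block metadata).
#' @param cfg an [analysis_config()].
#' @return A `scalar_waveform` of kind `"local"`.
#' @export
local_tep <- function(tep, hemisphere = NULL, cfg = analysis_config()) {
  if (is.null(hemisphere)) hemisphere <- tep$provenance$meta$hemisphere
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  set <- if (hemisphere == "left") cfg$left_channels else cfg$right_channels
  use <- intersect(set, tep$channels)
  if (!length(use)) stop("no usable channel of the ", hemisphere, " local set")
  idx <- match(use, tep$channels)
  vals <- colMeans(tep$data[idx, , drop = FALSE])
  new_waveform(vals, tep$fs, tep$t0, "local", use, hemisphere)
}

#' Global mean field amplitude
#'
#' Spatial standard deviation of voltage over channels at each time point,
#' with the population (1/K) denominator: `sqrt(mean((V_k - mean_k V)^2))`.
#' Invariant under common-average re-referencing; nonnegative.
#'
#' @param tep a [average_tep()] result with >= 2 channels.
#' @return A `scalar_waveform` of kind `"gmfa"`.
#' @export
gmfa <- function(tep) {
  K <- nrow(tep$data)
  if (K < 2) stop("GMFA needs at least 2 channels")
  mu <- colMeans(tep$data)
  vals <- sqrt(colMeans(sweep(tep$data, 2, mu)^2))
  new_waveform(vals, tep$fs, tep$t0, "gmfa", tep$channels)
}

#' Slice a waveform to the early or late scoring window
#'
#' Early keeps samples with `15 <= t < 80` ms, late keeps `80 <= t <= 350`
#' ms (the shared 80 ms boundary belongs to the late window only, so the
#' two slices tile 15-350 ms without duplication).
#'
#' @param w a `scalar_waveform`.
#' @param window `"early"` or `"late"`.
#' @param cfg an [analysis_config()].
#' @return sliced `scalar_waveform`.
#' @export
window_slice <- function(w, window = c("early", "late"), cfg = analysis_config()) {
  window <- match.arg(window)
  t_ms <- w$t0 + (seq_along(w$values) - 1) * 1000 / w$fs
  idx <- if (window == "early") {
    which(t_ms >= cfg$early_window[1] & t_ms < cfg$early_window[2])
  } else {
    which(t_ms >= cfg$late_window[1] & t_ms <= cfg$late_window[2])
  }
  if (!length(idx) || min(t_ms) > cfg$early_window[1] ||
      max(t_ms) < (if (window == "early") cfg$early_window[2] else cfg$late_window[2])) {
    stop("scoring window lies outside the waveform span")
  }
  out <- w
  out$values <- w$values[idx]
  out$t0 <- t_ms[idx[1]]
  out
}

#' Export a waveform as CSV (time_ms, value_uV)
#' @param w a `scalar_waveform`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(w, path) {
  t_ms <- w$t0 + (seq_along(w$values) - 1) * 1000 / w$fs
  utils::write.csv(data.frame(time_ms = t_ms, value_uV = w$values),
                   path, row.names = FALSE)
  invisible(path)
}
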