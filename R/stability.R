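#' Lin's concordance correlation coefficient
#'
#' `ccc(x, y) = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`
#' with population (1/n) moments. Unlike the Pearson correlation it
#' penalizes both location and scale differences, so it measures agreement,
#' not just linear association. Degenerate case: if both series are
#' constant the coefficient is 1 when they are equal and 0 otherwise.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return a value in `[-1, 1]`.
#' @export
#' @examples
#' ccc(c(1, 2, 3), c(2, 3, 4))  # 4/7
ccc <- function(x, y) {
  if (length(x) != length(y)) stop("ccc: series must have equal length")
  if (length(x) < 2) stop("ccc: need at least 2 samples")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("ccc: non-finite input")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  den <- vx + vy + (mx - my)^2
  if (den == 0) return(1)                # identical constants
  if (vx == 0 && vy == 0) return(0)      # distinct constants
  sxy <- mean((x - mx) * (y - my))
  2 * sxy / den
}

new_stability_curve <- function(pulse_grid, ccc_values, measure, window, mode,
                                preprocess_mode, block_id = NA_character_,
                                meta = NULL) {
  stopifnot(length(pulse_grid) == length(ccc_values),
            all(diff(pulse_grid) > 0))
  structure(list(pulse_grid = as.integer(pulse_grid),
                 ccc_values = as.numeric(ccc_values),
                 measure = measure, window = window, mode = mode,
                 preprocess_mode = preprocess_mode,
                 block_id = block_id, meta = meta),
            class = "stability_curve")
}

#' @export
print.stability_curve <- function(x, ...) {
  cat(sprintf("<stability_curve> %s/%s (%s, %s): n = %d..%d, CCC %.3f..%.3f\n",
              x$measure, x$window, x$mode, x$preprocess_mode,
              min(x$pulse_grid), max(x$pulse_grid),
              min(x$ccc_values), max(x$ccc_values)))
  invisible(x)
}

# Pulse-count grid: start, start+step, ..., always terminated at the
# block's total pulse count even when the remainder is not a full step.
pulse_grid <- function(n_total, cfg) {
  if (n_total < cfg$start_pulses) {
    stop("block has fewer usable pulses (", n_total,
         ") than start_pulses (", cfg$start_pulses, ")")
  }
  g <- seq(cfg$start_pulses, n_total, by = cfg$step_pulses)
  if (g[length(g)] < n_total) g <- c(g, n_total)
  as.integer(g)
}

# Waveform of one measure/window from a preprocessed epoch average.
measure_waveform <- function(tep, measure, window, cfg, hemisphere = NULL) {
  w <- if (measure == "local") local_tep(tep, hemisphere, cfg) else gmfa(tep)
  window_slice(w, window, cfg)
}

#' Stability curves of a block under a pulse-inclusion schedule
#'
#' Computes the gold-standard waveforms from all pulses, then for each count
#' `n` on the inclusion grid builds a candidate TEP from the first `n`
#' pulses (`mode = "consecutive"`) or from a seeded, nested random
#' `n`-subset (`mode = "random"`; each larger subset contains the smaller
#' ones, mirroring the act of adding pulses). Candidates are preprocessed
#' independently (`pp$mode = "per_subset"`, faithful to an experiment that
#' collected fewer pulses) or sub-averaged from the one fully-preprocessed
#' block (`"subset_only"`, fast; final grid point then equals the gold
#' standard exactly). Each candidate is scored by [ccc()] against the gold
#' standard within each requested window.
#'
#' @param block_raw raw [epoched_eeg()] block.
#' @param cfg an [analysis_config()].
#' @param pp a [preproc_config()].
#' @param mode pulse-inclusion rule, `"consecutive"` or `"random"`.
#' @param seed seed of the random inclusion order (required relevance only
#'   for `mode = "random"`).
#' @param measures,windows subsets of `c("local", "gmfa")` and
#'   `c("early", "late")`.
#' @param hemisphere stimulated hemisphere for the local measure; defaults
#'   to block metadata.
#' @return `stability_curves()`: a named list of [stability curves][mnp]
#'   (`"<measure>_<window>"`). `stability_curve()`: the single requested
#'   curve.
#' @export
stability_curves <- function(block_raw, cfg = analysis_config(),
                             pp = preproc_config(),
                             mode = c("consecutive", "random"), seed = 1L,
                             measures = c("local", "gmfa"),
                             windows = c("early", "late"),
                             hemisphere = NULL) {
  mode <- match.arg(mode)
  measures <- match.arg(measures, c("local", "gmfa"), several.ok = TRUE)
  windows <- match.arg(windows, c("early", "late"), several.ok = TRUE)
  if (is.null(hemisphere) && !is.null(block_raw$meta)) {
    hemisphere <- block_raw$meta$hemisphere
  }
  N <- n_trials(block_raw)
  grid <- pulse_grid(N, cfg)

  order_idx <- if (mode == "random") {
    with_seed(seed, sample.int(N))
  } else seq_len(N)

  gold_ep <- preprocess_block(block_raw, pp, "all")
  gold_tep <- average_tep(gold_ep)
  combos <- expand.grid(measure = measures, window = windows,
                        stringsAsFactors = FALSE)
  gold_w <- lapply(seq_len(nrow(combos)), function(j) {
    measure_waveform(gold_tep, combos$measure[j], combos$window[j], cfg,
                     hemisphere)
  })

  vals <- matrix(NA_real_, length(grid), nrow(combos))
  for (gi in seq_along(grid)) {
    subset <- sort(order_idx[seq_len(grid[gi])])
    cand_tep <- if (pp$mode == "subset_only") {
      average_tep(gold_ep, subset)
    } else {
      average_tep(preprocess_block(block_raw, pp, subset))
    }
    for (j in seq_len(nrow(combos))) {
      cw <- measure_waveform(cand_tep, combos$measure[j], combos$window[j],
                             cfg, hemisphere)
      vals[gi, j] <- ccc(cw$values, gold_w[[j]]$values)
    }
  }

  block_id <- attr(block_raw, "block_id")
  if (is.null(block_id)) block_id <- NA_character_
  out <- lapply(seq_len(nrow(combos)), function(j) {
    new_stability_curve(grid, vals[, j], combos$measure[j], combos$window[j],
                        mode, pp$mode, block_id, block_raw$meta)
  })
  names(out) <- paste(combos$measure, combos$window, sep = "_")
  out
}

#' @rdname stability_curves
#' @param measure `"local"` or `"gmfa"`.
#' @param window `"early"` or `"late"`.
#' @export
stability_curve <- function(block_raw, measure = c("local", "gmfa"),
                            window = c("early", "late"),
                            cfg = analysis_config(), pp = preproc_config(),
                            mode = c("consecutive", "random"), seed = 1L,
                            hemisphere = NULL) {
  measure <- match.arg(measure)
  window <- match.arg(window)
  stability_curves(block_raw, cfg, pp, match.arg(mode), seed,
                   measures = measure, windows = window,
                   hemisphere = hemisphere)[[1]]
}

#' Persistence-checked minimum number of pulses
#'
#' The MNP is the smallest grid count `n*` whose candidate CCC - and the
#' CCC of every larger candidate on the grid - is strictly greater than the
#' threshold, guarding against "local minima" in which an early candidate
#' crosses the threshold but a later one falls back below it. When no such
#' count exists the result carries `attained = FALSE` rather than being
#' assigned the block size.
#'
#' @param curve a [stability_curves()] element.
#' @param cfg an [analysis_config()] (supplies the threshold).
#' @return An `mnp_result`: `mnp` (NA when not attained), `attained`,
#'   `threshold`, `persistence_verified`.
#' @export
mnp <- function(curve, cfg = analysis_config()) {
  stopifnot(inherits(curve, "stability_curve"), length(curve$pulse_grid) >= 1)
  thr <- cfg$ccc_threshold
  ok <- curve$ccc_values > thr
  suffix_ok <- rev(cumprod(rev(ok))) > 0
  idx <- which(suffix_ok)
  attained <- length(idx) > 0
  structure(list(
    mnp = if (attained) curve$pulse_grid[idx[1]] else NA_integer_,
    attained = attained, threshold = thr, persistence_verified = TRUE,
    measure = curve$measure, window = curve$window, mode = curve$mode,
    preprocess_mode = curve$preprocess_mode, block_id = curve$block_id
  ), class = "mnp_result")
}

#' @export
print.mnp_result <- function(x, ...) {
  cat(sprintf("<mnp_result> %s/%s: %s (threshold %g)\n", x$measure, x$window,
              if (x$attained) x$mnp else "not attained", x$threshold))
  invisible(x)
}

#' Concordance of two waveforms over the early and late windows
#'
#' Used to compare pipeline variants (e.g. with versus without bad-trial
#' rejection, or two different preprocessing chains) on the same block.
#'
#' @param w1,w2 `scalar_waveform`s with identical sampling, onset and kind.
#' @param cfg an [analysis_config()].
#' @return named numeric `c(ccc_early, ccc_late)`.
#' @export
compare_tep_pair <- function(w1, w2, cfg = analysis_config()) {
  if (!isTRUE(all.equal(w1$fs, w2$fs)) || !isTRUE(all.equal(w1$t0, w2$t0)) ||
      !identical(w1$kind, w2$kind) || length(w1$values) != length(w2$values)) {
    stop("waveforms have mismatched sampling, onset, length or kind")
  }
  c(ccc_early = ccc(window_slice(w1, "early", cfg)$values,
                    window_slice(w2, "early", cfg)$values),
    ccc_late = ccc(window_slice(w1, "late", cfg)$values,
                   window_slice(w2, "late", cfg)$values))
}

#' Long-format export of stability curves
#' @param curves list of stability curves (as from [stability_curves()]).
#' @return data.frame `block_id, subject, measure, window, mode, grid_n, ccc`.
#' @export
curves_to_df <- function(curves) {
  do.call(rbind, lapply(curves, function(cu) {
    data.frame(
      block_id = cu$block_id,
      subject = if (!is.null(cu$meta)) cu$meta$subject_id else NA_character_,
      measure = cu$measure, window = cu$window, mode = cu$mode,
      preprocess_mode = cu$preprocess_mode,
      grid_n = cu$pulse_grid, ccc = cu$ccc_values,
      stringsAsFactors = FALSE)
  }))
}
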