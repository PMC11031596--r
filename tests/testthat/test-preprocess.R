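pp0 <- preproc_config()

test_that("pulse interpolation is exact on AR-stationary inputs", {
  # constant trace
  ep <- make_ep(1, "C3", fill = function(i, k, t) rep(5, length(t)))
  out <- interpolate_pulse_artifact(ep, pp0)
  expect_equal(out$data, ep$data, tolerance = 1e-12)
  # pure linear ramp
  ep <- make_ep(1, "C3", fill = function(i, k, t) 0.3 * t + 2)
  out <- interpolate_pulse_artifact(ep, pp0)
  expect_lt(max(abs(out$data - ep$data)), 1e-6)
  # only the window may change on arbitrary input
  ep <- make_ep(1, "C3", fill = function(i, k, t) sin(t / 7) + t^2 / 1e4)
  out <- interpolate_pulse_artifact(ep, pp0)
  t_ms <- time_axis(ep)
  outside <- !(t_ms >= -2 & t_ms < 12)
  expect_identical(out$data[, , outside], ep$data[, , outside])
})

test_that("pulse interpolation removes a large spike riding on a sine", {
  f <- 20; amp <- 40
  clean <- function(t) amp * sin(2 * pi * f * t / 1000)
  ep <- make_ep(1, "C3", fill = function(i, k, t) {
    x <- clean(t)
    x[t >= 2 & t <= 10] <- x[t >= 2 & t <= 10] + 1000
    x
  })
  out <- interpolate_pulse_artifact(ep, pp0)
  t_ms <- time_axis(ep)
  win <- t_ms >= -2 & t_ms < 12
  expect_lt(max(abs(out$data[1, 1, win] - clean(t_ms[win]))), 0.1 * amp)
})

test_that("interpolation falls back to a linear bridge on degenerate traces", {
  # too-short epoch errors
  ep <- make_ep(1, "C3", t0 = -15, n_samples = 80)
  expect_error(interpolate_pulse_artifact(ep, pp0), "epoch too short")
})

test_that("resampling preserves band-limited content and rejects bad targets", {
  ep <- make_ep(1, "C3", fs = 25000, t0 = -200, n_samples = 10001,
                fill = function(i, k, t) sin(2 * pi * 2 * t / 1000))
  out <- resample_epochs(ep, 1000)
  expect_equal(out$fs, 1000)
  t_new <- time_axis(out)
  mid <- abs(t_new) <= 150
  expect_lt(max(abs(out$data[1, 1, mid] - sin(2 * pi * 2 * t_new[mid] / 1000))),
            0.001)
  # identity and constants
  expect_identical(resample_epochs(ep, 25000), ep)
  epc <- make_ep(1, "C3", fill = function(i, k, t) rep(3, length(t)))
  outc <- resample_epochs(epc, 1000)
  expect_equal(outc$data[1, 1, ], rep(3, dim(outc$data)[3]), tolerance = 1e-9)
  expect_error(resample_epochs(ep, 50000), "must not exceed")
  expect_error(resample_epochs(ep, 999), "integer decimation")
})

test_that("baseline correction zeroes the window mean and is idempotent", {
  ep <- make_ep(2, c("C3", "C4"), t0 = -600, n_samples = 1601,
                fill = function(i, k, t) sin(t / 50) + i + k)
  out <- baseline_correct(ep, c(-500, -10))
  t_ms <- time_axis(out)
  idx <- t_ms >= -500 & t_ms <= -10
  for (i in 1:2) for (k in 1:2) {
    expect_lt(abs(mean(out$data[i, k, idx])), 1e-12)
  }
  expect_equal(baseline_correct(out, c(-500, -10))$data, out$data,
               tolerance = 1e-12)
  epc <- make_ep(1, "C3", fill = function(i, k, t) rep(7, length(t)))
  expect_equal(max(abs(baseline_correct(epc, c(-50, -10))$data)), 0)
  expect_error(baseline_correct(ep, c(-2000, -1900)), "no samples")
})

test_that("zero-phase filters meet their attenuation contracts", {
  fs <- 1000
  mk <- function(f_hz) make_ep(1, "C3", fs = fs, t0 = -1000, n_samples = 2501,
                               fill = function(i, k, t) sin(2 * pi * f_hz * t / 1000))
  rms_mid <- function(ep) {
    t_ms <- time_axis(ep)
    sqrt(mean(ep$data[1, 1, abs(t_ms) <= 500]^2))
  }
  # 60 Hz through the line notch: >= 40 dB down
  ep60 <- mk(60)
  out <- filter_epochs(ep60, "bandstop", c(58, 62))
  expect_lt(rms_mid(out) / rms_mid(ep60), 10^(-40 / 20))
  # 0.1 Hz drift through the 1 Hz high-pass: mid-epoch RMS down >= 90%
  epd <- mk(0.1)
  outd <- filter_epochs(epd, "highpass", 1)
  expect_lt(rms_mid(outd) / rms_mid(epd), 0.1)
  # DC offset through the low-pass: unchanged
  epc <- make_ep(1, "C3", fill = function(i, k, t) rep(4, length(t)))
  outc <- filter_epochs(epc, "lowpass", 200)
  expect_equal(outc$data, epc$data, tolerance = 1e-9)
  # in-band content is preserved by the notch
  ep10 <- mk(10)
  out10 <- filter_epochs(ep10, "bandstop", c(58, 62))
  expect_gt(rms_mid(out10) / rms_mid(ep10), 0.99)
  expect_error(filter_epochs(ep10, "lowpass", 600), "Nyquist")
})

test_that("bad-channel detection flags outliers and only outliers", {
  chans <- small_channels()
  flagged <- lapply(1:10, function(s) {
    set.seed(s)
    ep <- make_ep(3, chans, fill = function(i, k, t) rnorm(length(t)))
    detect_bad_channels(ep, pp0)
  })
  expect_true(all(lengths(flagged) == 0))  # statistically identical channels
  # one channel with 100x the noise SD
  flagged2 <- vapply(1:10, function(s) {
    set.seed(100 + s)
    ep <- make_ep(3, chans, fill = function(i, k, t) {
      rnorm(length(t), sd = if (k == 4) 100 else 1)
    })
    b <- detect_bad_channels(ep, pp0)
    identical(b, chans[4])
  }, logical(1))
  expect_true(all(flagged2))
  # an all-zero channel is flagged as flat
  set.seed(7)
  ep <- make_ep(3, chans, fill = function(i, k, t) {
    if (k == 2) numeric(length(t)) else rnorm(length(t))
  })
  expect_true(chans[2] %in% detect_bad_channels(ep, pp0))
  # more than 20% bad is a data-quality error
  set.seed(8)
  epbad <- make_ep(3, chans, fill = function(i, k, t) {
    rnorm(length(t), sd = if (k <= 5) 1000 else 1)
  })
  expect_error(detect_bad_channels(epbad, pp0), "data-quality")
  expect_error(detect_bad_channels(make_ep(1, c("C3", "C4")), pp0), "8 channels")
})

test_that("trial rejection flags exactly the contaminated trials", {
  set.seed(3)
  base <- make_ep(30, small_channels(),
                  fill = function(i, k, t) rnorm(length(t), sd = 10))
  expect_length(reject_bad_trials(base, pp0)$bad_trials, 0)
  contaminated <- c(3, 10, 17, 24)
  ep <- base
  t_ms <- time_axis(ep)
  for (i in contaminated) {
    ep$data[i, 2, ] <- ep$data[i, 2, ] + 1000 * exp(-((t_ms - 50) / 200)^2)
  }
  expect_identical(reject_bad_trials(ep, pp0)$bad_trials, as.integer(contaminated))
  # infinite threshold rejects nothing
  cfg_inf <- preproc_config(bad_trial_abs_uV = Inf)
  expect_length(reject_bad_trials(ep, cfg_inf)$bad_trials, 0)
  # rejection ignores the pulse-artifact window
  ep2 <- base
  ep2$data[5, 1, t_ms >= -2 & t_ms < 12] <- 5000
  expect_length(reject_bad_trials(ep2, pp0)$bad_trials, 0)
  # all-rejected is an error
  allbad <- base
  allbad$data <- allbad$data + 1e4
  expect_error(reject_bad_trials(allbad, pp0), "all trials rejected")
})

test_that("common-average re-referencing zeroes the spatial mean", {
  ep <- make_ep(2, c("C3", "C4"), fill = function(i, k, t) {
    if (k == 1) sin(t / 9) + i else cos(t / 5)
  })
  out <- rereference_common_average(ep)
  expect_equal(out$data[, 1, ], (ep$data[, 1, ] - ep$data[, 2, ]) / 2)
  expect_equal(out$data[, 2, ], -out$data[, 1, ])
  # spatially uniform signal vanishes
  epu <- make_ep(1, c("C3", "C4", "Cz"), fill = function(i, k, t) sin(t / 11))
  expect_lt(max(abs(rereference_common_average(epu)$data)), 1e-12)
  # good-channel sums vanish for random input, bad channels untouched
  set.seed(2)
  epr <- make_ep(3, small_channels(), fill = function(i, k, t) rnorm(length(t)))
  epr$bad_channels <- "Fz"
  outr <- rereference_common_average(epr)
  gi <- match(setdiff(epr$channels, "Fz"), epr$channels)
  sums <- apply(outr$data[, gi, , drop = FALSE], c(1, 3), sum)
  expect_lt(max(abs(sums)), 1e-9)
  expect_identical(outr$data[, match("Fz", epr$channels), ],
                   epr$data[, match("Fz", epr$channels), ])
  ep1 <- make_ep(1, "C3")
  expect_error(rereference_common_average(ep1), "at least 2 good channels")
})

test_that("the full chain respects its invariants on a synthetic block", {
  cfg <- quick_cfg(n_trials = 20, seed = 12, p_movement_trial = 0)
  ep_raw <- generate_block(cfg, test_meta())
  out <- preprocess_block(ep_raw, pp0)
  expect_s3_class(out, "epoched_eeg")
  expect_equal(out$fs, 1000)
  t_ms <- time_axis(out)
  # baseline means stay near zero after the chain: no systematic offset,
  # and per-trace means bounded by the (long-range-correlated) baseline
  # noise scale itself
  base_idx <- t_ms >= -500 & t_ms <= -10
  base <- out$data[, , base_idx, drop = FALSE]
  m <- rowMeans(base, dims = 2)
  expect_lt(abs(mean(m)), 0.3)
  trace_sd <- sqrt(rowMeans(base^2, dims = 2) - m^2)
  expect_lt(max(abs(m)), 2 * stats::median(trace_sd))
  # good channels sum to zero at every trial and sample
  gi <- match(setdiff(out$channels, out$bad_channels), out$channels)
  sums <- apply(out$data[, gi, , drop = FALSE], c(1, 3), sum)
  expect_lt(max(abs(sums)), 1e-8)
  # the input epochs object is unmodified (stages are pure)
  expect_identical(ep_raw$data, generate_block(cfg, test_meta())$data)
  # stage log records the fixed order
  stages <- attr(out, "stages")
  expect_true(grepl("interpolate", stages[2]))
  expect_true(grepl("rereference", stages[length(stages)]))
})

test_that("preprocessing a subset equals preprocessing the sliced block", {
  cfg <- quick_cfg(n_trials = 20, seed = 21)
  ep_raw <- generate_block(cfg, test_meta())
  a <- preprocess_block(ep_raw, pp0, 1:10)
  sliced <- epoched_eeg(ep_raw$data[1:10, , , drop = FALSE], ep_raw$fs,
                        ep_raw$t0, ep_raw$channels, meta = ep_raw$meta)
  b <- preprocess_block(sliced, pp0, "all")
  expect_equal(a$data, b$data, tolerance = 1e-12)
  expect_identical(a$bad_trials, b$bad_trials)
  expect_error(preprocess_block(ep_raw, pp0, c(0, 5)), "pulse_subset")
})

test_that("a noiseless artifact-free block passes through with little distortion", {
  cfg <- quick_cfg(n_trials = 4, noise_sd = 0, seed = 2, line_amp = 0,
                   pulse_artifact_amp = 0, muscle_artifact_amp = 0,
                   p_movement_trial = 0, trial_amp_jitter_sd = 0)
  ep_raw <- generate_block(cfg, test_meta())
  out <- preprocess_block(ep_raw, pp0)
  tep <- average_tep(out)
  w <- window_slice(local_tep(tep), "late")
  # expected: the common-average-referenced template, sliced identically
  E <- attr(ep_raw, "truth")$evoked
  E_car <- E - matrix(colMeans(E), nrow(E), ncol(E), byrow = TRUE)
  t_raw <- time_axis(ep_raw)
  li <- match(analysis_config()$left_channels, ep_raw$channels)
  ref <- colMeans(E_car[li, , drop = FALSE])
  ref_w <- stats::approx(t_raw, ref, xout = w$t0 + (seq_along(w$values) - 1))$y
  rel <- sqrt(mean((w$values - ref_w)^2)) / sqrt(mean(ref_w^2))
  expect_lt(rel, 0.1)
})
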