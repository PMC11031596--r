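# Shared fixtures. Simulated blocks used in tests are scaled down from the
# full 64-channel, -1000..1500 ms world: a montage subset that keeps both
# hemispheres' local 5-channel sets (plus distal channels where the
# local-vs-global contrast matters) and epochs that still cover the
# baseline (-500..-10 ms) and analysis (15..350 ms) windows.

small_channels <- function() {
  c("F3", "Fz", "F4", "FC3", "FC4", "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP3", "CP4", "P3", "P4")
}

acc_channels <- function() {
  c(small_channels(), "F7", "F8", "P7", "P8", "O1", "O2", "Fp1", "Fp2")
}

quick_cfg <- function(n_trials = 30, noise_sd = 4, seed = 1L, ...) {
  synthetic_config(n_trials = n_trials, epoch_span = c(-600, 500),
                   channels = small_channels(), noise_sd = noise_sd,
                   seed = seed, ...)
}

# tiny config for tests that only need the generator's bookkeeping
micro_cfg <- function(n_trials = 10, seed = 1L, ...) {
  synthetic_config(n_trials = n_trials, epoch_span = c(-150, 250),
                   channels = c("C3", "Cz", "C4", "Fz"), seed = seed, ...)
}

test_meta <- function(hemisphere = "left", n_pulses = 100) {
  block_metadata("S01", age_years = 10, hemisphere = hemisphere, day = 1,
                 block_order = 1, rmt_pct_mso = 85, asm_use = FALSE,
                 n_pulses = n_pulses)
}

# bare epochs object from an array-filling function f(trial, channel) -> values
make_ep <- function(n_trials, channels, t0 = -100, fs = 2000, n_samples = 401,
                    fill = function(i, k, t) numeric(length(t))) {
  t_ms <- t0 + (seq_len(n_samples) - 1) * 1000 / fs
  data <- array(0, c(n_trials, length(channels), n_samples))
  for (i in seq_len(n_trials)) {
    for (k in seq_along(channels)) data[i, k, ] <- fill(i, k, t_ms)
  }
  epoched_eeg(data, fs, t0, channels)
}

# independent direct-formula CCC used as the oracle in several files
ccc_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x) / n; sy <- sum(y) / n
  num <- 2 * sum((x - sx) * (y - sy)) / n
  den <- sum((x - sx)^2) / n + sum((y - sy)^2) / n + (sx - sy)^2
  num / den
}
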