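acfg <- analysis_config()

test_that("ccc agrees with the direct-formula oracle and its special cases", {
  set.seed(1)
  for (r in 1:200) {
    n <- sample(3:50, 1)
    x <- rnorm(n, sd = runif(1, 0.1, 10))
    y <- rnorm(n, sd = runif(1, 0.1, 10)) + runif(1, -5, 5)
    expect_equal(ccc(x, y), ccc_oracle(x, y), tolerance = 1e-12)
  }
  x <- rnorm(20)
  expect_equal(ccc(x, x), 1)
  x0 <- x - mean(x)
  expect_equal(ccc(x0, -x0), -1)
  expect_equal(ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7, tolerance = 1e-15)
  # degenerate constants
  expect_equal(ccc(c(2, 2), c(2, 2)), 1)
  expect_equal(ccc(c(2, 2), c(3, 3)), 0)
  expect_error(ccc(1:3, 1:4), "equal length")
  expect_error(ccc(1, 1), "at least 2")
  expect_error(ccc(c(1, NA), c(1, 2)), "non-finite")
})

test_that("ccc penalizes scale, unlike Pearson correlation", {
  set.seed(2)
  x <- rnorm(100)
  x <- x - mean(x)
  a_grid <- c(1.25, 1.5, 2, 4, 8)
  vals <- vapply(a_grid, function(a) ccc(x, a * x), numeric(1))
  expect_true(all(vals < 1))
  expect_true(all(diff(vals) < 0))               # worse as a departs from 1
  expect_true(all(abs(vals - 2 * a_grid / (1 + a_grid^2)) < 1e-12))
  # and the same moving a below 1
  vals_lo <- vapply(1 / a_grid, function(a) ccc(x, a * x), numeric(1))
  expect_true(all(diff(vals_lo) < 0))
})

test_that("mnp equals a brute-force suffix scan, including the local-minimum trap", {
  suffix_oracle <- function(grid, v, thr = 0.8) {
    for (i in seq_along(grid)) {
      if (all(v[i:length(v)] > thr)) return(grid[i])
    }
    NA_integer_
  }
  mk <- function(v) tepstab:::new_stability_curve(
    seq(10, by = 5, length.out = length(v)), v, "local", "early",
    "consecutive", "subset_only")
  trap <- mk(c(0.7, 0.85, 0.75, 0.9, 0.95))
  expect_equal(mnp(trap, acfg)$mnp, 25L)
  allgood <- mk(c(0.9, 0.92, 0.95))
  expect_equal(mnp(allgood, acfg)$mnp, 10L)
  crossing <- mk(c(0.2, 0.4, 0.5, 0.6, 0.65, 0.7, 0.78, 0.82, 0.9, 0.95))
  expect_equal(mnp(crossing, acfg)$mnp, 45L)  # crosses between 40 and 45
  none <- mk(c(0.5, 0.9, 0.7))
  r <- mnp(none, acfg)
  expect_false(r$attained)
  expect_true(is.na(r$mnp))
  set.seed(3)
  for (i in 1:1000) {
    v <- runif(sample(1:19, 1), 0.4, 1.05)
    cu <- mk(v)
    expect_identical(mnp(cu, acfg)$mnp,
                     suffix_oracle(cu$pulse_grid, v))
  }
})

test_that("the pulse grid terminates at the usable pulse count", {
  expect_identical(tepstab:::pulse_grid(100, acfg),
                   as.integer(seq(10, 100, 5)))
  expect_identical(tepstab:::pulse_grid(97, acfg),
                   as.integer(c(seq(10, 95, 5), 97)))
  expect_error(tepstab:::pulse_grid(8, acfg), "fewer usable pulses")
})

test_that("a zero-noise block is stable at the first grid point in both modes", {
  cfg <- quick_cfg(n_trials = 20, noise_sd = 0, line_amp = 0,
                   pulse_artifact_amp = 0, muscle_artifact_amp = 0,
                   p_movement_trial = 0, trial_amp_jitter_sd = 0, seed = 1)
  ep <- generate_block(cfg, test_meta())
  for (mode in c("subset_only", "per_subset")) {
    cus <- stability_curves(ep, acfg, preproc_config(mode = mode))
    for (cu in cus) {
      expect_equal(cu$ccc_values, rep(1, length(cu$pulse_grid)),
                   tolerance = 1e-9)
      expect_equal(mnp(cu, acfg)$mnp, 10L)
    }
  }
})

test_that("subset_only candidates at n = N reproduce the gold standard exactly", {
  cfg <- quick_cfg(n_trials = 25, seed = 8)
  ep <- generate_block(cfg, test_meta())
  cus <- stability_curves(ep, acfg, preproc_config(mode = "subset_only"))
  for (cu in cus) {
    expect_identical(cu$ccc_values[length(cu$ccc_values)], 1)
    expect_equal(max(cu$pulse_grid), 25L)
    expect_true(all(cu$ccc_values >= -1 & cu$ccc_values <= 1))
  }
})

test_that("random inclusion is seeded, nested and shares the final point", {
  cfg <- quick_cfg(n_trials = 25, noise_sd = 6, seed = 10)
  ep <- generate_block(cfg, test_meta())
  pp <- preproc_config(mode = "subset_only")
  c1 <- stability_curve(ep, "local", "early", acfg, pp, mode = "random", seed = 1)
  c1b <- stability_curve(ep, "local", "early", acfg, pp, mode = "random", seed = 1)
  c2 <- stability_curve(ep, "local", "early", acfg, pp, mode = "random", seed = 2)
  expect_identical(c1$ccc_values, c1b$ccc_values)
  expect_false(identical(c1$ccc_values[1], c2$ccc_values[1]))
  expect_equal(c1$ccc_values[length(c1$ccc_values)], 1)
  expect_equal(c2$ccc_values[length(c2$ccc_values)], 1)
})

test_that("compare_tep_pair scores both windows and enforces compatibility", {
  cfg <- quick_cfg(n_trials = 100, noise_sd = 4, seed = 13)
  ep <- generate_block(cfg, test_meta())
  gold <- preprocess_block(ep, preproc_config(mode = "subset_only"))
  w_all <- local_tep(average_tep(gold), "left")
  expect_equal(unname(compare_tep_pair(w_all, w_all, acfg)), c(1, 1))
  # dropping ~4 of 100 trials barely moves the waveform
  keep <- setdiff(seq_len(100), c(17, 42, 61, 88))
  w_96 <- local_tep(average_tep(gold, keep), "left")
  both <- compare_tep_pair(w_all, w_96, acfg)
  expect_true(all(both > 0.8))
  # a large offset destroys concordance through the mean-shift penalty
  w_off <- w_all
  w_off$values <- w_all$values + 100
  expect_true(all(compare_tep_pair(w_all, w_off, acfg) < 0.1))
  w_bad <- w_all
  w_bad$fs <- 500
  expect_error(compare_tep_pair(w_all, w_bad, acfg), "mismatched")
})

test_that("stability errors on blocks with too few pulses", {
  cfg <- quick_cfg(n_trials = 5, seed = 3)
  ep <- generate_block(cfg, test_meta())
  expect_error(stability_curves(ep, acfg, preproc_config(mode = "subset_only")),
               "fewer usable pulses")
})
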