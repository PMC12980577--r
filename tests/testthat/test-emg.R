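test_that("rectification is the absolute deviation from the mean", {
  x <- c(-2, 0, 1, 5)
  expect_equal(emg_rectify(x), abs(x - 1))
  expect_equal(emg_rectify(x + 100), emg_rectify(x)) # offset-invariant
  expect_equal(emg_rectify(rep(3, 10)), rep(0, 10)) # constant is fine
})

test_that("the envelope filter has unit DC gain and a steep roll-off", {
  fs <- 1024
  n <- 4096
  t <- (seq_len(n) - 1) / fs
  dc <- emg_envelope(rep(1, n), fs, normalize = FALSE)
  expect_equal(mean(dc[1000:3000]), 1, tolerance = 1e-6)
  gain_at <- function(f) {
    y <- emg_envelope(sin(2 * pi * f * t), fs, normalize = FALSE)
    core <- seq(n / 4, 3 * n / 4)
    sqrt(2 * mean(y[core]^2)) # amplitude of the filtered sinusoid
  }
  # a 40 Hz component is attenuated at least 12 dB more than a 5 Hz one
  expect_gt(20 * log10(gain_at(5) / gain_at(40)), 12)
  # normalized output peaks at 1; all-zero input stays all-zero
  expect_equal(max(emg_envelope(abs(sin(2 * pi * 5 * t)), fs)), 1)
  expect_equal(emg_envelope(rep(0, n), fs), rep(0, n))
})

test_that("onset detection recovers a clean synthetic burst", {
  fs <- 1024
  times <- -0.5 + (seq_len(2 * fs) - 1) / fs
  set.seed(4)
  env <- abs(rnorm(length(times), 0, 0.01))
  burst <- times >= 0.3 & times <= 0.8
  env[burst] <- env[burst] + 1
  res <- emg_onset_duration(env, times)
  expect_true(res$kept)
  expect_equal(res$onset, 0.3, tolerance = 0.01)
  expect_equal(res$duration, 0.5, tolerance = 0.03)
  # a burst-free trial is dropped, not mis-marked
  res0 <- emg_onset_duration(abs(rnorm(length(times), 0, 0.01)), times)
  expect_false(res0$kept)
  expect_true(is.na(res0$onset))
  expect_error(
    emg_onset_duration(env, times + 5), # no pre-cue segment
    "baseline"
  )
})

test_that("session EMG metrics track the generator ground truth", {
  sc <- sim_scenario(n_trials = 120)
  ses <- generate_session(sc, group = "HC", seed = 21)
  met <- emg_session_metrics(ses$emg)
  expect_equal(nrow(met), 120)
  # pure-noise trials are (almost) all excluded; burst trials kept
  expect_lt(mean(met$kept[ses$emg$noise_trial]), 0.2)
  expect_gt(mean(met$kept[!ses$emg$noise_trial]), 0.9)
  err <- met$onset - ses$emg$onset_true
  expect_lt(mean(abs(err), na.rm = TRUE), 0.025)
  # scale invariance: thresholds are relative to the session scale
  ses2 <- ses$emg
  ses2$data <- ses2$data * 7.3
  met2 <- emg_session_metrics(ses2)
  expect_equal(met2$kept, met$kept)
  expect_equal(met2$onset, met$onset, tolerance = 1e-9)
})

test_that("joint exclusion drops the same trials from the EEG", {
  sc <- sim_scenario(n_trials = 30)
  ses <- generate_session(sc, group = "MS_F", seed = 13)
  met <- emg_session_metrics(ses$emg)
  joint <- apply_joint_exclusion(ses$eeg, met)
  expect_equal(dim(joint$epochs$data)[1], sum(met$kept))
  expect_equal(joint$epochs$kept_trial_ids, which(met$kept))
  expect_true(all(joint$emg_metrics$kept))
})
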