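# A 5-channel-free way to keep the full-grid decomposition cheap: use a
# montage-sized epochs object but only a couple of trials.

test_that("the decomposition grid is 179 bins by 10-ms steps", {
  ep <- make_epochs(signal = function(t) sin(2 * pi * 20 * t), n_trials = 1)
  tfr <- morlet_tfr(ep)
  expect_equal(length(tfr$freqs), 179)
  expect_equal(tfr$freqs[1], 1)
  expect_equal(tfr$freqs[179], 90)
  expect_equal(dim(tfr$power), c(1, 61, 179, length(tfr$times)))
  # 10-ms grid spanning the epoch [-0.5, 1.5), snapped to sample times
  expect_equal(length(tfr$times), 200)
  target <- seq(-0.5, by = 0.01, length.out = 200)
  expect_lt(max(abs(tfr$times - target)), 0.5 / ep$fs)
  # cycles grow linearly from 3 to 10
  expect_equal(tfr$n_cycles[1], 3)
  expect_equal(tfr$n_cycles[179], 10)
})

test_that("a pure tone peaks at its own frequency with a stable plateau", {
  ep <- make_epochs(signal = function(t) sin(2 * pi * 20 * t), n_trials = 1)
  tfr <- morlet_tfr(ep, fmin = 5, fmax = 45)
  mid <- which.min(abs(tfr$times - 0.5))
  spec <- tfr$power[1, 1, , mid]
  expect_equal(tfr$freqs[which.max(spec)], 20, tolerance = 0.5)
  # unit-amplitude real sinusoid: analytic power ~ 0.25 at the peak
  expect_equal(max(spec), 0.25, tolerance = 0.02)
  # mid-epoch plateau is stationary: CV below 5%
  sel <- tfr$times >= 0.2 & tfr$times <= 0.8
  plateau <- tfr$power[1, 1, which.max(spec), sel]
  expect_lt(sd(plateau) / mean(plateau), 0.05)
})

test_that("two tones on different channels stay separable", {
  ep <- make_epochs(
    n_trials = 1,
    per_channel = function(ch) {
      f <- if (ch == 1) 15 else 22
      function(t) sin(2 * pi * f * t)
    }
  )
  tfr <- morlet_tfr(ep, fmin = 10, fmax = 30)
  mid <- which.min(abs(tfr$times - 0.5))
  expect_equal(tfr$freqs[which.max(tfr$power[1, 1, , mid])], 15)
  expect_equal(tfr$freqs[which.max(tfr$power[1, 2, , mid])], 22)
})

test_that("zero input gives zero power and wide wavelets flag edges", {
  ep <- make_epochs(signal = 0, n_trials = 1)
  tfr <- morlet_tfr(ep, fmin = 1, fmax = 30)
  expect_equal(max(abs(tfr$power)), 0)
  # the 1 Hz wavelet (half-width ~1.4 s) cannot fit in a 2 s epoch
  expect_false(any(tfr$edge_ok[1, ]))
  # a mid-band wavelet has a clean centre
  j <- which(tfr$freqs == 20)
  mid <- which.min(abs(tfr$times - 0.5))
  expect_true(tfr$edge_ok[j, mid])
})

test_that("whole-trial normalization zeroes the epoch mean exactly", {
  sc <- small_scenario(n_trials = 3)
  ses <- generate_session(sc, group = "HC", seed = 3)
  tc <- beta_timecourse(ses$eeg, channels = c("FCz", "C3", "C4", "Cz"))
  mean_dev <- apply(tc$value, c(1, 2), mean)
  expect_lt(max(abs(mean_dev)), 1e-10)
  # band power is positive and mu matches its time-mean
  expect_true(all(tc$band_power > 0))
  expect_equal(tc$mu, apply(tc$band_power, c(1, 2), mean))
})

test_that("the memory-light band path matches the full decomposition", {
  ep <- make_epochs(
    n_trials = 2,
    per_channel = function(ch) {
      function(t) sin(2 * pi * 18 * t) + 0.3 * sin(2 * pi * 23 * t + ch)
    }
  )
  tfr <- morlet_tfr(ep, fmin = 13.5, fmax = 25)
  a <- baseline_normalize(tfr, band = c(13.5, 25))
  b <- beta_timecourse(ep, band = c(13.5, 25))
  expect_equal(b$value, a$value, tolerance = 1e-10)
  expect_equal(b$band_power, a$band_power, tolerance = 1e-10)
  expect_error(baseline_normalize(tfr, band = c(1, 30)), "outside")
})
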