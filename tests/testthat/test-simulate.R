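test_that("identical seeds give bit-identical sessions", {
  sc <- small_scenario(n_trials = 4)
  a <- generate_session(sc, group = "HC", seed = 31)
  b <- generate_session(sc, group = "HC", seed = 31)
  expect_identical(a$eeg$data, b$eeg$data)
  expect_identical(a$emg$data, b$emg$data)
  expect_identical(a$truth, b$truth)
  c <- generate_session(sc, group = "HC", seed = 32)
  expect_false(identical(a$eeg$data, c$eeg$data))
})

test_that("background noise follows 1/f within the fitted-slope tolerance", {
  set.seed(7)
  n <- 16384
  fs <- 256
  x <- betamod:::one_over_f_noise(n, 6, fs, slope = 1)
  f <- (seq_len(n / 2) - 1) * fs / n
  sel <- f >= 2 & f <= 45
  slopes <- apply(x, 2, function(v) {
    p <- Mod(stats::fft(v)[seq_len(n / 2)])^2
    -coef(lm(log(p[sel]) ~ log(f[sel])))[[2]]
  })
  expect_true(all(abs(slopes - 1) < 0.3))
  # unit variance per series
  expect_equal(apply(x, 2, var), rep(1, 6), tolerance = 0.25)
})

test_that("envelope design hits its targets against the forward response", {
  sc <- sim_scenario()
  times <- -0.5 + (0:511) / 256
  grid <- betamod:::tfr_time_grid(times, 0.01)
  des <- betamod:::design_envelope(
    erd_target = -0.8, ers_target = 2.5, erd_latency = 0.3,
    ers_latency = 0.85, times = times, fs = 256, band = c(13.5, 25),
    f0 = 20, bg_power = 1, snr = 30, grid_idx = grid$idx
  )
  tg <- times[grid$idx]
  expect_equal(min(des$profile[tg >= 0 & tg < 0.7]), -0.8, tolerance = 0.01)
  expect_equal(max(des$profile[tg >= 0.7 & tg <= 1.0]), 2.5,
    tolerance = 0.01
  )
  # the no-dynamics branch is flat: constant amplitude, no dip or bump
  flat <- betamod:::design_envelope(
    erd_target = -0.8, ers_target = 2.5, erd_latency = 0.3,
    ers_latency = 0.85, times = times, fs = 256, band = c(13.5, 25),
    f0 = 20, bg_power = 1, snr = 30, grid_idx = grid$idx, flat = TRUE
  )
  expect_equal(flat$d_erd, 0)
  expect_equal(flat$d_ers, 0)
  expect_lt(diff(range(flat$amplitude)), 1e-12)
})

test_that("session epochs have the configured geometry and truth table", {
  sc <- small_scenario(n_trials = 3)
  ses <- generate_session(sc, group = "MS_F", seed = 5)
  expect_s3_class(ses$eeg, "eeg_epochs")
  expect_equal(dim(ses$eeg$data), c(3, 61, 512))
  expect_equal(range(ses$eeg$times), c(-0.5, 1.5 - 1 / 256))
  expect_equal(nrow(ses$truth), 3)
  expect_equal(
    ses$truth$modulation_depth,
    ses$truth$ers - ses$truth$erd
  )
  gp <- sc$group_params[sc$group_params$group == "MS_F", ]
  expect_equal(
    ses$truth$modulation_depth[match(gp$region, ses$truth$region)],
    gp$depth_mean
  )
})

test_that("cohorts have the configured sizes and consistent labels", {
  sc <- sim_scenario()
  co <- generate_cohort(sc, seed = 7)$features
  expect_equal(nrow(co), 59)
  expect_equal(
    as.integer(table(co$group)[c("MS_F", "MS_NF", "HC")]),
    c(19, 22, 18)
  )
  # fatigue label coincides with the FSS cut-off among patients
  pats <- co[co$group != "HC", ]
  expect_identical(pats$group == "MS_F", pats$FSS >= 4)
  # healthy controls carry NA for patient-only scales
  hc <- co[co$group == "HC", ]
  expect_true(all(is.na(hc$EDSS)))
  expect_true(all(is.na(hc$disease_duration)))
  expect_true(all(!is.na(hc$FSS)))
  # determinism and per-subject seeds
  co2 <- generate_cohort(sc, seed = 7)$features
  expect_identical(co, co2)
  expect_equal(anyDuplicated(co$session_seed), 0)
})

test_that("feature CSV round-trips with missing values", {
  sc <- sim_scenario()
  co <- generate_cohort(sc, seed = 9)$features
  path <- tempfile(fileext = ".csv")
  write_features_csv(co, path)
  co2 <- read_features_csv(path)
  expect_equal(names(co2), names(co))
  expect_equal(co2$FSS, co$FSS, tolerance = 1e-12)
  expect_identical(is.na(co2$EDSS), is.na(co$EDSS))
  unlink(path)
})
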