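# Hand-built band-power arrays make the metric layer fully checkable:
# band power 1 everywhere except a dip/bump on chosen channels.

build_bp <- function(montage, times, n_trials = 1,
                     shape = function(ch, t) rep(1, length(t))) {
  bp <- array(1, dim = c(n_trials, nrow(montage), length(times)))
  for (tr in seq_len(n_trials)) {
    for (ch in seq_len(nrow(montage))) {
      bp[tr, ch, ] <- shape(ch, times)
    }
  }
  bp
}

test_that("ROI selection picks the configured peak electrode", {
  m <- standard_montage()
  times <- seq(-0.5, 1.49, by = 0.01)
  target <- match("C3", m$label)
  shape <- function(ch, t) {
    depth <- if (ch == target) 1 else 0.3
    1 - depth * exp(-(t - 0.3)^2 / 0.01) + depth * exp(-(t - 0.85)^2 / 0.01)
  }
  tc <- make_timecourse(build_bp(m, times, shape = shape), times, m)
  roi <- select_roi(tc, candidate_regions()$right_sensorimotor, m)
  expect_equal(roi$peak_electrode, "C3")
  expect_equal(length(roi$members), 7)
  expect_equal(roi$members[1], "C3")
  expect_setequal(roi$members[-1], brute_force_neighbours(m, "C3"))
  expect_error(select_roi(tc, c("C3", "QQ7"), m), "not in montage")
})

test_that("the 0.7 s sample belongs to the rebound window only", {
  m <- standard_montage()
  times <- seq(-0.5, 1.49, by = 0.01)
  # global maximum exactly at 0.7 s; the ERD window must not see it
  shape <- function(ch, t) {
    1 - 0.5 * exp(-(t - 0.3)^2 / 0.01) + 2 * exp(-(t - 0.7)^2 / 1e-4)
  }
  tc <- make_timecourse(build_bp(m, times, shape = shape), times, m)
  roi <- select_roi(tc, candidate_regions()$frontal, m)
  met <- extract_metrics(tc, roi)
  expect_equal(met$per_trial$ers_latency, 0.7)
  expect_lt(met$per_trial$erd_latency, 0.7)
  expect_equal(met$per_trial$erd_latency, 0.3, tolerance = 0.02)
})

test_that("per-trial metrics satisfy the depth identity and averaging", {
  m <- standard_montage()
  times <- seq(-0.5, 1.49, by = 0.01)
  set.seed(8)
  shape <- function(ch, t) {
    d <- runif(1, 0.3, 0.9)
    1 - d * exp(-(t - 0.3)^2 / 0.01) + d * exp(-(t - 0.85)^2 / 0.01)
  }
  bp <- build_bp(m, times, n_trials = 6, shape = shape)
  tc <- make_timecourse(bp, times, m)
  roi <- select_roi(tc, candidate_regions()$frontal, m)
  met <- extract_metrics(tc, roi)
  expect_equal(
    met$per_trial$modulation_depth,
    met$per_trial$peak_ers - met$per_trial$peak_erd
  )
  expect_equal(met$summary$modulation_depth,
    mean(met$per_trial$modulation_depth))
  expect_equal(met$summary$n_trials, 6)
  # epoch mean of the normalized course is ~0 per trial
  expect_lt(max(abs(met$per_trial$mean_beta)), 1e-10)
})

test_that("metrics are invariant to trial order", {
  m <- standard_montage()
  times <- seq(-0.5, 1.49, by = 0.01)
  set.seed(9)
  shape <- function(ch, t) {
    d <- runif(1, 0.3, 0.9)
    1 - d * exp(-(t - 0.3)^2 / 0.01) + d * exp(-(t - 0.85)^2 / 0.01)
  }
  bp <- build_bp(m, times, n_trials = 5, shape = shape)
  tc1 <- make_timecourse(bp, times, m)
  tc2 <- make_timecourse(bp[c(4, 2, 5, 1, 3), , , drop = FALSE], times, m)
  roi1 <- select_roi(tc1, candidate_regions()$frontal, m)
  roi2 <- select_roi(tc2, candidate_regions()$frontal, m)
  expect_identical(roi1$members, roi2$members)
  s1 <- extract_metrics(tc1, roi1)$summary
  s2 <- extract_metrics(tc2, roi2)$summary
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("the exclusion rule requires both a dip and a rebound", {
  ok <- tibble::tibble(peak_erd = c(-0.5, -0.1), peak_ers = c(0.5, 0.1))
  expect_true(keep_subject(ok))
  flat <- tibble::tibble(peak_erd = c(-0.1, -0.15), peak_ers = c(0.5, 0.4))
  expect_false(keep_subject(flat))
  no_rebound <- tibble::tibble(peak_erd = -0.6, peak_ers = 0.1)
  expect_false(keep_subject(no_rebound))
  # stricter thresholds can only exclude more
  expect_true(keep_subject(ok, erd_threshold = -0.2, ers_threshold = 0.2))
  expect_false(keep_subject(ok, erd_threshold = -0.6, ers_threshold = 0.6))
})

test_that("the session wrapper returns one summary row per region", {
  sc <- small_scenario(n_trials = 10)
  ses <- generate_session(sc, group = "MS_NF", seed = 17)
  res <- session_beta_metrics(ses$eeg)
  expect_s3_class(res, "session_beta_metrics")
  expect_equal(sort(res$summary$region), sort(names(candidate_regions())))
  expect_equal(nrow(res$per_trial), 3 * 10)
  expect_true(res$kept)
  for (roi in res$rois) expect_equal(length(roi$members), 7)
})
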