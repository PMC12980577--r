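test_that("test results tidy to plain tibbles", {
  d <- data.frame(y = c(1, 5, 2, 8, 3, 9), g = rep(c("a", "b"), each = 3))
  kw <- kw_test(d, "y", "g")
  td <- tidy(kw)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "kw_result"))
  expect_equal(td$statistic, kw$statistic)

  dd <- data.frame(
    y = c(1, 5, 2, 8, 3, 9, 4, 7, 6),
    g = rep(c("a", "b", "c"), each = 3)
  )
  expect_s3_class(tidy(dunn_posthoc(dd, "y", "g")), "tbl_df")
  sp <- spearman_boot(
    data.frame(x = rnorm(20), y = rnorm(20)), "x", "y",
    n_boot = 50
  )
  expect_s3_class(tidy(sp), "tbl_df")
})

test_that("model objects tidy and glance broom-style", {
  set.seed(15)
  d <- data.frame(y = rnorm(40), a = rnorm(40), b = rnorm(40))
  fit <- std_regression(d, "y", c("a", "b"))
  expect_equal(tidy(fit)$term, c("a", "b"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("r_squared", "f_statistic", "p_value") %in% names(gl)))

  n <- 40
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- rep(c(0, 1), each = n / 2)
  cv <- suppressWarnings(fatigue_nested_cv(x, y, n_repeats = 2, seed = 1))
  expect_s3_class(tidy(cv), "tbl_df")
  gl2 <- glance(cv)
  expect_true("roc_auc" %in% names(gl2))
  rf <- stability_refit(x, y, cv$selection, n_boot = 20, seed = 1)
  expect_true(all(c("mcfadden", "nagelkerke") %in% names(glance(rf))))
})

test_that("plot constructors return ggplot objects", {
  m <- standard_montage()
  expect_s3_class(plot_montage(m), "ggplot")
  roi <- list(
    peak_electrode = "C3",
    members = c("C3", montage_neighbours(m, "C3"))
  )
  expect_s3_class(plot_montage(m, roi = roi), "ggplot")

  sc <- small_scenario(n_trials = 2)
  ses <- generate_session(sc, group = "HC", seed = 2)
  tc <- beta_timecourse(ses$eeg, channels = c("FCz", "Cz"))
  expect_s3_class(ggplot2::autoplot(tc), "ggplot")

  d <- data.frame(
    modulation_depth = rnorm(30, 4),
    group = rep(c("MS_F", "MS_NF", "HC"), 10)
  )
  expect_s3_class(plot_group_depths(d), "ggplot")

  set.seed(16)
  n <- 40
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- rep(c(0, 1), each = n / 2)
  cv <- suppressWarnings(fatigue_nested_cv(x, y, n_repeats = 2, seed = 1))
  expect_s3_class(ggplot2::autoplot(cv), "ggplot")
  expect_s3_class(plot_selection_frequency(cv), "ggplot")
})
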