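test_that("the feature matrix has the pre-specified 23 predictors", {
  sc <- sim_scenario()
  co <- generate_cohort(sc, seed = 7)$features
  ff <- fatigue_features(co)
  expect_equal(ncol(ff$x), 23)
  expect_equal(length(ff$y), nrow(ff$x))
  expect_true(all(ff$y %in% c(0, 1)))
  expect_equal(sum(ff$y), sum(co$group == "MS_F"))
  expect_true(all(c(
    "sex_female", "depth_frontal", "depth_left", "depth_right",
    "FA_CST_left", "ICF", "MADRS"
  ) %in% colnames(ff$x)))
  expect_true(all(ff$x[, "sex_female"] %in% c(0, 1)))
  # an incomplete patient is dropped and counted
  co2 <- co
  co2$RMT[which(co2$group == "MS_F")[1]] <- NA
  ff2 <- fatigue_features(co2)
  expect_equal(ff2$n_dropped, 1)
  expect_equal(nrow(ff2$x), nrow(ff$x) - 1)
})

test_that("rank-based metrics agree with pROC and handle edge cases", {
  skip_if_not_installed("pROC")
  set.seed(14)
  y <- rep(c(0, 1), each = 30)
  prob <- plogis(y + rnorm(60))
  expect_equal(
    roc_auc(y, prob),
    as.numeric(pROC::auc(pROC::roc(y, prob, quiet = TRUE))),
    tolerance = 1e-12
  )
  # ties are handled by mid-ranks: constant scores give AUC 0.5
  expect_equal(roc_auc(y, rep(0.7, 60)), 0.5)
  expect_true(is.na(roc_auc(rep(1, 5), runif(5))))
  # perfect ranking
  expect_equal(roc_auc(y, y), 1)
  expect_equal(pr_auc(y, y + runif(60, 0, 0.1)), 1)
  # Brier score of a constant 0.5 prediction is exactly 0.25
  expect_identical(brier_score(y, rep(0.5, 60)), 0.25)
  cm <- classification_metrics(c(0, 0, 1, 1), c(0.1, 0.6, 0.4, 0.9))
  expect_equal(cm$accuracy, 0.5)
  expect_equal(cm$sensitivity, 0.5)
  expect_equal(cm$specificity, 0.5)
  expect_equal(cm$balanced_accuracy, 0.5)
})

test_that("stratified folds cover both classes and lambda_max kills betas", {
  y <- c(rep(0, 12), rep(1, 8))
  f <- betamod:::stratified_folds(y, 4, seed = 2)
  for (k in 1:4) expect_setequal(unique(y[f == k]), c(0, 1))
  expect_equal(as.integer(table(f)), rep(5L, 4))

  set.seed(3)
  x <- scale(matrix(rnorm(20 * 5), 20, 5))
  grid <- betamod:::lambda_grid(x, y, alpha = 1, n_lambda = 100)
  expect_equal(length(grid), 100)
  expect_equal(log10(grid[1] / grid[100]), 4, tolerance = 1e-9)
  fit <- glmnet::glmnet(x, y,
    family = "binomial", alpha = 1,
    lambda = grid[1], standardize = FALSE
  )
  expect_equal(max(abs(as.numeric(coef(fit))[-1])), 0)
})

test_that("nested CV is deterministic in the seed and leak-free", {
  set.seed(20)
  n <- 40
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("v", 1:6)))
  y <- rep(c(0, 1), each = n / 2)
  a <- suppressWarnings(fatigue_nested_cv(x, y, n_repeats = 3, seed = 9))
  b <- suppressWarnings(fatigue_nested_cv(x, y, n_repeats = 3, seed = 9))
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$selection, b$selection)
  c <- suppressWarnings(fatigue_nested_cv(x, y, n_repeats = 3, seed = 10))
  expect_false(identical(a$metrics, c$metrics))
  # outcome-independent predictors: held-out AUC stays near chance
  auc <- a$metrics$mean[a$metrics$metric == "roc_auc"]
  expect_gt(auc, 0.25)
  expect_lt(auc, 0.75)
  expect_true(all(a$selection$msf >= 0 & a$selection$msf <= 1))
})

test_that("a stronger planted effect never hurts the mean AUC much", {
  aucs <- sapply(c(0.8, 2.4), function(b) {
    set.seed(30)
    n <- 60
    x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
    y <- as.numeric(runif(n) < plogis(b * x[, 1] - b * x[, 2]))
    rep <- suppressWarnings(fatigue_nested_cv(x, y, n_repeats = 4, seed = 6))
    rep$metrics$mean[rep$metrics$metric == "roc_auc"]
  })
  expect_gt(aucs[2], aucs[1] - 0.02)
})

test_that("the ridge refit reports OR = exp(beta) and honest null output", {
  set.seed(40)
  n <- 80
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- as.numeric(runif(n) < plogis(-1.5 * x[, 1]))
  sel <- tibble::tibble(term = colnames(x), msf = c(0.9, 0.8, 0.2, 0.1))
  rf <- stability_refit(x, y, sel, n_boot = 300, seed = 4)
  expect_equal(rf$retained, c("v1", "v2"))
  expect_equal(rf$coefficients$odds_ratio, exp(rf$coefficients$beta),
    tolerance = 1e-12
  )
  # the planted protective predictor: OR below 1 with CI excluding 1
  v1 <- rf$coefficients[rf$coefficients$term == "v1", ]
  expect_lt(v1$odds_ratio, 1)
  expect_lt(v1$conf_high, 1)
  expect_true(all(rf$pseudo_r2 >= 0 & rf$pseudo_r2 <= 1))
  # empty retained set: intercept-only, all pseudo-R2 zero
  sel0 <- tibble::tibble(term = colnames(x), msf = rep(0.1, 4))
  rf0 <- stability_refit(x, y, sel0, n_boot = 10, seed = 4)
  expect_equal(unname(rf0$pseudo_r2), c(0, 0, 0))
  expect_equal(nrow(rf0$coefficients), 0)
})
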