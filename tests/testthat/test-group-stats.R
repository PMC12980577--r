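test_that("Kruskal-Wallis matches the textbook value and handles ties", {
  d <- data.frame(
    y = c(1, 2, 3, 4, 5, 6),
    g = rep(c("a", "b", "c"), each = 2)
  )
  kw <- kw_test(d, "y", "g")
  expect_equal(kw$statistic, 32 / 7, tolerance = 1e-3) # 4.571
  expect_equal(kw$df, 2)
  # all-identical observations: H = 0, p = 1
  d0 <- data.frame(y = rep(5, 9), g = rep(c("a", "b", "c"), 3))
  kw0 <- kw_test(d0, "y", "g")
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_value, 1)
  expect_error(kw_test(d[1:2, ], "y", "g"), "groups")
})

test_that("Dunn's z follows the tie-corrected formula and is antisymmetric", {
  d <- data.frame(
    y = c(1, 2, 2, 3, 5, 5, 5, 8, 9, 4, 6, 7),
    g = rep(c("a", "b", "c"), each = 4)
  )
  dn <- dunn_posthoc(d, "y", "g")
  expect_equal(nrow(dn), 3)
  # oracle: recompute one z by the printed formula
  r <- rank(d$y)
  rbar <- tapply(r, d$g, mean)
  n_all <- 12
  ties <- table(d$y)
  tt <- sum(ties^3 - ties) / (12 * (n_all - 1))
  se <- sqrt((n_all * (n_all + 1) / 12 - tt) * (1 / 4 + 1 / 4))
  z_ab <- (rbar[["a"]] - rbar[["b"]]) / se
  expect_equal(dn$z[dn$group1 == "a" & dn$group2 == "b"], z_ab)
  expect_equal(dn$p_adj, pmin(1, dn$p_value * 3))
  # antisymmetry: relabelling a <-> b flips the sign of their z
  d2 <- d
  d2$g <- c(b = "a", a = "b", c = "c")[d2$g]
  dn2 <- dunn_posthoc(d2, "y", "g")
  expect_equal(
    dn2$z[dn2$group1 == "a" & dn2$group2 == "b"],
    -z_ab
  )
})

test_that("Spearman correlation is exact for monotone data and seeded", {
  d <- data.frame(x = 1:20, y = (1:20)^3)
  up <- spearman_boot(d, "x", "y", n_boot = 200, seed = 3)
  expect_equal(up$rho, 1)
  d$y <- -d$y
  dn <- spearman_boot(d, "x", "y", n_boot = 200, seed = 3)
  expect_equal(dn$rho, -1)
  set.seed(10)
  d2 <- data.frame(x = rnorm(40), y = rnorm(40))
  a <- spearman_boot(d2, "x", "y", n_boot = 300, seed = 5)
  b <- spearman_boot(d2, "x", "y", n_boot = 300, seed = 5)
  expect_identical(a, b)
  expect_lt(a$conf_low, a$conf_high)
  expect_error(
    spearman_boot(data.frame(x = rep(1, 10), y = 1:10), "x", "y"),
    "zero variance"
  )
})

test_that("mediation effects decompose exactly and recover a known truth", {
  set.seed(6)
  n <- 2000
  x <- rnorm(n)
  m <- 0.5 * x + rnorm(n)
  y <- 0.5 * m + 0.3 * x + rnorm(n)
  d <- data.frame(x = x, m = m, y = y)
  res <- mediate_boot(d, "x", "m", "y", n_boot = 300, seed = 2)
  est <- setNames(res$estimate, res$effect)
  expect_equal(est[["total"]], est[["direct"]] + est[["indirect"]],
    tolerance = 1e-12
  )
  expect_lt(abs(est[["indirect"]] - 0.25), 0.06)
  expect_lt(abs(est[["direct"]] - 0.3), 0.08)
  # collinear mediator is rejected
  d$m2 <- d$x
  expect_error(mediate_boot(d, "x", "m2", "y"), "collinear")
})

test_that("standardized regression recovers planted coefficients", {
  set.seed(12)
  n <- 200
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  y <- -0.38 * z1 + 0.40 * z2 + rnorm(n, 0, sqrt(1 - 0.38^2 - 0.40^2))
  d <- data.frame(y = y, z1 = z1, z2 = z2)
  fit <- std_regression(d, "y", c("z1", "z2"))
  co <- setNames(fit$coefficients$beta, fit$coefficients$term)
  expect_lt(abs(co[["z1"]] - -0.38), 0.1)
  expect_lt(abs(co[["z2"]] - 0.40), 0.1)
  # an orthogonal noise predictor gets a near-zero beta
  d$junk <- rnorm(n)
  fit2 <- std_regression(d, "y", c("z1", "z2", "junk"))
  expect_lt(abs(fit2$coefficients$beta[fit2$coefficients$term == "junk"]),
    0.15)
  # a perfect fit is flagged rather than reported as a finite F
  d3 <- data.frame(y = 1:30, x = 1:30)
  fit3 <- suppressWarnings(std_regression(d3, "y", "x"))
  expect_true(fit3$perfect_fit)
  expect_identical(fit3$f_statistic, Inf)
  expect_identical(fit3$p_value, 0)
})

test_that("the sex table chi-square matches hand arithmetic and scales", {
  counts <- rbind(c(13, 6), c(11, 11), c(11, 7))
  res <- chi_square_sex(counts)
  # hand-computed Pearson statistic
  expd <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  x2 <- sum((counts - expd)^2 / expd)
  expect_equal(res$statistic, x2, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$n, 59)
  # doubling every count doubles the statistic
  res2 <- chi_square_sex(2 * counts)
  expect_equal(res2$statistic, 2 * x2, tolerance = 1e-12)
  expect_error(chi_square_sex(rbind(c(0, 0), c(1, 2))), "degenerate")
  expect_error(chi_square_sex(rbind(c(-1, 3), c(1, 2))), "nonnegative")
})

test_that("the primary-measure correction is Bonferroni over the family", {
  p <- c(peak_erd = 0.01, peak_ers = 0.4, modulation_depth = 0.02)
  adj <- adjust_primary_measures(p)
  expect_equal(adj$p_adj, pmin(1, p * 3), ignore_attr = TRUE)
  expect_equal(adj$measure, names(p))
})
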