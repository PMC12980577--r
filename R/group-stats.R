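#' Kruskal-Wallis test on a long data frame
#'
#' Rank-based H with tie correction, p from a chi-square with k - 1
#' degrees of freedom. All-identical observations give H = 0, p = 1.
#'
#' @param data Data frame.
#' @param value,group Column names (strings) of the numeric outcome and
#'   the grouping factor.
#' @return One-row tibble of class `kw_result`: `statistic`, `df`,
#'   `p_value`, `n`, `group_sizes` (list column).
#' @export
kw_test <- function(data, value, group) {
  x <- data[[value]]
  g <- factor(data[[group]])
  ok <- stats::complete.cases(x, g)
  x <- x[ok]
  g <- droplevels(g[ok])
  if (length(x) < 3 || nlevels(g) < 2) {
    stop("need >= 2 nonempty groups and N >= 3", call. = FALSE)
  }
  if (length(unique(x)) == 1) {
    res <- tibble::tibble(
      statistic = 0, df = nlevels(g) - 1, p_value = 1,
      n = length(x), group_sizes = list(table(g))
    )
    return(structure(res, class = c("kw_result", class(res))))
  }
  kt <- stats::kruskal.test(x, g)
  res <- tibble::tibble(
    statistic = unname(kt$statistic), df = unname(kt$parameter),
    p_value = kt$p.value, n = length(x), group_sizes = list(table(g))
  )
  structure(res, class = c("kw_result", class(res)))
}

#' Dunn's post-hoc pairwise comparisons with Bonferroni correction
#'
#' Textbook rank-sum z statistics with the tie correction term:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))`
#' where `T = sum(t^3 - t) / (12 (N - 1))` over tie groups. Two-tailed
#' p-values are reported raw and Bonferroni-corrected over all pairs
#' (`p_adj = min(1, p * n_pairs)`); z is antisymmetric under swapping the
#' pair order.
#'
#' @inheritParams kw_test
#' @return Tibble of class `dunn_result`, one row per unordered pair:
#'   `group1`, `group2`, `z`, `p_value`, `p_adj`.
#' @export
dunn_posthoc <- function(data, value, group) {
  x <- data[[value]]
  g <- factor(data[[group]])
  ok <- stats::complete.cases(x, g)
  x <- x[ok]
  g <- droplevels(g[ok])
  k <- nlevels(g)
  if (k < 2) stop("need >= 2 groups for pairwise comparisons", call. = FALSE)
  n_all <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n_all - 1))
  base_var <- n_all * (n_all + 1) / 12 - tie_term

  pairs <- utils::combn(levels(g), 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]
    j <- pr[2]
    se <- sqrt(base_var * (1 / n[[i]] + 1 / n[[j]]))
    z <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    tibble::tibble(
      group1 = i, group2 = j, z = z,
      p_value = 2 * stats::pnorm(-abs(z))
    )
  })
  out <- dplyr::bind_rows(res)
  out$p_adj <- pmin(1, out$p_value * nrow(out))
  structure(out, class = c("dunn_result", class(out)))
}

#' Spearman correlation with percentile bootstrap CI
#'
#' Rank correlation (tie-handled via mid-ranks) with a seeded
#' percentile bootstrap confidence interval over paired resamples, and
#' the asymptotic t-approximation p-value. Pairwise-complete deletion.
#'
#' @param data Data frame.
#' @param x,y Column names (strings).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return One-row tibble of class `spearman_result`: `rho`, `p_value`,
#'   `conf_low`, `conf_high`, `n`, `n_boot`.
#' @export
spearman_boot <- function(data, x, y, n_boot = 1000, conf = 0.95,
                          seed = 1) {
  xv <- data[[x]]
  yv <- data[[y]]
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]
  yv <- yv[ok]
  n <- length(xv)
  if (n < 5) stop("need n >= 5 complete pairs", call. = FALSE)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("zero variance in x or y: correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(xv, yv, method = "spearman")
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  bs <- with_seed(seed, {
    replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      suppressWarnings(stats::cor(xv[idx], yv[idx], method = "spearman"))
    })
  })
  qs <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
    na.rm = TRUE, names = FALSE
  )
  res <- tibble::tibble(
    rho = rho, p_value = p, conf_low = qs[1], conf_high = qs[2],
    n = n, n_boot = n_boot
  )
  structure(res, class = c("spearman_result", class(res)))
}

#' Simple mediation with bias-corrected percentile bootstrap CIs
#'
#' Product-of-coefficients mediation for `x -> m -> y` with linear
#' models: `a` from `m ~ x`, `b` and the direct effect from `y ~ x + m`,
#' the total effect from `y ~ x`; `IE = a * b` and `TE = DE + IE` holds
#' exactly for OLS. Confidence intervals are bias-corrected (BC, not
#' BCa) percentile bootstrap over `n_boot` case resamples; p-values are
#' two-sided bootstrap proportions. Listwise deletion; a binary group
#' dummy is a valid `x`.
#'
#' @param data Data frame.
#' @param x,m,y Column names (strings) of cause, mediator and outcome.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Tibble of class `mediation_result`, rows `indirect`, `direct`,
#'   `total`: `effect`, `estimate`, `conf_low`, `conf_high`, `p_value`.
#' @export
mediate_boot <- function(data, x, m, y, n_boot = 1000, conf = 0.95,
                         seed = 1) {
  xv <- data[[x]]
  mv <- data[[m]]
  yv <- data[[y]]
  ok <- stats::complete.cases(xv, mv, yv)
  xv <- as.numeric(xv[ok])
  mv <- mv[ok]
  yv <- yv[ok]
  n <- length(xv)
  if (n < 10) stop("need n >= 10 complete triples", call. = FALSE)
  r_xm <- abs(stats::cor(xv, mv))
  if (!is.finite(r_xm) || r_xm > 0.999) {
    stop("x and m are collinear: mediation effects not identified",
      call. = FALSE
    )
  }
  est <- mediation_effects(xv, mv, yv)
  bs <- with_seed(seed, {
    t(replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      mediation_effects(xv[idx], mv[idx], yv[idx])
    }))
  })
  alpha <- 1 - conf
  rows <- lapply(c("indirect", "direct", "total"), function(e) {
    th <- bs[, e]
    th <- th[is.finite(th)]
    z0 <- stats::qnorm(mean(th < est[[e]]) +
      0.5 * mean(th == est[[e]]))
    lo <- stats::pnorm(2 * z0 + stats::qnorm(alpha / 2))
    hi <- stats::pnorm(2 * z0 + stats::qnorm(1 - alpha / 2))
    ci <- stats::quantile(th, c(lo, hi), names = FALSE)
    p <- 2 * min(mean(th <= 0), mean(th >= 0))
    tibble::tibble(
      effect = e, estimate = est[[e]],
      conf_low = ci[1], conf_high = ci[2], p_value = min(1, p)
    )
  })
  res <- dplyr::bind_rows(rows)
  structure(res, class = c("mediation_result", class(res)))
}

# Closed-form OLS mediation effects (a*b, c', c) for one sample.
mediation_effects <- function(xv, mv, yv) {
  a <- stats::cov(xv, mv) / stats::var(xv)
  # y ~ x + m by the normal equations on centred data
  X <- cbind(xv - mean(xv), mv - mean(mv))
  cf <- solve(crossprod(X), crossprod(X, yv - mean(yv)))
  de <- cf[1]
  b <- cf[2]
  c(indirect = a * b, direct = de, total = a * b + de)
}

#' Multiple regression with standardized coefficients
#'
#' OLS of the outcome on z-scored predictors (outcome z-scored as well
#' for the standardized betas), reporting per-predictor standardized
#' beta and t, and the overall F test.
#'
#' @param data Data frame (complete cases used).
#' @param outcome Column name (string) of the dependent variable.
#' @param predictors Character vector of predictor column names.
#' @return List of class `std_regression`: `coefficients` tibble
#'   (`term`, `beta`, `t`, `p_value`), `f_statistic`, `df1`, `df2`,
#'   `p_value`, `r_squared`, `n`.
#' @export
std_regression <- function(data, outcome, predictors) {
  d <- data[, c(outcome, predictors)]
  d <- d[stats::complete.cases(d), ]
  n <- nrow(d)
  if (n <= length(predictors) + 1) {
    stop("too few complete cases for the requested model", call. = FALSE)
  }
  z <- function(v) (v - mean(v)) / stats::sd(v)
  dz <- as.data.frame(lapply(d, z))
  fml <- stats::reformulate(predictors, response = outcome)
  fit <- stats::lm(fml, data = dz)
  sm <- summary(fit)
  co <- sm$coefficients[predictors, , drop = FALSE]
  perfect <- sm$r.squared > 1 - 1e-12
  structure(
    list(
      coefficients = tibble::tibble(
        term = rownames(co), beta = co[, 1], t = co[, 3],
        p_value = co[, 4]
      ),
      f_statistic = if (perfect) Inf else unname(sm$fstatistic[1]),
      df1 = unname(sm$fstatistic[2]), df2 = unname(sm$fstatistic[3]),
      p_value = if (perfect) {
        0
      } else {
        stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
          lower.tail = FALSE
        )
      },
      r_squared = sm$r.squared, n = n, perfect_fit = perfect,
      fit = fit
    ),
    class = "std_regression"
  )
}

#' @exportS3Method base::print
print.std_regression <- function(x, ...) {
  cat(
    "<std_regression> n = ", x$n, ", R^2 = ", round(x$r_squared, 3),
    ", F(", x$df1, ", ", x$df2, ") = ", round(x$f_statistic, 2),
    ", p = ", signif(x$p_value, 3), "\n",
    sep = ""
  )
  print(x$coefficients)
  invisible(x)
}

#' Pearson chi-square test of a sex-by-group contingency table
#'
#' Pearson statistic without continuity correction on a groups-by-sex
#' count table. A zero row or column margin is an error (degenerate
#' table).
#'
#' @param counts Matrix or table of nonnegative integer counts
#'   (groups x categories).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n`.
#' @export
chi_square_sex <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero row or column margin: table is degenerate", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(
    statistic = unname(ct$statistic), df = unname(ct$parameter),
    p_value = ct$p.value, n = sum(counts)
  )
}

#' Bonferroni adjustment across the primary EEG measures
#'
#' Familywise correction over the three primary measures (peak ERD, peak
#' ERS, modulation depth): each p-value is multiplied by the family size
#' and capped at 1, equivalently tested at alpha / 3.
#'
#' @param p_values Named numeric vector of p-values, one per primary
#'   measure.
#' @return Tibble: `measure`, `p_value`, `p_adj`.
#' @export
adjust_primary_measures <- function(p_values) {
  k <- length(p_values)
  tibble::tibble(
    measure = names(p_values) %||% paste0("measure_", seq_len(k)),
    p_value = unname(p_values),
    p_adj = pmin(1, unname(p_values) * k)
  )
}
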