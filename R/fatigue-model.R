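#' Assemble the pre-specified fatigue-classification feature matrix
#'
#' Patients only (the two MS groups), complete cases only. The
#' pre-specified predictor set combines demographics and clinical scores
#' (age, sex, education, disease duration, EDSS, MADRS, nine-hole peg
#' test both hands), TMS excitability indices (RMT, MEP latency, SICI,
#' ICF, CSP), MRI volumetry (white/grey matter, thalamus, caudate,
#' lesion volume), beta modulation depth for the three ROIs, and
#' corticospinal-tract FA -- 23 predictors. Sex is coded female = 1.
#' The outcome is fatigued = 1 (fatigued MS group), non-fatigued = 0.
#'
#' @param features Cohort feature tibble (see [generate_cohort()]).
#' @param depth_cols Names of the three modulation-depth columns
#'   (default the generator's ground-truth columns; pass pipeline
#'   estimates for a full end-to-end run).
#' @return List: `x` (numeric matrix, rows = complete-case patients),
#'   `y` (0/1 outcome), `ids`, `n_dropped` (incomplete patients).
#' @export
fatigue_features <- function(features,
                             depth_cols = c(
                               "true_depth_frontal",
                               "true_depth_left",
                               "true_depth_right"
                             )) {
  stopifnot(all(depth_cols %in% names(features)))
  pats <- features[features$group %in% c("MS_F", "MS_NF"), ]
  pred_cols <- c(
    "age", "sex", "education", "disease_duration", "EDSS", "MADRS",
    "HPT9_right", "HPT9_left",
    "RMT", "MEP_latency", "SICI", "ICF", "CSP",
    "WM_volume", "GM_volume", "thalamus_volume", "caudate_volume",
    "lesion_volume",
    depth_cols,
    "FA_CST_left", "FA_CST_right"
  )
  stopifnot(all(pred_cols %in% names(pats)))
  d <- pats[, pred_cols]
  d$sex <- as.numeric(pats$sex == "F")
  ok <- stats::complete.cases(d)
  x <- as.matrix(d[ok, ])
  colnames(x) <- sub("^true_", "", pred_cols)
  colnames(x)[colnames(x) == "sex"] <- "sex_female"
  list(
    x = x,
    y = as.numeric(pats$group[ok] == "MS_F"),
    ids = pats$id[ok],
    n_dropped = sum(!ok)
  )
}

#' Nested cross-validated elastic-net fatigue classifier
#'
#' Stratified 5x5 nested cross-validation of a penalized logistic
#' regression, repeated `n_repeats` times with fresh splits. For each
#' outer training set, predictors are z-scored on that set only, an
#' inner stratified CV searches the (alpha, lambda) grid -- alpha from
#' `alphas`, about 100 log-spaced lambda values from the data-driven
#' `lambda_max` down four decades -- for the lowest inner-CV binomial
#' deviance, and the winning pair is refit on the full outer training
#' set. Held-out probabilities from all outer folds of a repeat are
#' pooled before computing metrics; aggregates are means with percentile
#' 95% intervals over repeats. The selection frequency of a predictor is
#' the fraction of outer fits giving it a nonzero coefficient.
#'
#' Everything downstream of the seed is deterministic. A degenerate
#' (single-class) inner fold triggers a logged re-split with a bumped
#' seed.
#'
#' @param x Numeric predictor matrix (rows = subjects).
#' @param y 0/1 outcome vector.
#' @param n_outer,n_inner Outer / inner fold counts (default 5).
#' @param alphas Elastic-net mixing grid (default 0.1 to 1 by 0.1;
#'   1 = LASSO).
#' @param n_lambda Size of the lambda grid (default 100).
#' @param n_repeats Repetitions of the whole nested CV (default 50).
#' @param threshold Probability cut-off for the thresholded metrics
#'   (default 0.5).
#' @param seed Integer seed.
#' @return List of class `fatigue_cv_report`: `metrics` (tibble: one row
#'   per metric with `mean`, `conf_low`, `conf_high` over repeats),
#'   `per_repeat` (tibble of all metric values), `selection` (tibble:
#'   `term`, `msf`), `predictions` (pooled outer-test probabilities of
#'   the first repeat), `settings`.
#' @export
fatigue_nested_cv <- function(x, y, n_outer = 5, n_inner = 5,
                              alphas = seq(0.1, 1, by = 0.1),
                              n_lambda = 100, n_repeats = 50,
                              threshold = 0.5, seed = 1) {
  stopifnot(is.matrix(x), length(y) == nrow(x), all(y %in% c(0, 1)))
  if (min(table(y)) < n_outer) {
    stop("too few cases in a class for ", n_outer, "-fold stratification",
      call. = FALSE
    )
  }
  p <- ncol(x)
  sel_count <- numeric(p)
  n_fits <- 0L
  per_repeat <- vector("list", n_repeats)
  first_preds <- NULL

  for (rep_i in seq_len(n_repeats)) {
    folds <- stratified_folds(y, n_outer, child_seed(seed, rep_i))
    prob <- rep(NA_real_, length(y))
    for (k in seq_len(n_outer)) {
      tr <- folds != k
      te <- !tr
      xs <- scale_train(x[tr, , drop = FALSE])
      xte <- scale_apply(x[te, , drop = FALSE], xs)
      fit <- elastic_net_inner(
        xs$x, y[tr], n_inner, alphas, n_lambda,
        seed = child_seed(seed, 10000L + rep_i * 100L + k)
      )
      prob[te] <- as.numeric(stats::predict(fit$fit,
        newx = xte,
        s = fit$lambda, type = "response"
      ))
      cf <- as.numeric(stats::coef(fit$fit, s = fit$lambda))[-1]
      sel_count <- sel_count + (cf != 0)
      n_fits <- n_fits + 1L
    }
    per_repeat[[rep_i]] <- classification_metrics(y, prob, threshold)
    if (rep_i == 1L) first_preds <- tibble::tibble(y = y, prob = prob)
  }

  pr <- dplyr::bind_rows(per_repeat, .id = "repeat_id")
  long <- tidyr::pivot_longer(pr, -"repeat_id",
    names_to = "metric", values_to = "value"
  )
  metrics <- dplyr::summarise(
    dplyr::group_by(long, .data$metric),
    mean = mean(.data$value),
    conf_low = stats::quantile(.data$value, 0.025, names = FALSE),
    conf_high = stats::quantile(.data$value, 0.975, names = FALSE),
    .groups = "drop"
  )
  structure(
    list(
      metrics = metrics,
      per_repeat = pr,
      selection = tibble::tibble(
        term = colnames(x),
        msf = sel_count / n_fits
      ),
      predictions = first_preds,
      settings = list(
        n_outer = n_outer, n_inner = n_inner, alphas = alphas,
        n_lambda = n_lambda, n_repeats = n_repeats,
        threshold = threshold, seed = seed
      )
    ),
    class = "fatigue_cv_report"
  )
}

#' @exportS3Method base::print
print.fatigue_cv_report <- function(x, ...) {
  cat(
    "<fatigue_cv_report> ", x$settings$n_repeats, " repeats of ",
    x$settings$n_outer, "x", x$settings$n_inner, " nested CV\n",
    sep = ""
  )
  print(x$metrics)
  invisible(x)
}

# Stratified fold assignment; every fold gets both classes when the
# class counts allow it.
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    f <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })
}

scale_train <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- 1
  list(x = sweep(sweep(x, 2, mu), 2, sd, "/"), mu = mu, sd = sd)
}

scale_apply <- function(x, xs) {
  sweep(sweep(x, 2, xs$mu), 2, xs$sd, "/")
}

# lambda grid: data-driven lambda_max for this alpha, down four decades.
lambda_grid <- function(x, y, alpha, n_lambda) {
  lmax <- max(abs(crossprod(x, y - mean(y)))) / (length(y) * alpha)
  10^seq(log10(lmax), log10(lmax) - 4, length.out = n_lambda)
}

# Inner-CV (alpha, lambda) search by binomial deviance; returns the
# winning glmnet fit on the full training set and the chosen pair.
elastic_net_inner <- function(x, y, n_inner, alphas, n_lambda, seed,
                              max_resplit = 20L) {
  folds <- stratified_folds(y, n_inner, seed)
  tries <- 0L
  while (any(vapply(
    seq_len(n_inner),
    function(k) length(unique(y[folds == k])) < 2, logical(1)
  )) && tries < max_resplit) {
    tries <- tries + 1L
    message("degenerate inner fold; re-splitting with bumped seed")
    folds <- stratified_folds(y, n_inner, seed + tries)
  }
  best <- list(dev = Inf)
  eps <- 1e-12
  for (alpha in alphas) {
    grid <- lambda_grid(x, y, alpha, n_lambda)
    dev_sum <- numeric(length(grid))
    n_obs <- 0L
    for (k in seq_len(n_inner)) {
      tr <- folds != k
      fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr],
        family = "binomial", alpha = alpha, lambda = grid,
        standardize = FALSE
      )
      pr <- stats::predict(fit,
        newx = x[!tr, , drop = FALSE],
        s = grid, type = "response"
      )
      pr <- pmin(pmax(pr, eps), 1 - eps)
      yk <- y[!tr]
      dev_sum <- dev_sum - 2 * colSums(yk * log(pr) +
        (1 - yk) * log(1 - pr))
      n_obs <- n_obs + length(yk)
    }
    dev <- dev_sum / n_obs
    j <- which.min(dev)
    if (dev[j] < best$dev) {
      best <- list(dev = dev[j], alpha = alpha, lambda = grid[j])
    }
  }
  fit <- glmnet::glmnet(x, y,
    family = "binomial", alpha = best$alpha,
    lambda = lambda_grid(x, y, best$alpha, n_lambda),
    standardize = FALSE
  )
  list(fit = fit, alpha = best$alpha, lambda = best$lambda)
}

#' Classification metrics on pooled held-out predictions
#'
#' Rank-based ROC-AUC (ties handled by mid-ranks), PR-AUC as average
#' precision, accuracy / sensitivity / specificity / balanced accuracy
#' at the probability `threshold`, and the Brier score.
#'
#' @param y 0/1 outcomes.
#' @param prob Predicted probabilities.
#' @param threshold Cut-off (default 0.5).
#' @return One-row tibble of the seven metrics.
#' @export
classification_metrics <- function(y, prob, threshold = 0.5) {
  tibble::tibble(
    roc_auc = roc_auc(y, prob),
    pr_auc = pr_auc(y, prob),
    accuracy = mean((prob >= threshold) == y),
    sensitivity = mean(prob[y == 1] >= threshold),
    specificity = mean(prob[y == 0] < threshold),
    balanced_accuracy = (mean(prob[y == 1] >= threshold) +
      mean(prob[y == 0] < threshold)) / 2,
    brier = brier_score(y, prob)
  )
}

#' @rdname classification_metrics
#' @export
roc_auc <- function(y, prob) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    return(NA_real_)
  }
  r <- rank(prob)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname classification_metrics
#' @export
pr_auc <- function(y, prob) {
  n1 <- sum(y == 1)
  if (n1 == 0) {
    return(NA_real_)
  }
  ord <- order(prob, decreasing = TRUE)
  ys <- y[ord]
  precision <- cumsum(ys) / seq_along(ys)
  sum(precision * ys) / n1
}

#' @rdname classification_metrics
#' @export
brier_score <- function(y, prob) {
  mean((prob - y)^2)
}

#' Descriptive ridge refit of the stability-selected predictors
#'
#' Refits a logistic model on all complete cases using only predictors
#' whose mean selection frequency exceeds `msf_threshold`, with a small
#' L2 ridge penalty against separation. If the fit is still separated
#' (fitted probabilities pinned to 0/1), the penalty is increased one
#' decade at a time with a logged message. Reports odds ratios with
#' percentile CIs from a stratified (per-class) bootstrap, and McFadden,
#' Cox-Snell and Nagelkerke pseudo-R-squared. An empty retained set
#' yields the intercept-only model with all pseudo-R-squared equal to 0.
#'
#' @param x Numeric predictor matrix (same columns the CV saw).
#' @param y 0/1 outcome.
#' @param selection Tibble with `term` and `msf` from
#'   [fatigue_nested_cv()].
#' @param msf_threshold Retention cut-off (default 0.5, i.e. selected in
#'   more than half of the outer fits).
#' @param ridge_lambda Initial ridge penalty (default 0.01).
#' @param n_boot Stratified bootstrap resamples for the OR CIs
#'   (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return List of class `fatigue_refit`: `coefficients` tibble (`term`,
#'   `beta`, `odds_ratio`, `conf_low`, `conf_high` on the OR scale),
#'   `pseudo_r2` (named vector), `retained`, `ridge_lambda`.
#' @export
stability_refit <- function(x, y, selection, msf_threshold = 0.5,
                            ridge_lambda = 0.01, n_boot = 1000,
                            conf = 0.95, seed = 1) {
  stopifnot(is.matrix(x), all(selection$term %in% colnames(x)))
  retained <- selection$term[selection$msf > msf_threshold]
  n <- length(y)
  p1 <- mean(y)
  ll0 <- sum(y * log(p1) + (1 - y) * log(1 - p1))

  if (length(retained) == 0) {
    return(structure(
      list(
        coefficients = tibble::tibble(
          term = character(), beta = numeric(), odds_ratio = numeric(),
          conf_low = numeric(), conf_high = numeric()
        ),
        pseudo_r2 = c(mcfadden = 0, cox_snell = 0, nagelkerke = 0),
        retained = character(), ridge_lambda = ridge_lambda
      ),
      class = "fatigue_refit"
    ))
  }

  xr <- scale_train(x[, retained, drop = FALSE])$x
  lam <- ridge_lambda
  for (i in 1:10) {
    fit <- ridge_logit(xr, y, lam)
    pr <- fit$prob
    if (all(pr > 1e-8 & pr < 1 - 1e-8)) break
    message(
      "separation at ridge penalty ", lam,
      "; increasing one decade"
    )
    lam <- lam * 10
  }
  beta <- fit$beta

  eps <- 1e-12
  prc <- pmin(pmax(pr, eps), 1 - eps)
  ll <- sum(y * log(prc) + (1 - y) * log(1 - prc))
  cs <- 1 - exp(2 * (ll0 - ll) / n)
  pseudo <- c(
    mcfadden = 1 - ll / ll0,
    cox_snell = cs,
    nagelkerke = cs / (1 - exp(2 * ll0 / n))
  )

  bs <- with_seed(seed, {
    idx1 <- which(y == 1)
    idx0 <- which(y == 0)
    t(replicate(n_boot, {
      idx <- c(
        sample(idx1, length(idx1), replace = TRUE),
        sample(idx0, length(idx0), replace = TRUE)
      )
      ridge_logit(xr[idx, , drop = FALSE], y[idx], lam)$beta
    }))
  })
  bs <- matrix(bs, ncol = length(retained))
  alpha <- 1 - conf
  ci <- apply(bs, 2, stats::quantile,
    probs = c(alpha / 2, 1 - alpha / 2), names = FALSE
  )
  structure(
    list(
      coefficients = tibble::tibble(
        term = retained, beta = beta,
        odds_ratio = exp(beta),
        conf_low = exp(ci[1, ]), conf_high = exp(ci[2, ])
      ),
      pseudo_r2 = pseudo, retained = retained, ridge_lambda = lam
    ),
    class = "fatigue_refit"
  )
}

#' @exportS3Method base::print
print.fatigue_refit <- function(x, ...) {
  cat(
    "<fatigue_refit> ", length(x$retained), " retained predictor(s), ",
    "ridge penalty ", x$ridge_lambda, "\n",
    sep = ""
  )
  if (nrow(x$coefficients)) print(x$coefficients)
  cat(
    "pseudo-R2: McFadden ", round(x$pseudo_r2[["mcfadden"]], 3),
    ", Cox-Snell ", round(x$pseudo_r2[["cox_snell"]], 3),
    ", Nagelkerke ", round(x$pseudo_r2[["nagelkerke"]], 3), "\n",
    sep = ""
  )
  invisible(x)
}

# Ridge-penalized logistic regression (coefficients penalized, intercept
# free), glmnet backend at a fixed penalty.
ridge_logit <- function(x, y, lambda) {
  fit <- glmnet::glmnet(x, y,
    family = "binomial", alpha = 0,
    lambda = lambda * c(100, 10, 1), standardize = FALSE
  )
  prob <- as.numeric(stats::predict(fit,
    newx = x, s = lambda,
    type = "response"
  ))
  list(beta = as.numeric(stats::coef(fit, s = lambda))[-1], prob = prob)
}
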