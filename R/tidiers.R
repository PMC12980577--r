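#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy methods for the statistics results
#'
#' All test results tidy to the plain tibble of their estimates; model
#' objects tidy to their per-term coefficient tables, and `glance()`
#' gives the one-row model summary.
#'
#' @param x A result object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name betamod-tidiers
NULL

#' @rdname betamod-tidiers
#' @export
tidy.kw_result <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' @rdname betamod-tidiers
#' @export
tidy.dunn_result <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' @rdname betamod-tidiers
#' @export
tidy.spearman_result <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' @rdname betamod-tidiers
#' @export
tidy.mediation_result <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

unclass_result <- function(x) {
  class(x) <- setdiff(
    class(x),
    c(
      "kw_result", "dunn_result", "spearman_result",
      "mediation_result"
    )
  )
  x
}

#' @rdname betamod-tidiers
#' @export
tidy.std_regression <- function(x, ...) {
  x$coefficients
}

#' @rdname betamod-tidiers
#' @export
glance.std_regression <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared, f_statistic = x$f_statistic,
    df1 = x$df1, df2 = x$df2, p_value = x$p_value, n = x$n
  )
}

#' @rdname betamod-tidiers
#' @export
tidy.fatigue_cv_report <- function(x, ...) {
  x$metrics
}

#' @rdname betamod-tidiers
#' @export
glance.fatigue_cv_report <- function(x, ...) {
  m <- x$metrics
  wide <- stats::setNames(as.list(m$mean), m$metric)
  tibble::as_tibble(c(wide, list(
    n_repeats = x$settings$n_repeats,
    n_outer = x$settings$n_outer,
    n_inner = x$settings$n_inner
  )))
}

#' @rdname betamod-tidiers
#' @export
tidy.fatigue_refit <- function(x, ...) {
  x$coefficients
}

#' @rdname betamod-tidiers
#' @export
glance.fatigue_refit <- function(x, ...) {
  tibble::tibble(
    mcfadden = x$pseudo_r2[["mcfadden"]],
    cox_snell = x$pseudo_r2[["cox_snell"]],
    nagelkerke = x$pseudo_r2[["nagelkerke"]],
    n_retained = length(x$retained),
    ridge_lambda = x$ridge_lambda
  )
}

#' @rdname betamod-tidiers
#' @export
tidy.session_beta_metrics <- function(x, ...) {
  x$summary
}

#' @rdname betamod-tidiers
#' @export
tidy.beta_metrics <- function(x, ...) {
  x$per_trial
}

#' @rdname betamod-tidiers
#' @export
glance.beta_metrics <- function(x, ...) {
  x$summary
}
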