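#' Generate a synthetic cohort feature table (and optionally sessions)
#'
#' Draws one subject record per participant with the scenario's group
#' means/SDs and rank-correlation structure. The subject's true
#' modulation depths per region, fatigue severity (FSS), intracortical
#' facilitation (ICF), caudate volume and depression score (MADRS) are
#' tied together by a within-group Gaussian copula whose latent
#' correlations come from `scenario$feature_model$within_rho`; combined
#' with the between-group mean separation, the pooled Spearman
#' coefficients land near the `rho` targets. FSS marginals are truncated
#' normals split at the cut-off of 4, so the fatigued/non-fatigued labels
#' coincide with the simulated FSS by construction. Healthy controls
#' carry `NA` for patient-only scales.
#'
#' @param scenario A `sim_scenario`.
#' @param seed Integer seed (default the scenario seed). Per-subject
#'   `session_seed`s are derived deterministically from it.
#' @param sessions Also generate the EEG/EMG session of every subject
#'   (default `FALSE`; a full cohort of 300-trial sessions is
#'   compute-heavy).
#' @return List with `features` (tibble, one row per subject) and
#'   `sessions` (named list of [generate_session()] results, or `NULL`).
#' @export
generate_cohort <- function(scenario, seed = NULL, sessions = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  seed <- seed %||% scenario$seed
  fm <- scenario$feature_model
  validate_feature_model(fm)
  R <- copula_correlation(fm$within_rho)
  L <- chol(R)
  gp <- scenario$group_params

  features <- with_seed(seed, {
    rows <- lapply(names(scenario$n_per_group), function(g) {
      n <- scenario$n_per_group[[g]]
      U <- stats::pnorm(matrix(stats::rnorm(n * 7), n, 7) %*% L)
      colnames(U) <- copula_vars

      depth <- sapply(
        c(
          depth_frontal = "frontal",
          depth_left = "left_sensorimotor",
          depth_right = "right_sensorimotor"
        ),
        function(reg) {
          p <- gp[gp$group == g & gp$region == reg, ]
          stats::qnorm(
            U[, paste0("depth_", short_region(reg))],
            p$depth_mean, p$depth_sd
          )
        }
      )
      depth <- matrix(depth, nrow = n, dimnames = list(NULL, c(
        "depth_frontal", "depth_left", "depth_right"
      )))

      mrow <- function(v) fm$means[fm$means$variable == v &
        fm$means$group == g, ]
      fss_p <- mrow("FSS")
      fss_lim <- if (g == "MS_F") c(4, 7) else c(1, 4)
      fss <- qnorm_trunc(U[, "FSS"], fss_p$mean, fss_p$sd, fss_lim)
      madrs_p <- mrow("MADRS")
      madrs <- qnorm_trunc(U[, "MADRS"], madrs_p$mean, madrs_p$sd, c(0, Inf))
      icf_p <- mrow("ICF")
      icf <- stats::qnorm(U[, "ICF"], icf_p$mean, icf_p$sd)
      cau_p <- mrow("caudate_volume")
      caudate <- stats::qnorm(
        U[, "caudate_volume"], cau_p$mean, cau_p$sd
      )

      # independent marginals for the remaining variables
      other_vars <- setdiff(
        unique(fm$means$variable),
        c("FSS", "MADRS", "ICF", "caudate_volume")
      )
      others <- sapply(other_vars, function(v) {
        p <- mrow(v)
        if (is.na(p$mean)) rep(NA_real_, n) else stats::rnorm(n, p$mean, p$sd)
      })
      others <- matrix(others, nrow = n, dimnames = list(NULL, other_vars))
      others[, "lesion_count"] <- pmax(0, round(others[, "lesion_count"]))
      others[, "lesion_volume"] <- pmax(0, others[, "lesion_volume"])

      sex <- ifelse(stats::runif(n) < fm$p_female[[g]], "F", "M")

      # per-region true peak ERD; ERS follows from depth = ERS - ERD
      erd <- sapply(
        c(
          true_erd_frontal = "frontal",
          true_erd_left = "left_sensorimotor",
          true_erd_right = "right_sensorimotor"
        ),
        function(reg) {
          p <- gp[gp$group == g & gp$region == reg, ]
          stats::rnorm(n, p$erd_mean, p$erd_sd)
        }
      )
      erd <- matrix(erd, nrow = n, dimnames = list(NULL, c(
        "true_erd_frontal", "true_erd_left", "true_erd_right"
      )))

      em <- scenario$emg_params[scenario$emg_params$group == g, ]
      tibble::tibble(
        group = g,
        sex = sex,
        FSS = fss,
        MADRS = madrs,
        ICF = icf,
        caudate_volume = caudate,
        tibble::as_tibble(others),
        true_depth_frontal = depth[, "depth_frontal"],
        true_depth_left = depth[, "depth_left"],
        true_depth_right = depth[, "depth_right"],
        tibble::as_tibble(erd),
        no_dynamics = stats::runif(n) < scenario$no_dynamics_rate,
        rt_mean = em$rt_mean + stats::rnorm(n, 0, em$rt_sd_between)
      )
    })
    out <- dplyr::bind_rows(rows)
    dplyr::mutate(out,
      id = sprintf("S%03d", dplyr::row_number()),
      session_seed = vapply(
        dplyr::row_number(), function(i) child_seed(seed, 1000L + i),
        numeric(1)
      ),
      .before = 1
    )
  })
  # the fatigue label must coincide with the simulated FSS cut-off
  stopifnot(all((features$group == "MS_F") ==
    (features$FSS >= 4 & features$group != "HC")))

  ses <- NULL
  if (isTRUE(sessions)) {
    ses <- lapply(seq_len(nrow(features)), function(i) {
      generate_session(scenario, subject = as.list(features[i, ]))
    })
    names(ses) <- features$id
  }
  list(features = features, sessions = ses)
}

# Quantile of a normal truncated to [lim[1], lim[2]].
qnorm_trunc <- function(u, mean, sd, lim) {
  plo <- stats::pnorm(lim[1], mean, sd)
  phi <- stats::pnorm(lim[2], mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

#' Write / read a cohort feature table as CSV
#'
#' Plain UTF-8 CSV with one row per subject; missing patient-only scales
#' are empty fields. See [generate_cohort()] for the column inventory:
#' identifiers (`id`, `group`, `session_seed`), demographics (`sex`,
#' `age`, `education`), clinical scales (`FSS`, `MADRS`, `mFIS_*`,
#' `EDSS`, `MSQOL54_*`, `HPT9_*`, `disease_duration`), TMS indices
#' (`RMT`, `MEP_latency`, `SICI`, `ICF`, `CSP`), MRI volumetry
#' (`*_volume`, `lesion_count`), tract FA columns (`FA_*`), and the
#' generator ground truth (`true_depth_*`, `true_erd_*`, `no_dynamics`,
#' `rt_mean`).
#'
#' @param features Tibble from [generate_cohort()].
#' @param path File path.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, na.strings = ""))
}
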