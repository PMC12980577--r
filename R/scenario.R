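#' Simulation scenario for the cued pinch-movement study design
#'
#' Bundles every parameter of the synthetic-data generator: cohort sizes,
#' trial counts and timing, the per-group beta ERD/ERS targets by scalp
#' region (defaults are the study-condition group means and SDs), the
#' beta-to-background power ratio, EMG reaction-time structure, and the
#' feature-table model (group means/SDs plus rank-correlation targets).
#'
#' The group modulation-depth ordering of the defaults is
#' MS-F < HC <= MS-NF in every region.
#'
#' @param n_per_group Named counts for the three groups
#'   (`MS_F`, `MS_NF`, `HC`).
#' @param n_trials Cued movements per session (default 300).
#' @param fs EEG sampling rate in Hz (default 256).
#' @param epoch_window Epoch limits in seconds relative to the cue
#'   (default `c(-0.5, 1.5)`).
#' @param fs_emg EMG sampling rate in Hz (default 1024; the acquisition
#'   rate is a free design parameter of the generator).
#' @param snr Mean beta carrier band power relative to the background
#'   band power at the topography centre, measured after the CSD
#'   transform (default 30).
#' @param carrier_freq Beta carrier centre frequency in Hz (default 20).
#' @param band Analysis band in Hz (default `c(13.5, 25)`).
#' @param topo_sigma Angular SD (radians) of the Gaussian scalp
#'   topography around each region centre (default 0.22, keeping the
#'   six nearest neighbours near 35-40% of the peak amplitude so the
#'   three regional sources spatially distinct).
#' @param bg_sigma_uv Background EEG SD per channel in microvolts
#'   (default 10).
#' @param bg_spatial_sigma Angular SD (radians) of the distance-decaying
#'   inter-channel correlation of the background (volume-conduction-like
#'   blur; default 0.6).
#' @param bg_slope Spectral exponent of the 1/f^slope background
#'   (default 1).
#' @param group_params Tibble of per-group, per-region ERD/ERS targets;
#'   see [default_group_params()].
#' @param emg_params Tibble of per-group EMG parameters; see
#'   [default_emg_params()].
#' @param feature_model Feature-table model; see
#'   [default_feature_model()].
#' @param no_dynamics_rate Fraction of subjects generated with a flat
#'   beta envelope ("no visible beta dynamics", exercising the exclusion
#'   rule; default 0.12).
#' @param recovery_gamma Frozen per-region multiplicative calibration of
#'   the envelope design targets, compensating ROI-averaging dilution
#'   and the per-trial extreme-value bias of min/max extraction (see
#'   [default_recovery_gamma()] and [calibrate_depth_recovery()]).
#' @param seed Default base seed for cohort generation.
#' @return A validated list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_per_group = c(MS_F = 19, MS_NF = 22, HC = 18),
                         n_trials = 300,
                         fs = 256,
                         epoch_window = c(-0.5, 1.5),
                         fs_emg = 1024,
                         snr = 30,
                         carrier_freq = 20,
                         band = c(13.5, 25),
                         topo_sigma = 0.22,
                         bg_sigma_uv = 10,
                         bg_spatial_sigma = 0.6,
                         bg_slope = 1,
                         group_params = default_group_params(),
                         emg_params = default_emg_params(),
                         feature_model = default_feature_model(),
                         no_dynamics_rate = 0.12,
                         recovery_gamma = default_recovery_gamma(),
                         seed = 1L) {
  stopifnot(
    all(c("MS_F", "MS_NF", "HC") %in% names(n_per_group)),
    length(epoch_window) == 2, epoch_window[1] < 0, epoch_window[2] > 1
  )
  assert_scalar_number(snr, "snr", positive = TRUE)
  assert_scalar_number(n_trials, "n_trials", positive = TRUE)
  assert_scalar_number(fs, "fs", positive = TRUE)
  montage <- standard_montage()
  bad_centre <- setdiff(unique(group_params$centre), montage$label)
  if (length(bad_centre)) {
    stop("unknown centre electrode(s): ",
      paste(bad_centre, collapse = ", "),
      call. = FALSE
    )
  }
  validate_feature_model(feature_model)
  stopifnot(
    is.data.frame(recovery_gamma),
    all(c("region", "erd", "ers") %in% names(recovery_gamma)),
    all(unique(group_params$region) %in% recovery_gamma$region)
  )
  structure(
    list(
      n_per_group = n_per_group, n_trials = as.integer(n_trials),
      fs = fs, epoch_window = epoch_window, fs_emg = fs_emg,
      snr = snr, carrier_freq = carrier_freq, band = band,
      topo_sigma = topo_sigma, bg_sigma_uv = bg_sigma_uv,
      bg_spatial_sigma = bg_spatial_sigma, bg_slope = bg_slope,
      group_params = group_params, emg_params = emg_params,
      feature_model = feature_model,
      no_dynamics_rate = no_dynamics_rate,
      recovery_gamma = recovery_gamma,
      seed = as.integer(seed),
      montage = montage
    ),
    class = "sim_scenario"
  )
}

#' @exportS3Method base::print
print.sim_scenario <- function(x, ...) {
  cat(
    "<sim_scenario> groups ", paste(names(x$n_per_group), x$n_per_group,
      sep = "=", collapse = ", "
    ),
    "; ", x$n_trials, " trials @ ", x$fs, " Hz, snr ", x$snr, "\n",
    sep = ""
  )
  invisible(x)
}

#' Default per-group beta ERD/ERS targets by region
#'
#' Group means (and SDs) of peak ERD and modulation depth per scalp
#' region under the study conditions; ERS follows from
#' `depth = ERS - ERD`. Latencies place the desynchronization trough at
#' 0.30 s and the rebound peak at 0.85 s in every group (latency showed
#' no group differences). The topography centres are FCz for the frontal
#' region and the hand-knob electrodes C4/C3 for the two sensorimotor
#' regions (named for the printed region labels, see
#' [candidate_regions()]).
#'
#' @return Tibble with columns `group`, `region`, `erd_mean`, `erd_sd`,
#'   `depth_mean`, `depth_sd`, `erd_latency`, `ers_latency`, `centre`.
#' @export
default_group_params <- function() {
  tibble::tribble(
    ~group, ~region, ~erd_mean, ~erd_sd, ~depth_mean, ~depth_sd, ~centre,
    "MS_F", "frontal", -0.85, 0.02, 3.53, 0.26, "FCz",
    "MS_NF", "frontal", -0.89, 0.03, 4.20, 0.62, "FCz",
    "HC", "frontal", -0.88, 0.02, 4.07, 0.44, "FCz",
    "MS_F", "left_sensorimotor", -0.83, 0.032, 3.21, 0.34, "C4",
    "MS_NF", "left_sensorimotor", -0.83, 0.032, 3.69, 0.52, "C4",
    "HC", "left_sensorimotor", -0.85, 0.03, 3.65, 0.75, "C4",
    "MS_F", "right_sensorimotor", -0.83, 0.03, 3.45, 0.50, "C3",
    "MS_NF", "right_sensorimotor", -0.86, 0.04, 3.93, 0.69, "C3",
    "HC", "right_sensorimotor", -0.86, 0.03, 3.68, 0.48, "C3"
  ) |>
    dplyr::mutate(erd_latency = 0.30, ers_latency = 0.85)
}

#' Default per-group EMG parameters
#'
#' Healthy controls react fastest, fatigued patients slowest; the
#' burst-free "excessive noise" trial rate is set so that on average
#' about 286 of 300 movements survive the exclusion rule.
#'
#' @return Tibble with columns `group`, `rt_mean`, `rt_sd_between`,
#'   `rt_sd_within`, `burst_dur`, `burst_dur_sd`, `burst_gain`,
#'   `noise_sd`, `noise_trial_rate`.
#' @export
default_emg_params <- function() {
  tibble::tibble(
    group = c("MS_F", "MS_NF", "HC"),
    rt_mean = c(0.34, 0.31, 0.28),
    rt_sd_between = 0.03,
    rt_sd_within = 0.02,
    burst_dur = 0.45,
    burst_dur_sd = 0.08,
    burst_gain = 8,
    noise_sd = 0.02,
    noise_trial_rate = 0.052
  )
}

#' Default depth-recovery calibration factors
#'
#' Per-region multiplicative factors applied to the envelope design
#' targets so that the full pipeline (CSD, band-averaged Morlet power,
#' whole-trial normalization, personalized-ROI averaging, per-trial
#' min/max extraction) recovers the injected modulation-depth targets.
#' The values were frozen by iterating [calibrate_depth_recovery()] to
#' convergence under the default scenario; they are a property of the
#' generator's geometry and noise model, not of any particular cohort.
#'
#' @return Tibble with columns `region`, `erd`, `ers`.
#' @export
default_recovery_gamma <- function() {
  tibble::tribble(
    ~region, ~erd, ~ers,
    "frontal", 1.171, 1.076,
    "left_sensorimotor", 1.300, 1.253,
    "right_sensorimotor", 1.300, 1.266
  )
}

#' Default feature-table model
#'
#' Group means and SDs for the clinical, TMS, MRI and diffusion columns
#' of the subject record, plus the rank-correlation structure tying the
#' subject's true beta modulation depth to fatigue severity (FSS),
#' intracortical facilitation (ICF), caudate volume and depression
#' (MADRS). `rho` states the pooled (across patients) Spearman targets;
#' `within_rho` holds the within-group latent copula correlations, whose
#' defaults were chosen once so that, combined with the group-mean
#' separation, the pooled coefficients land near the `rho` targets.
#'
#' Patient-only scales (mFIS, EDSS, MSQOL-54, disease duration) are
#' missing (`NA`) for healthy controls.
#'
#' @return List with elements `means` (long tibble: `variable`, `group`,
#'   `mean`, `sd`), `rho`, `within_rho`.
#' @export
default_feature_model <- function() {
  g <- function(variable, ms_f, ms_nf, hc, sd_f, sd_nf = sd_f,
                sd_hc = sd_f) {
    tibble::tibble(
      variable = variable,
      group = c("MS_F", "MS_NF", "HC"),
      mean = c(ms_f, ms_nf, hc),
      sd = c(sd_f, sd_nf, sd_hc)
    )
  }
  means <- dplyr::bind_rows(
    g("age", 41.84, 42.41, 41.61, 10.56, 9.62, 11.07),
    g("education", 13.26, 14.14, 16.39, 3.53, 3.06, 3.01),
    g("disease_duration", 107.69, 107.53, NA, 90.71, 90.94, NA),
    g("FSS", 5.24, 2.40, 2.20, 0.82, 0.86, 0.80),
    g("MADRS", 8.56, 4.68, 2.67, 4.26, 5.38, 2.35),
    g("mFIS_total", 42.74, 22.05, NA, 11.43, 14.41, NA),
    g("mFIS_cog", 18.05, 9.96, NA, 6.20, 7.54, NA),
    g("mFIS_ph", 20.84, 10.77, NA, 5.53, 7.10, NA),
    g("mFIS_psy", 3.63, 1.32, NA, 2.06, 1.29, NA),
    g("EDSS", 1.76, 1.48, NA, 0.61, 0.47, NA),
    g("MSQOL54_ph", 4.68, 5.74, NA, 1.50, 2.04, NA),
    g("MSQOL54_mh", 4.22, 5.62, NA, 1.50, 1.91, NA),
    g("HPT9_right", 20.66, 23.94, 21.66, 3.01, 3.58, 3.57),
    g("HPT9_left", 22.12, 24.06, 24.20, 4.85, 2.22, 7.50),
    g("RMT", 45, 44, 43, 8),
    g("MEP_latency", 22.0, 21.5, 21.0, 1.5),
    g("SICI", 0.55, 0.50, 0.45, 0.20),
    g("ICF", 110, 236, 177, 60, 80, 70),
    g("CSP", 95, 108, 110, 25),
    g("WM_volume", 447.6, 462.1, 470.0, 30),
    g("GM_volume", 590, 595, 600, 40),
    g("total_volume", 1130, 1155, 1180, 60),
    g("thalamus_volume", 13.99, 14.38, 16.00, 1.5),
    g("caudate_volume", 6.37, 6.90, 7.20, 0.8),
    g("lesion_count", 26, 25, 0.8, 12, 12, 0.9),
    g("lesion_volume", 6.5, 6.0, 0.15, 5, 5, 0.2),
    g("FA_CST_left", 0.55, 0.60, 0.56, 0.03),
    g("FA_CST_right", 0.54, 0.57, 0.57, 0.03),
    g("FA_SLF_left", 0.53, 0.57, 0.54, 0.03),
    g("FA_SLF_right", 0.52, 0.57, 0.53, 0.03),
    g("FA_thal_rad_left", 0.51, 0.52, 0.51, 0.03),
    g("FA_thal_rad_right", 0.50, 0.54, 0.51, 0.03),
    g("FA_cingulum_left", 0.55, 0.55, 0.55, 0.03),
    g("FA_cingulum_right", 0.55, 0.55, 0.55, 0.03)
  )
  list(
    means = means,
    p_female = c(MS_F = 13 / 19, MS_NF = 11 / 22, HC = 11 / 18),
    rho = c(
      fss_depth = -0.54, icf_depth = 0.49,
      caudate_depth = 0.35, madrs_fss = 0.35
    ),
    within_rho = c(
      fss_depth = -0.05, icf_depth = 0.10,
      caudate_depth = 0.18, madrs_fss = 0.18,
      depth_region = 0.60
    )
  )
}

# Latent-variable order for the within-group Gaussian copula.
copula_vars <- c(
  "depth_frontal", "depth_left", "depth_right",
  "FSS", "ICF", "caudate_volume", "MADRS"
)

# Build the latent Pearson correlation matrix from the within-group
# Spearman targets (Spearman -> Pearson via 2 sin(pi rho / 6)).
copula_correlation <- function(within_rho) {
  sp <- matrix(0, 7, 7, dimnames = list(copula_vars, copula_vars))
  diag(sp) <- 1
  set <- function(a, b, v) {
    sp[a, b] <<- v
    sp[b, a] <<- v
  }
  dr <- within_rho[["depth_region"]]
  set("depth_frontal", "depth_left", dr)
  set("depth_frontal", "depth_right", dr)
  set("depth_left", "depth_right", dr)
  r1 <- within_rho[["fss_depth"]]
  set("FSS", "depth_frontal", r1)
  set("FSS", "depth_left", 0.65 * r1)
  set("FSS", "depth_right", 0.65 * r1)
  r2 <- within_rho[["icf_depth"]]
  set("ICF", "depth_frontal", r2)
  set("ICF", "depth_left", 0.8 * r2)
  set("ICF", "depth_right", 0.8 * r2)
  r3 <- within_rho[["caudate_depth"]]
  set("caudate_volume", "depth_frontal", r3)
  set("caudate_volume", "depth_left", 0.9 * r3)
  set("caudate_volume", "depth_right", 0.5 * r3)
  set("MADRS", "FSS", within_rho[["madrs_fss"]])
  set("MADRS", "ICF", -0.5 * within_rho[["madrs_fss"]])
  2 * sin(pi * sp / 6)
}

validate_feature_model <- function(fm) {
  stopifnot(
    is.list(fm),
    all(c("means", "rho", "within_rho", "p_female") %in% names(fm))
  )
  R <- copula_correlation(fm$within_rho)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    evr <- eigen(R, symmetric = TRUE)
    lam <- pmax(evr$values, 1e-6)
    Rn <- evr$vectors %*% diag(lam) %*% t(evr$vectors)
    Rn <- stats::cov2cor(Rn)
    dimnames(Rn) <- dimnames(R)
    stop(
      "infeasible correlation targets: latent matrix is not positive ",
      "semi-definite (min eigenvalue ", signif(min(ev), 3),
      "). Nearest feasible matrix has, e.g., fss_depth = ",
      signif(Rn["FSS", "depth_frontal"], 3), ", icf_depth = ",
      signif(Rn["ICF", "depth_frontal"], 3),
      call. = FALSE
    )
  }
  invisible(fm)
}

#' Write / read a scenario as a plain-text YAML config
#'
#' Tibbles are flattened to lists of columns; `read_scenario()`
#' reconstitutes and re-validates the scenario.
#'
#' @param scenario A `sim_scenario` object.
#' @param path File path.
#' @export
write_scenario <- function(scenario, path) {
  x <- unclass(scenario)
  x$montage <- NULL
  # yaml drops names on atomic vectors; store named vectors as maps
  x$n_per_group <- as.list(x$n_per_group)
  x$feature_model$p_female <- as.list(x$feature_model$p_female)
  x$feature_model$rho <- as.list(x$feature_model$rho)
  x$feature_model$within_rho <- as.list(x$feature_model$within_rho)
  x$group_params <- as.list(x$group_params)
  x$emg_params <- as.list(x$emg_params)
  x$recovery_gamma <- as.list(x$recovery_gamma)
  x$feature_model$means <- as.list(x$feature_model$means)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(sim_scenario, list(
    n_per_group = unlist(x$n_per_group),
    n_trials = x$n_trials, fs = x$fs,
    epoch_window = unlist(x$epoch_window), fs_emg = x$fs_emg,
    snr = x$snr, carrier_freq = x$carrier_freq, band = unlist(x$band),
    topo_sigma = x$topo_sigma, bg_sigma_uv = x$bg_sigma_uv,
    bg_spatial_sigma = x$bg_spatial_sigma, bg_slope = x$bg_slope,
    group_params = tibble::as_tibble(x$group_params),
    emg_params = tibble::as_tibble(x$emg_params),
    feature_model = list(
      means = tibble::as_tibble(x$feature_model$means),
      p_female = unlist(x$feature_model$p_female),
      rho = unlist(x$feature_model$rho),
      within_rho = unlist(x$feature_model$within_rho)
    ),
    no_dynamics_rate = x$no_dynamics_rate,
    recovery_gamma = tibble::as_tibble(x$recovery_gamma),
    seed = x$seed
  ))
}
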