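#' Select a personalized ROI within a candidate region
#'
#' Data-driven two-pass ROI construction: on the trial-averaged,
#' baseline-normalized beta time course, every electrode of the candidate
#' region gets a modulation depth (maximum in the rebound window minus
#' minimum in the desynchronization window). The electrode with the
#' largest depth becomes the peak, and the personalized ROI is the peak
#' plus its six nearest montage electrodes by 3-D Euclidean distance on
#' the unit-sphere positions. Ties in depth are broken by distance to the
#' region centroid, then lexicographically, so selection is
#' deterministic. The neighbour search ranges over the whole montage by
#' default (set `restrict_to_region = TRUE` to confine it).
#'
#' The desynchronization window is half-open (`[0, 0.7)` s) and the
#' rebound window closed (`[0.7, 1.0]` s), so the 0.7 s sample belongs to
#' the rebound side only.
#'
#' @param tc A `beta_timecourse` object (trials are averaged internally).
#' @param region Character vector of candidate electrode labels, e.g. one
#'   entry of [candidate_regions()].
#' @param montage Montage tibble.
#' @param erd_window,ers_window Search windows in seconds.
#' @param n_neighbours Number of neighbours (default 6).
#' @param restrict_to_region Restrict the neighbour search to the region
#'   members (default `FALSE`).
#' @return A `personalized_roi` list: `peak_electrode`, `members`
#'   (peak + neighbours), `depth_by_electrode` tibble.
#' @export
select_roi <- function(tc, region, montage, erd_window = c(0, 0.7),
                       ers_window = c(0.7, 1.0), n_neighbours = 6,
                       restrict_to_region = FALSE) {
  stopifnot(inherits(tc, "beta_timecourse"))
  missing_lab <- setdiff(region, montage$label)
  if (length(missing_lab)) {
    stop(
      "region member(s) not in montage: ",
      paste(missing_lab, collapse = ", "),
      call. = FALSE
    )
  }
  idx <- match(region, tc$montage$label)
  if (anyNA(idx)) {
    stop("time course lacks channels: ",
      paste(region[is.na(idx)], collapse = ", "),
      call. = FALSE
    )
  }
  avg <- apply(tc$value[, idx, , drop = FALSE], c(2, 3), mean)
  in_erd <- tc$times >= erd_window[1] & tc$times < erd_window[2]
  in_ers <- tc$times >= ers_window[1] & tc$times <= ers_window[2]
  depth <- apply(avg[, in_ers, drop = FALSE], 1, max) -
    apply(avg[, in_erd, drop = FALSE], 1, min)

  pm <- montage_matrix(montage)
  centroid <- colMeans(pm[region, , drop = FALSE])
  centroid <- centroid / sqrt(sum(centroid^2))
  d_cent <- sqrt(colSums((t(pm[region, , drop = FALSE]) - centroid)^2))
  ord <- order(-depth, d_cent, region)
  peak <- region[ord[1]]

  search_montage <- if (restrict_to_region) {
    montage[montage$label %in% region, ]
  } else {
    montage
  }
  members <- c(
    peak,
    montage_neighbours(search_montage, peak, n = n_neighbours)
  )
  structure(
    list(
      peak_electrode = peak,
      members = members,
      depth_by_electrode = tibble::tibble(
        electrode = region,
        depth = depth
      )
    ),
    class = "personalized_roi"
  )
}

#' @exportS3Method base::print
print.personalized_roi <- function(x, ...) {
  cat(
    "<personalized_roi> peak ", x$peak_electrode, "; members: ",
    paste(x$members, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Per-trial and subject-level beta ERD/ERS metrics within an ROI
#'
#' The ROI time course is the mean of the normalized beta series over the
#' ROI members, per trial. Peak ERD is the minimum (with its latency) in
#' `[0, 0.7)` s, peak ERS the maximum in `[0.7, 1.0]` s, and modulation
#' depth is their difference -- per trial, then averaged over kept trials
#' for the subject-level value. The epoch mean of the normalized ROI
#' course (`mean_beta`, identically near zero by the baseline identity)
#' and the pre-normalization ROI band power (`mean_band_power`, for
#' baseline-difference tests) are retained as well.
#'
#' @param tc A `beta_timecourse` object (per-trial values).
#' @param roi A `personalized_roi` from [select_roi()].
#' @inheritParams select_roi
#' @return List of class `beta_metrics`: `per_trial` tibble (`trial`,
#'   `peak_erd`, `erd_latency`, `peak_ers`, `ers_latency`,
#'   `modulation_depth`, `mean_beta`, `mean_band_power`) and `summary`
#'   one-row tibble of trial means plus `n_trials`.
#' @export
extract_metrics <- function(tc, roi, erd_window = c(0, 0.7),
                            ers_window = c(0.7, 1.0)) {
  stopifnot(inherits(tc, "beta_timecourse"))
  idx <- match(roi$members, tc$montage$label)
  if (anyNA(idx)) {
    stop("time course lacks ROI member(s): ",
      paste(roi$members[is.na(idx)], collapse = ", "),
      call. = FALSE
    )
  }
  n_tr <- dim(tc$value)[1]
  if (n_tr == 0) stop("no kept trials for this subject", call. = FALSE)
  course <- apply(tc$value[, idx, , drop = FALSE], c(1, 3), mean)
  course <- matrix(course, nrow = n_tr)
  bp <- apply(tc$band_power[, idx, , drop = FALSE], c(1, 3), mean)
  bp <- matrix(bp, nrow = n_tr)
  in_erd <- tc$times >= erd_window[1] & tc$times < erd_window[2]
  in_ers <- tc$times >= ers_window[1] & tc$times <= ers_window[2]
  t_erd <- tc$times[in_erd]
  t_ers <- tc$times[in_ers]

  erd_i <- apply(course[, in_erd, drop = FALSE], 1, which.min)
  ers_i <- apply(course[, in_ers, drop = FALSE], 1, which.max)
  peak_erd <- course[cbind(seq_len(n_tr), which(in_erd)[erd_i])]
  peak_ers <- course[cbind(seq_len(n_tr), which(in_ers)[ers_i])]

  per_trial <- tibble::tibble(
    trial = tc$kept_trial_ids,
    peak_erd = peak_erd,
    erd_latency = t_erd[erd_i],
    peak_ers = peak_ers,
    ers_latency = t_ers[ers_i],
    modulation_depth = peak_ers - peak_erd,
    mean_beta = rowMeans(course),
    mean_band_power = rowMeans(bp)
  )
  summary <- tibble::tibble(
    peak_erd = mean(per_trial$peak_erd),
    erd_latency = mean(per_trial$erd_latency),
    peak_ers = mean(per_trial$peak_ers),
    ers_latency = mean(per_trial$ers_latency),
    modulation_depth = mean(per_trial$modulation_depth),
    mean_beta = mean(per_trial$mean_beta),
    mean_band_power = mean(per_trial$mean_band_power),
    n_trials = n_tr
  )
  structure(
    list(per_trial = per_trial, summary = summary, roi = roi),
    class = "beta_metrics"
  )
}

#' Exclusion rule for subjects without discernible beta dynamics
#'
#' A subject is excluded when, in every ROI, the trial-averaged peak ERD
#' is above `erd_threshold` or the trial-averaged peak ERS is below
#' `ers_threshold` -- i.e. no region shows both a clear power dip and a
#' clear rebound. Thresholds are configurable.
#'
#' @param summaries Tibble with one row per ROI containing `peak_erd` and
#'   `peak_ers` columns (e.g. stacked `summary` rows from
#'   [extract_metrics()]).
#' @param erd_threshold Required depth of the trial-averaged ERD
#'   (default -0.2).
#' @param ers_threshold Required height of the trial-averaged ERS
#'   (default 0.2).
#' @return `TRUE` if the subject is kept, `FALSE` if excluded.
#' @export
keep_subject <- function(summaries, erd_threshold = -0.2,
                         ers_threshold = 0.2) {
  stopifnot(all(c("peak_erd", "peak_ers") %in% names(summaries)))
  any(summaries$peak_erd <= erd_threshold &
    summaries$peak_ers >= ers_threshold)
}

#' End-to-end beta modulation metrics for one session
#'
#' Convenience wrapper running the full per-subject analysis chain on an
#' epoched session: current source density, band-averaged Morlet power
#' with whole-trial baseline normalization, two-pass personalized-ROI
#' selection within each candidate region, and per-trial metric
#' extraction. Only the channels actually needed (region members and the
#' selected ROI members) are decomposed, which keeps full sessions
#' tractable.
#'
#' @param epochs An `eeg_epochs` object (sensor-space voltages).
#' @param regions Named list of candidate regions (default
#'   [candidate_regions()]).
#' @param band Beta band in Hz (default `c(13.5, 25)`).
#' @param apply_csd Apply the CSD transform first (default `TRUE`).
#' @param ... Passed to [select_roi()] / [extract_metrics()] (windows,
#'   neighbour options).
#' @return List of class `session_beta_metrics`: `per_trial` (tibble with
#'   a `region` column), `summary` (one row per region), `rois`, and
#'   `kept` (the subject-level exclusion flag).
#' @export
session_beta_metrics <- function(epochs, regions = candidate_regions(),
                                 band = c(13.5, 25), apply_csd = TRUE,
                                 ...) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  x <- if (apply_csd) csd_transform(epochs) else epochs
  region_chans <- unique(unlist(regions))
  tc <- beta_timecourse(x, band = band, channels = region_chans)

  rois <- lapply(regions, function(reg) {
    select_roi(tc, reg, x$montage, ...)
  })
  extra <- setdiff(unique(unlist(lapply(rois, `[[`, "members"))),
    region_chans
  )
  tc_all <- if (length(extra)) {
    beta_timecourse(x, band = band, channels = c(region_chans, extra))
  } else {
    tc
  }

  mets <- lapply(rois, function(roi) extract_metrics(tc_all, roi, ...))
  per_trial <- dplyr::bind_rows(
    lapply(names(mets), function(r) {
      dplyr::mutate(mets[[r]]$per_trial, region = r, .before = 1)
    })
  )
  summary <- dplyr::bind_rows(
    lapply(names(mets), function(r) {
      dplyr::mutate(mets[[r]]$summary, region = r, .before = 1)
    })
  )
  structure(
    list(
      per_trial = per_trial, summary = summary, rois = rois,
      kept = keep_subject(summary)
    ),
    class = "session_beta_metrics"
  )
}

#' @exportS3Method base::print
print.session_beta_metrics <- function(x, ...) {
  cat("<session_beta_metrics>\n")
  print(x$summary)
  invisible(x)
}
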