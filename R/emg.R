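#' Full-wave rectification of an EMG trace
#'
#' Absolute deviation from the trace mean: `|x - mean(x)|`. Invariant to
#' adding any constant to the raw signal; an all-constant input yields an
#' all-zero trace (not an error).
#'
#' @param x Numeric vector, one trial's EMG.
#' @return Non-negative numeric vector of the same length.
#' @export
emg_rectify <- function(x) {
  abs(x - mean(x))
}

#' Smoothed EMG envelope
#'
#' Zero-phase (forward-backward) second-order Butterworth low-pass of the
#' rectified signal. The nominal 20 Hz cutoff is raised by 25% at design
#' time so that the double-pass response has its effective -3 dB point at
#' the desired 20 Hz (a single-pass second-order Butterworth applied twice
#' is -3 dB at about 0.802 times its design cutoff). The output is divided
#' by its maximum so the trace peaks at 1; an all-zero input stays
#' all-zero.
#'
#' @param x Rectified (non-negative) EMG trace.
#' @param fs Sampling rate in Hz.
#' @param cutoff Desired effective -3 dB frequency in Hz (default 20).
#' @param adjust Design-cutoff inflation factor (default 1.25).
#' @param normalize Divide by the maximum (default `TRUE`).
#' @return Envelope trace, the same length as `x`.
#' @export
emg_envelope <- function(x, fs, cutoff = 20, adjust = 1.25,
                         normalize = TRUE) {
  assert_scalar_number(fs, "fs", positive = TRUE)
  b <- signal::butter(2, cutoff * adjust / (fs / 2), type = "low")
  y <- signal::filtfilt(b, x)
  if (normalize) {
    mx <- max(y)
    if (mx > 0) y <- y / mx
  }
  y
}

#' Automated EMG onset and contraction duration
#'
#' Threshold surrogate for visual onset marking: the envelope must exceed
#' the pre-cue baseline mean plus `k_sd` baseline standard deviations for
#' at least `min_run` seconds. Onset is the start of the first qualifying
#' run; offset is the last supra-threshold sample of the last qualifying
#' run; duration is their difference. A trial is dropped (`kept = FALSE`,
#' "no clear EMG peak") when no qualifying run exists or the envelope peak
#' is below `peak_ratio` baseline standard deviations. All thresholds are
#' arguments.
#'
#' @param envelope Envelope trace over the whole epoch.
#' @param times Sample times in seconds relative to the cue (must include
#'   a pre-cue segment).
#' @param k_sd Baseline SD multiplier for the onset threshold (default 3).
#' @param min_run Minimum supra-threshold run in seconds (default 0.025).
#' @param peak_ratio Minimum peak / baseline-SD ratio for a trial to be
#'   kept (default 5).
#' @return One-row tibble: `onset`, `duration`, `envelope_peak`, `kept`.
#' @export
emg_onset_duration <- function(envelope, times, k_sd = 3, min_run = 0.025,
                               peak_ratio = 5) {
  stopifnot(length(envelope) == length(times))
  base <- envelope[times < 0]
  if (length(base) < 2) {
    stop("no pre-cue baseline segment in `times`", call. = FALSE)
  }
  fs <- 1 / mean(diff(times))
  thr <- mean(base) + k_sd * stats::sd(base)
  post <- times >= 0
  env_post <- envelope[post]
  t_post <- times[post]
  above <- env_post > thr
  r <- rle(above)
  min_n <- ceiling(min_run * fs)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  good <- which(r$values & r$lengths >= min_n)

  peak <- max(envelope)
  bsd <- stats::sd(base)
  no_peak <- bsd <= 0 || peak < peak_ratio * bsd

  if (length(good) == 0 || no_peak) {
    return(tibble::tibble(
      onset = NA_real_, duration = NA_real_,
      envelope_peak = peak, kept = FALSE
    ))
  }
  onset <- t_post[starts[good[1]]]
  offset <- t_post[ends[good[length(good)]]]
  tibble::tibble(
    onset = onset, duration = offset - onset,
    envelope_peak = peak, kept = TRUE
  )
}

#' Per-trial EMG metrics for a session
#'
#' Runs the rectification / envelope / onset chain on every trial of an
#' `emg_traces` object. Rectification is restricted to the 1.5-s post-cue
#' movement segment; the pre-cue segment enters only through the baseline
#' statistics of the onset rule. Envelopes are normalized jointly by the
#' session maximum, so the largest envelope value across kept trials is 1
#' and per-trial peaks are comparable within the session.
#'
#' @param emg An `emg_traces` object (see [generate_session()]): `data`
#'   (trials x samples), `fs`, `times`.
#' @inheritParams emg_onset_duration
#' @return Tibble with one row per trial: `trial`, `onset`, `duration`,
#'   `envelope_peak`, `kept`.
#' @export
emg_session_metrics <- function(emg, k_sd = 3, min_run = 0.025,
                                peak_ratio = 5) {
  stopifnot(is.matrix(emg$data), length(emg$times) == ncol(emg$data))
  times <- emg$times
  move <- times >= 0 & times <= 1.5
  n_tr <- nrow(emg$data)
  envs <- matrix(0, n_tr, ncol(emg$data))
  for (i in seq_len(n_tr)) {
    x <- emg$data[i, ]
    # movement-window mean defines the rectification offset
    rect <- abs(x - mean(x[move]))
    envs[i, ] <- emg_envelope(rect, emg$fs, normalize = FALSE)
  }
  mx <- max(envs)
  if (mx > 0) envs <- envs / mx
  res <- lapply(seq_len(n_tr), function(i) {
    emg_onset_duration(envs[i, ], times,
      k_sd = k_sd, min_run = min_run,
      peak_ratio = peak_ratio
    )
  })
  out <- dplyr::bind_rows(res)
  dplyr::mutate(out, trial = seq_len(n_tr), .before = 1)
}

#' Joint EEG/EMG trial exclusion
#'
#' Trials excluded for unclear EMG are removed from the EEG epochs as
#' well, so downstream averaging uses the same kept set on both
#' modalities.
#'
#' @param epochs An `eeg_epochs` object.
#' @param emg_metrics Tibble from [emg_session_metrics()].
#' @return List with the subset `epochs` and the kept `emg_metrics` rows;
#'   both carry the same trial ids.
#' @export
apply_joint_exclusion <- function(epochs, emg_metrics) {
  stopifnot(nrow(emg_metrics) == dim(epochs$data)[1])
  keep <- which(emg_metrics$kept)
  list(
    epochs = subset_trials(epochs, keep),
    emg_metrics = emg_metrics[keep, ]
  )
}
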