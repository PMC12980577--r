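#' Complex Morlet wavelet time-frequency decomposition
#'
#' Convolves every trial and channel with complex Morlet wavelets on a
#' regular frequency grid (default 1-90 Hz in 0.5 Hz increments, 179 bins)
#' and returns power on a 10-ms time grid. The number of cycles grows
#' linearly with frequency between 3 cycles at 1 Hz and 10 cycles at
#' 90 Hz. Samples closer to an epoch edge than the wavelet half-width
#' (3 Gaussian SDs) are flagged per frequency as edge-contaminated;
#' frequencies whose wavelet does not fit in the epoch at all are flagged
#' entirely rather than raising an error.
#'
#' Wavelet kernels are normalized to unit envelope area, so a unit
#' complex exponential at the wavelet's centre frequency yields power 1
#' (a real unit-amplitude sinusoid yields about 0.25).
#'
#' @param epochs An `eeg_epochs` object.
#' @param fmin,fmax,fstep Frequency grid in Hz (defaults 1, 90, 0.5).
#' @param tstep Output time step in seconds (default 0.01).
#' @return An `eeg_tfr` object: a list with `power`
#'   (trials x channels x frequencies x timepoints), `freqs`, `times`,
#'   `n_cycles`, `edge_ok` (frequencies x timepoints logical), `fs`,
#'   `montage`.
#' @export
morlet_tfr <- function(epochs, fmin = 1, fmax = 90, fstep = 0.5,
                       tstep = 0.01) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  freqs <- seq(fmin, fmax, by = fstep)
  fs <- epochs$fs
  times <- epochs$times
  grid <- tfr_time_grid(times, tstep)
  d <- epochs$data
  dm <- dim(d)
  x <- matrix(aperm(d, c(3, 1, 2)), nrow = dm[3]) # samples x (trial*channel)

  pw <- band_power_core(x, fs, times, freqs, grid$idx, average = FALSE)
  power <- aperm(
    array(pw$power, dim = c(length(grid$idx), dm[1], dm[2], length(freqs))),
    c(2, 3, 4, 1)
  )
  structure(
    list(
      power = power, freqs = freqs, times = grid$times,
      n_cycles = pw$n_cycles, edge_ok = pw$edge_ok, fs = fs,
      montage = epochs$montage,
      kept_trial_ids = epochs$kept_trial_ids %||% seq_len(dm[1])
    ),
    class = "eeg_tfr"
  )
}

#' @exportS3Method base::print
print.eeg_tfr <- function(x, ...) {
  dm <- dim(x$power)
  cat(
    "<eeg_tfr> ", dm[1], " trials x ", dm[2], " channels x ",
    dm[3], " freqs (", min(x$freqs), "-", max(x$freqs), " Hz) x ",
    dm[4], " timepoints\n",
    sep = ""
  )
  invisible(x)
}

# Linear cycle mapping anchored at the conventional endpoints.
morlet_cycles <- function(f) 3 + (10 - 3) * (f - 1) / (90 - 1)

tfr_time_grid <- function(times, tstep) {
  fs <- 1 / mean(diff(times))
  tg <- seq(times[1], times[length(times)], by = tstep)
  idx <- round((tg - times[1]) * fs) + 1
  list(times = times[idx], idx = idx)
}

# Shared convolution engine. `x` is samples x series. Returns power at the
# grid indices; if `average`, the mean over frequencies (band-averaged
# power), else the full (grid x series x freq) stack.
band_power_core <- function(x, fs, times, freqs, grid_idx, average = TRUE,
                            chunk = 4000L) {
  n <- nrow(x)
  ncyc <- morlet_cycles(freqs)
  sigma <- ncyc / (2 * pi * freqs)
  half <- ceiling(3 * sigma * fs)
  max_half <- min(max(half), n) # truncate at the epoch if needed
  nfft <- 2^ceiling(log2(n + 2 * max_half + 1))

  # frequency-domain kernels, centred (zero-delay) via wrapped placement
  kern <- matrix(0 + 0i, nfft, length(freqs))
  for (j in seq_along(freqs)) {
    h <- min(half[j], n)
    tt <- (-h:h) / fs
    env <- exp(-tt^2 / (2 * sigma[j]^2))
    w <- env * exp(2i * pi * freqs[j] * tt) / sum(env)
    v <- complex(length.out = nfft)
    v[1:(h + 1)] <- w[(h + 1):(2 * h + 1)]
    v[(nfft - h + 1):nfft] <- w[1:h]
    kern[, j] <- stats::fft(v)
  }

  edge_ok <- matrix(TRUE, length(freqs), length(grid_idx))
  for (j in seq_along(freqs)) {
    hw <- half[j] / fs
    tg <- times[grid_idx]
    ok <- tg >= times[1] + hw & tg <= times[length(times)] - hw
    edge_ok[j, ] <- ok
  }

  nser <- ncol(x)
  out <- if (average) {
    matrix(0, length(grid_idx), nser)
  } else {
    array(0, dim = c(length(grid_idx), nser, length(freqs)))
  }
  starts <- seq(1L, nser, by = chunk)
  for (s in starts) {
    cols <- s:min(s + chunk - 1L, nser)
    xp <- rbind(x[, cols, drop = FALSE], matrix(0, nfft - n, length(cols)))
    Fx <- stats::mvfft(xp)
    for (j in seq_along(freqs)) {
      cv <- stats::mvfft(Fx * kern[, j], inverse = TRUE) / nfft
      pj <- Mod(cv[grid_idx, , drop = FALSE])^2
      if (average) {
        out[, cols] <- out[, cols] + pj
      } else {
        out[, cols, j] <- pj
      }
    }
  }
  if (average) out <- out / length(freqs)
  list(power = out, n_cycles = ncyc, edge_ok = edge_ok)
}

#' Whole-trial subtract-and-divide baseline normalization of band power
#'
#' Averages TFR power over a frequency band, then normalizes each trial
#' and channel by the time-mean of that band power over the entire epoch:
#' `(P - mu) / mu`. By construction the time-mean of the normalized
#' time course over the epoch grid is exactly zero.
#'
#' @param tfr An `eeg_tfr` object from [morlet_tfr()].
#' @param band Numeric length-2 band limits in Hz (default beta,
#'   `c(13.5, 25)`).
#' @return A `beta_timecourse` object: `value`
#'   (trials x channels x timepoints), `band_power` (same shape,
#'   pre-normalization), `mu` (trials x channels), `flagged` (trials with
#'   non-positive baseline), `band`, `times`, `montage`.
#' @export
baseline_normalize <- function(tfr, band = c(13.5, 25)) {
  stopifnot(inherits(tfr, "eeg_tfr"), length(band) == 2)
  if (band[1] < min(tfr$freqs) || band[2] > max(tfr$freqs)) {
    stop("band outside the decomposed frequency range", call. = FALSE)
  }
  sel <- tfr$freqs >= band[1] & tfr$freqs <= band[2]
  bp <- apply(tfr$power[, , sel, , drop = FALSE], c(1, 2, 4), mean)
  normalize_band_power(bp, band, tfr$times, tfr$montage,
    kept_trial_ids = tfr$kept_trial_ids
  )
}

normalize_band_power <- function(bp, band, times, montage,
                                 kept_trial_ids = NULL) {
  mu <- apply(bp, c(1, 2), mean)
  flagged <- which(mu <= 0, arr.ind = TRUE)
  safe_mu <- mu
  safe_mu[safe_mu <= 0] <- NA_real_
  value <- sweep(sweep(bp, c(1, 2), safe_mu, `-`), c(1, 2), safe_mu, `/`)
  structure(
    list(
      value = value, band_power = bp, mu = mu,
      flagged = unique(flagged[, "row"]),
      band = band, times = times, montage = montage,
      kept_trial_ids = kept_trial_ids %||% seq_len(dim(bp)[1])
    ),
    class = "beta_timecourse"
  )
}

#' @exportS3Method base::print
print.beta_timecourse <- function(x, ...) {
  dm <- dim(x$value)
  cat(
    "<beta_timecourse> ", dm[1], " trials x ", dm[2], " channels x ",
    dm[3], " timepoints, band ", x$band[1], "-", x$band[2], " Hz\n",
    sep = ""
  )
  invisible(x)
}

#' Band-averaged, baseline-normalized power (memory-light path)
#'
#' Computes the band-averaged Morlet power directly (accumulating over
#' band frequencies without materializing the full TFR array) and applies
#' the whole-trial subtract-and-divide normalization. Identical in result
#' to `baseline_normalize(morlet_tfr(epochs, fmin = band[1],
#' fmax = band[2]), band)` but usable on full sessions.
#'
#' @inheritParams morlet_tfr
#' @param band Band limits in Hz (default `c(13.5, 25)`).
#' @param fstep Frequency step within the band (default 0.5).
#' @param channels Optional character vector restricting the computation
#'   to a subset of channels (in montage order).
#' @return A `beta_timecourse` object (see [baseline_normalize()]).
#' @export
beta_timecourse <- function(epochs, band = c(13.5, 25), fstep = 0.5,
                            tstep = 0.01, channels = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  freqs <- seq(band[1], band[2], by = fstep)
  d <- epochs$data
  montage <- epochs$montage
  if (!is.null(channels)) {
    idx <- match(channels, montage$label)
    if (anyNA(idx)) stop("unknown channel in `channels`", call. = FALSE)
    d <- d[, idx, , drop = FALSE]
    montage <- montage[idx, ]
  }
  dm <- dim(d)
  grid <- tfr_time_grid(epochs$times, tstep)
  x <- matrix(aperm(d, c(3, 1, 2)), nrow = dm[3])
  pw <- band_power_core(x, epochs$fs, epochs$times, freqs, grid$idx,
    average = TRUE
  )
  bp <- aperm(array(pw$power, dim = c(length(grid$idx), dm[1], dm[2])),
    perm = c(2, 3, 1)
  )
  normalize_band_power(bp, band, grid$times, montage,
    kept_trial_ids = epochs$kept_trial_ids %||% seq_len(dm[1])
  )
}
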