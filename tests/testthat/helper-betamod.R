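# Shared builders for the test suite.

# An eeg_epochs object whose every channel carries `signal` (a function of
# time, or a constant), on the standard montage unless given another one.
make_epochs <- function(signal = 0, n_trials = 1, fs = 256,
                        window = c(-0.5, 1.5), montage = standard_montage(),
                        per_channel = NULL) {
  nsamp <- round(diff(window) * fs)
  times <- window[1] + (seq_len(nsamp) - 1) / fs
  n_ch <- nrow(montage)
  base <- if (is.function(signal)) signal(times) else rep(signal, nsamp)
  d <- array(0, dim = c(n_trials, n_ch, nsamp))
  for (tr in seq_len(n_trials)) {
    for (ch in seq_len(n_ch)) {
      d[tr, ch, ] <- if (is.null(per_channel)) {
        base
      } else {
        per_channel(ch)(times)
      }
    }
  }
  betamod:::new_eeg_epochs(d, fs, times, montage)
}

# A beta_timecourse built directly from a band-power array, bypassing the
# decomposition (for oracle tests of the metric layer).
make_timecourse <- function(bp, times, montage) {
  betamod:::normalize_band_power(bp, c(13.5, 25), times, montage)
}

# A fast low-volume scenario for generator tests.
small_scenario <- function(n_trials = 8, ...) {
  sim_scenario(n_trials = n_trials, ...)
}

# Six nearest montage neighbours of `label` by explicit brute force.
brute_force_neighbours <- function(montage, label, n = 6) {
  pm <- as.matrix(montage[, c("x", "y", "z")])
  rownames(pm) <- montage$label
  ref <- pm[label, ]
  d <- apply(pm, 1, function(p) sqrt(sum((p - ref)^2)))
  d <- d[names(d) != label]
  # documented tie rule: distance, then label
  names(d)[order(d, names(d))][seq_len(n)]
}
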