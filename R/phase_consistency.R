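#' Extract envelope windows centered on IU onsets
#'
#' Each retained onset yields a window spanning
#' `[onset - window_s/2, onset + window_s/2)`. Onsets are snapped to the
#' nearest envelope sample; onsets whose window would extend beyond the
#' recording are dropped (their count is reported in the `n_dropped`
#' attribute and a message).
#'
#' @param env An [envelope_signal()].
#' @param onsets Numeric vector of onset times (s).
#' @param window_s Window length in seconds (default 2).
#' @return A numeric matrix with `round(window_s * rate)` rows and one
#'   column per retained onset, with attributes `onsets` (the retained onset
#'   times) and `n_dropped`. Zero retained onsets is an error.
#' @export
extract_windows <- function(env, onsets, window_s = 2.0) {
  if (window_s <= 0) stop("window_s must be positive")
  rate <- env$sample_rate_hz
  n_win <- round(window_s * rate)
  idx <- onset_sample_index(onsets, rate)
  keep <- window_in_bounds(idx, n_win, length(env$values))
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " onset(s) dropped: window exceeds recording bounds")
  }
  if (!any(keep)) stop("no onset yields a full window within the recording")
  idx <- idx[keep]
  start <- idx - n_win %/% 2
  w <- vapply(start, function(s) env$values[s:(s + n_win - 1)],
              numeric(n_win))
  w <- matrix(w, nrow = n_win)
  attr(w, "onsets") <- onsets[keep]
  attr(w, "n_dropped") <- n_dropped
  w
}

# 1-based sample index nearest to each onset time.
onset_sample_index <- function(onsets, rate) as.integer(round(onsets * rate)) + 1L

# TRUE where a window of n_win samples centered at idx fits inside 1..len.
window_in_bounds <- function(idx, n_win, len) {
  start <- idx - n_win %/% 2
  start >= 1L & (start + n_win - 1L) <= len
}

# Frequencies of the analyzed positive-frequency bins: k / window_s for
# k = 1 .. floor((n-1)/2), i.e. DC and (for even n) the Nyquist bin excluded.
window_bin_frequencies <- function(n_win, window_s) {
  k <- seq_len((n_win - 1) %/% 2)
  k / window_s
}

# Unit phase vectors of each window at each analyzed bin.
# Pipeline per window: subtract the window mean, multiply by one full-length
# (symmetric) Hann taper, DFT without padding, keep the phase at each
# positive-frequency bin. Returns a complex matrix (windows x bins) of unit
# magnitude entries; bins where a window has (numerically) zero amplitude
# are NA (phase undefined, the event drops out of that bin).
unit_phase_matrix <- function(windows, window_s, max_freq_hz = Inf) {
  n <- nrow(windows)
  k <- seq_len((n - 1) %/% 2)
  freqs <- k / window_s
  sel <- which(freqs <= max_freq_hz + 1e-12)
  taper <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  x <- sweep(windows, 2, colMeans(windows)) * taper
  z <- stats::mvfft(x)[k[sel] + 1L, , drop = FALSE]
  amp <- Mod(z)
  scale_ref <- max(amp, 1)
  u <- z / amp
  u[amp < 1e-12 * scale_ref] <- NA_complex_
  structure(t(u), frequencies = freqs[sel])
}

#' Phase of one envelope window at each frequency bin
#'
#' Demeans the window, applies a single full-length Hann taper, takes the
#' DFT without padding, and returns the phase angle at each
#' positive-frequency bin (`k / window_s` Hz, DC excluded). Bins where the
#' tapered window has no amplitude (e.g. a constant window) get `NA`.
#'
#' @param window Numeric vector, one envelope segment.
#' @param window_s Window length in seconds.
#' @return A data frame with columns `frequency_hz` and `phase_rad`
#'   (in (-pi, pi]).
#' @export
window_phases <- function(window, window_s) {
  u <- unit_phase_matrix(matrix(window, ncol = 1), window_s)
  data.frame(frequency_hz = attr(u, "frequencies"),
             phase_rad = Arg(u[1, ]))
}

#' Pairwise phase consistency (PPC)
#'
#' The mean, over all distinct pairs of events, of the cosine of their phase
#' difference: (2 / (N (N - 1))) * sum_{j<k} cos(theta_j - theta_k).
#' Computed through the O(N) identity
#' ((sum cos)^2 + (sum sin)^2 - N) / (N (N - 1)). PPC estimates the squared
#' population phase-locking and is unbiased by the number of events.
#'
#' @param angles Numeric vector of phase angles in radians, length >= 2.
#' @return A single value in [-1, 1].
#' @export
ppc <- function(angles) {
  angles <- angles[!is.na(angles)]
  n <- length(angles)
  if (n < 2) stop("PPC requires at least 2 phase angles")
  (sum(cos(angles))^2 + sum(sin(angles))^2 - n) / (n * (n - 1))
}

# PPC per column of a complex unit-phase matrix (events x bins), tolerating
# NA entries; bins with fewer than 2 defined events get NA.
ppc_columns <- function(u) {
  def <- !is.na(u)
  n_b <- colSums(def)
  u0 <- u
  u0[!def] <- 0 + 0i
  s <- colSums(u0)
  out <- (Mod(s)^2 - n_b) / (n_b * (n_b - 1))
  out[n_b < 2] <- NA_real_
  out
}

#' Consistency spectrum for one speaker
#'
#' PPC of the speaker's IU onsets against the envelope, per frequency bin.
#' Following the eligibility rule, a speaker must have strictly more than
#' `min_events` retained onsets (default 5); otherwise an error is thrown
#' and the caller should exclude the speaker.
#'
#' @param env An [envelope_signal()] for the speaker's recording.
#' @param ann An [iu_annotation()].
#' @param speaker Speaker label.
#' @param window_s Analysis window length in seconds (default 2; bin spacing
#'   is `1/window_s` Hz).
#' @param max_freq_hz Highest analyzed frequency (default 10 Hz).
#' @param min_events Minimum onset count; speakers with `<= min_events`
#'   retained onsets are rejected.
#' @return An object of class `consistency_spectrum`: list with
#'   `frequency_hz`, `ppc`, `n_events`, `speaker_id`, `recording_id`,
#'   `window_s`.
#' @export
speaker_spectrum <- function(env, ann, speaker, window_s = 2.0,
                             max_freq_hz = 10, min_events = 5L) {
  onsets <- speaker_onsets(ann, speaker, env$recording_id)
  if (!length(onsets)) stop("speaker '", speaker, "' has no IUs in recording '",
                            env$recording_id, "'")
  w <- extract_windows(env, onsets, window_s)
  if (ncol(w) <= min_events) {
    stop("speaker '", speaker, "' excluded: only ", ncol(w),
         " retained onsets (need > ", min_events, ")")
  }
  u <- unit_phase_matrix(w, window_s, max_freq_hz)
  structure(
    list(frequency_hz = attr(u, "frequencies"),
         ppc = ppc_columns(u),
         n_events = ncol(w),
         speaker_id = as.character(speaker),
         recording_id = env$recording_id,
         window_s = window_s),
    class = "consistency_spectrum"
  )
}

#' @export
print.consistency_spectrum <- function(x, ...) {
  cat(sprintf("<consistency spectrum> speaker=%s n_events=%d bins=%d (%g-%g Hz)\n",
              x$speaker_id, x$n_events, length(x$frequency_hz),
              min(x$frequency_hz), max(x$frequency_hz)))
  invisible(x)
}

#' Group-average consistency spectrum with bootstrap confidence band
#'
#' Unweighted mean of per-speaker spectra per frequency bin, with a
#' percentile bootstrap confidence interval obtained by resampling speakers
#' with replacement.
#'
#' @param spectra List of `consistency_spectrum` objects on identical
#'   frequency grids.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `iu_group_spectrum`: list with
#'   `frequency_hz`, `mean_ppc`, `ci_low`, `ci_high`, `n_speakers`.
#' @export
group_spectrum <- function(spectra, n_boot = 1000, conf = 0.95,
                           seed = NULL) {
  if (!length(spectra)) stop("no speaker spectra supplied")
  freqs <- spectra[[1]]$frequency_hz
  for (i in seq_along(spectra)) {
    if (!isTRUE(all.equal(spectra[[i]]$frequency_hz, freqs))) {
      stop("spectrum ", i, " (speaker '", spectra[[i]]$speaker_id,
           "') is on a different frequency grid")
    }
  }
  m <- do.call(rbind, lapply(spectra, `[[`, "ppc"))
  mean_ppc <- colMeans(m, na.rm = TRUE)
  if (!is.null(seed)) set.seed(seed)
  ns <- nrow(m)
  alpha <- (1 - conf) / 2
  boot <- matrix(NA_real_, n_boot, ncol(m))
  for (b in seq_len(n_boot)) {
    boot[b, ] <- colMeans(m[sample.int(ns, ns, replace = TRUE), ,
                            drop = FALSE], na.rm = TRUE)
  }
  ci <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE, names = FALSE)
  structure(
    list(frequency_hz = freqs, mean_ppc = mean_ppc,
         ci_low = pmin(ci[1, ], mean_ppc), ci_high = pmax(ci[2, ], mean_ppc),
         n_speakers = ns),
    class = "iu_group_spectrum"
  )
}

#' @export
print.iu_group_spectrum <- function(x, ...) {
  pk <- which.max(x$mean_ppc)
  cat(sprintf("<group spectrum> %d speakers, %d bins; peak PPC %.4f at %g Hz\n",
              x$n_speakers, length(x$frequency_hz), x$mean_ppc[pk],
              x$frequency_hz[pk]))
  invisible(x)
}
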