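#' Cochlear-spaced filterbank edges
#'
#' Band cut-offs equidistant on the human cochlear map: frequencies are
#' mapped to cochlear position with the Greenwood function
#' f(x) = 165.4 (10^(0.06 x) - 1) (x in mm from the apex), edges are placed
#' at uniform steps of x between the positions of `f_lo_hz` and `f_hi_hz`,
#' and mapped back to Hz.
#'
#' @param n_bands Number of bands (default 10).
#' @param f_lo_hz,f_hi_hz Lower and upper frequency limits in Hz
#'   (defaults 100 and 8000).
#' @return A list of class `filterbank_spec` with fields `n_bands`,
#'   `f_lo_hz`, `f_hi_hz` and `edges_hz` (length `n_bands + 1`, strictly
#'   increasing).
#' @export
cochlear_band_edges <- function(n_bands = 10, f_lo_hz = 100,
                                f_hi_hz = 8000) {
  if (n_bands < 1) stop("n_bands must be >= 1")
  if (!(0 < f_lo_hz && f_lo_hz < f_hi_hz)) {
    stop("need 0 < f_lo_hz < f_hi_hz")
  }
  x <- seq(greenwood_position(f_lo_hz), greenwood_position(f_hi_hz),
           length.out = n_bands + 1)
  edges <- greenwood_frequency(x)
  edges[1] <- f_lo_hz
  edges[n_bands + 1] <- f_hi_hz
  structure(
    list(n_bands = as.integer(n_bands), f_lo_hz = f_lo_hz,
         f_hi_hz = f_hi_hz, edges_hz = edges),
    class = "filterbank_spec"
  )
}

# Greenwood map for the human cochlea: position (mm) <-> frequency (Hz).
greenwood_position <- function(f_hz) log10(f_hz / 165.4 + 1) / 0.06
greenwood_frequency <- function(x_mm) 165.4 * (10^(0.06 * x_mm) - 1)

# Zero-phase Butterworth filtering applied in the frequency domain: the
# signal's spectrum is multiplied by the squared magnitude response of an
# order-`order` Butterworth filter (the response a forward-backward
# application has). Direct transfer-function filtering is numerically
# unusable at the very low normalized cutoffs needed here (e.g. a 40 Hz
# anti-alias cutoff on 16 kHz audio); the spectral form is stable at any
# cutoff and exactly zero-phase.
fft_butterworth <- function(x, fs, order, f_lo = NULL, f_hi = NULL) {
  n <- length(x)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)              # fold to [0, fs/2]
  if (is.null(f_lo)) {              # low-pass
    h <- 1 / (1 + (f / f_hi)^(2 * order))
  } else {                          # band-pass (analog prototype transform)
    f0sq <- f_lo * f_hi
    bw <- f_hi - f_lo
    fg <- pmax(f, 1e-12)
    h <- 1 / (1 + ((fg^2 - f0sq) / (fg * bw))^(2 * order))
    h[f == 0] <- 0
  }
  Re(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

# Analytic signal via the frequency-domain construction: zero the negative
# frequencies, double the positive ones.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Compute the wideband speech envelope
#'
#' The waveform is band-pass filtered into the bands of `spec` (4th-order
#' Butterworth response, applied as a zero-phase spectral filter), the
#' amplitude envelope of each band is taken as the magnitude of the analytic
#' (Hilbert) signal, and the narrowband envelopes are averaged into the
#' wideband envelope. The result is low-pass filtered below half the
#' envelope rate (8th-order Butterworth response at 0.4 x `env_rate_hz`,
#' zero phase), resampled to `env_rate_hz`, and optionally scaled to a
#' maximum of 1.
#'
#' @param w A [waveform()].
#' @param spec A [cochlear_band_edges()] filterbank; all edges must lie
#'   below the waveform's Nyquist frequency.
#' @param env_rate_hz Envelope sample rate in Hz (default 100, giving 0.5 Hz
#'   frequency bins for 2-s analysis windows).
#' @param normalization `"unit_max"` (default) or `"none"`. A silent input
#'   with `"unit_max"` returns all zeros with a warning.
#' @return An [envelope_signal()] with
#'   `round(duration * env_rate_hz)` samples.
#' @export
compute_envelope <- function(w, spec = cochlear_band_edges(),
                             env_rate_hz = 100,
                             normalization = c("unit_max", "none")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(w, "waveform"))
  if (!length(w$samples)) stop("waveform is empty")
  fs <- w$sample_rate_hz
  nyq <- fs / 2
  if (spec$f_hi_hz > nyq) {
    stop(sprintf("filterbank upper edge (%g Hz) exceeds Nyquist (%g Hz)",
                 spec$f_hi_hz, nyq))
  }
  if (env_rate_hz > fs) stop("env_rate_hz cannot exceed the waveform rate")

  x <- w$samples
  acc <- numeric(length(x))
  for (b in seq_len(spec$n_bands)) {
    xb <- fft_butterworth(x, fs, order = 4, f_lo = spec$edges_hz[b],
                          f_hi = min(spec$edges_hz[b + 1], 0.999 * nyq))
    acc <- acc + Mod(analytic_signal(xb))
  }
  wide <- acc / spec$n_bands

  # anti-alias before decimation, then sample onto the envelope grid
  wide <- fft_butterworth(wide, fs, order = 8, f_hi = 0.4 * env_rate_hz)
  wide[wide < 0] <- 0

  n_env <- round(length(x) / fs * env_rate_hz)
  t_env <- (seq_len(n_env) - 1) / env_rate_hz
  t_orig <- (seq_along(x) - 1) / fs
  v <- stats::approx(t_orig, wide, xout = t_env, rule = 2)$y

  if (normalization == "unit_max") {
    m <- max(v)
    if (m > 0) {
      v <- v / m
    } else {
      warning("silent input: unit_max normalization skipped, envelope is 0")
    }
  }
  envelope_signal(v, env_rate_hz, w$recording_id, normalization)
}
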