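#' Construct a waveform object
#'
#' A waveform holds raw mono audio samples together with their sample rate.
#' It is the input to [compute_envelope()].
#'
#' @param samples Numeric vector of pressure samples (arbitrary units).
#' @param sample_rate_hz Positive sampling rate in Hz.
#' @param recording_id Label identifying the recording.
#'
#' @return An object of class `waveform` with fields `samples`,
#'   `sample_rate_hz` and `recording_id`.
#' @export
waveform <- function(samples, sample_rate_hz, recording_id = "rec") {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("waveform samples must all be finite")
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      sample_rate_hz <= 0) {
    stop("sample_rate_hz must be a single positive number")
  }
  structure(
    list(samples = samples, sample_rate_hz = as.numeric(sample_rate_hz),
         recording_id = as.character(recording_id)),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform '%s'> %d samples @ %g Hz (%.2f s)\n",
              x$recording_id, length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz))
  invisible(x)
}

#' Construct an envelope signal
#'
#' The wideband amplitude envelope of a recording: a nonnegative series at a
#' reduced sample rate, optionally normalized so its maximum equals 1.
#'
#' @param values Nonnegative numeric vector of envelope values.
#' @param sample_rate_hz Envelope sample rate in Hz.
#' @param recording_id Label identifying the recording.
#' @param normalization Either `"unit_max"` (maximum scaled to 1) or
#'   `"none"`.
#'
#' @return An object of class `envelope_signal`.
#' @export
envelope_signal <- function(values, sample_rate_hz, recording_id = "rec",
                            normalization = c("unit_max", "none")) {
  normalization <- match.arg(normalization)
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("envelope values must be finite")
  if (any(values < 0)) stop("envelope values must be nonnegative")
  structure(
    list(values = values, sample_rate_hz = as.numeric(sample_rate_hz),
         recording_id = as.character(recording_id),
         normalization = normalization),
    class = "envelope_signal"
  )
}

#' @export
print.envelope_signal <- function(x, ...) {
  cat(sprintf("<envelope '%s'> %d values @ %g Hz (%.2f s), normalization=%s\n",
              x$recording_id, length(x$values), x$sample_rate_hz,
              length(x$values) / x$sample_rate_hz, x$normalization))
  invisible(x)
}

#' Times (s) of the envelope samples
#' @param env An `envelope_signal`.
#' @return Numeric vector of sample times, starting at 0.
#' @export
envelope_times <- function(env) {
  (seq_along(env$values) - 1) / env$sample_rate_hz
}

#' Construct an IU annotation table
#'
#' An annotation is a data frame of Intonation Unit intervals: one row per
#' IU with its onset, offset, and the speaker who produced it. Records are
#' kept sorted by onset within each recording.
#'
#' @param onset_s Numeric vector of IU onset times (s, from recording start).
#' @param offset_s Numeric vector of IU offset times (s).
#' @param speaker_id Character vector of speaker labels.
#' @param recording_id Recording label, recycled to the number of records.
#'
#' @return A `data.frame` of class `iu_annotation` with columns
#'   `recording_id`, `speaker_id`, `onset_s`, `offset_s`, sorted by
#'   recording and onset.
#' @export
iu_annotation <- function(onset_s, offset_s, speaker_id,
                          recording_id = "rec") {
  ann <- data.frame(
    recording_id = as.character(rep_len(recording_id, length(onset_s))),
    speaker_id = as.character(rep_len(speaker_id, length(onset_s))),
    onset_s = as.numeric(onset_s),
    offset_s = as.numeric(offset_s),
    stringsAsFactors = FALSE
  )
  validate_annotation(ann)
}

#' Validate and normalize an annotation table
#'
#' Checks the IU interval invariants (finite nonnegative times, onset before
#' offset) and sorts records by onset within recording. A table that arrives
#' unsorted is repaired with a message; an onset at or after its offset is a
#' hard error naming the offending rows.
#'
#' @param ann Data frame with columns `recording_id`, `speaker_id`,
#'   `onset_s`, `offset_s`.
#' @return The validated table with class `iu_annotation`.
#' @export
validate_annotation <- function(ann) {
  need <- c("recording_id", "speaker_id", "onset_s", "offset_s")
  miss <- setdiff(need, names(ann))
  if (length(miss)) {
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(!is.finite(ann$onset_s)) || any(!is.finite(ann$offset_s))) {
    stop("annotation times must be finite numbers")
  }
  if (any(ann$onset_s < 0)) stop("annotation onsets must be nonnegative")
  bad <- which(ann$onset_s >= ann$offset_s)
  if (length(bad)) {
    stop("annotation record(s) with onset >= offset at row(s): ",
         paste(bad, collapse = ", "))
  }
  ord <- order(ann$recording_id, ann$onset_s)
  if (is.unsorted(ord)) {
    message("annotation records were unsorted; sorted by recording and onset")
    ann <- ann[ord, , drop = FALSE]
    rownames(ann) <- NULL
  }
  class(ann) <- unique(c("iu_annotation", class(ann)))
  ann
}

#' Onset times for one speaker in one recording
#' @param ann An `iu_annotation`.
#' @param speaker Speaker label.
#' @param recording Recording label; `NULL` means all recordings.
#' @return Numeric vector of onsets (s).
#' @export
speaker_onsets <- function(ann, speaker, recording = NULL) {
  keep <- ann$speaker_id == speaker
  if (!is.null(recording)) keep <- keep & ann$recording_id == recording
  ann$onset_s[keep]
}
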