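#' Per-speaker and group consistency spectra for a set of recordings
#'
#' Convenience wrapper running [speaker_spectrum()] for every eligible
#' speaker (strictly more than `min_events` retained IU onsets) and
#' averaging with [group_spectrum()]. Ineligible speakers are skipped with
#' a message.
#'
#' @inheritParams permutation_test
#' @param n_boot,conf Bootstrap settings for the group confidence band.
#' @return A list with `speaker_spectra` (named list of
#'   `consistency_spectrum`) and `group` (an `iu_group_spectrum`).
#' @export
consistency_analysis <- function(envs, ann, window_s = 2.0,
                                 max_freq_hz = 10, min_events = 5L,
                                 n_boot = 1000, conf = 0.95, seed = NULL) {
  if (inherits(envs, "envelope_signal")) envs <- list(envs)
  names(envs) <- vapply(envs, `[[`, character(1), "recording_id")
  pairs <- unique(ann[ann$recording_id %in% names(envs),
                      c("recording_id", "speaker_id")])
  spectra <- list()
  for (i in seq_len(nrow(pairs))) {
    key <- paste0(pairs$recording_id[i], "/", pairs$speaker_id[i])
    sp <- tryCatch(
      speaker_spectrum(envs[[pairs$recording_id[i]]], ann,
                       pairs$speaker_id[i], window_s, max_freq_hz,
                       min_events),
      error = function(e) {
        message("skipping ", key, ": ", conditionMessage(e))
        NULL
      })
    if (!is.null(sp)) spectra[[key]] <- sp
  }
  if (!length(spectra)) stop("no eligible speaker")
  list(speaker_spectra = spectra,
       group = group_spectrum(spectra, n_boot = n_boot, conf = conf,
                              seed = seed))
}
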