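#' IU durations
#'
#' @param ann An [iu_annotation()].
#' @return Numeric vector of durations (offset - onset, s), one per record,
#'   pooled across speakers.
#' @export
iu_durations <- function(ann) {
  ann$offset_s - ann$onset_s
}

#' Duration distribution summary
#'
#' Histogram of IU durations at fixed-width bins (50 ms by default),
#' normalized to probabilities, together with the median and its percentile
#' bootstrap confidence interval (resampling individual IUs).
#'
#' @param durations Numeric vector of IU durations (s), length >= 2.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param bin_s Histogram bin width in seconds (default 0.05).
#' @param conf Confidence level for the median CI (default 0.95).
#' @param seed Optional integer seed.
#' @return An object of class `duration_stats`: list with `durations_s`,
#'   `median_s`, `ci_low_s`, `ci_high_s`, `bin_edges_s`, `probability`.
#' @export
duration_stats <- function(durations, n_boot = 1000, bin_s = 0.05,
                           conf = 0.95, seed = NULL) {
  durations <- as.numeric(durations)
  if (length(durations) < 2) stop("need at least 2 durations")
  if (any(durations <= 0)) stop("durations must be positive")
  if (!is.null(seed)) set.seed(seed)
  med <- stats::median(durations)
  n <- length(durations)
  boot <- vapply(seq_len(n_boot), function(b) {
    stats::median(durations[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
  edges <- seq(0, (floor(max(durations) / bin_s) + 1) * bin_s, by = bin_s)
  counts <- graphics::hist(durations, breaks = edges, plot = FALSE)$counts
  structure(
    list(durations_s = durations, median_s = med,
         ci_low_s = min(ci[1], med), ci_high_s = max(ci[2], med),
         bin_edges_s = edges, probability = counts / sum(counts)),
    class = "duration_stats"
  )
}

#' @export
print.duration_stats <- function(x, ...) {
  cat(sprintf("<duration stats> n=%d, median %.3f s (95%% CI %.3f-%.3f s)\n",
              length(x$durations_s), x$median_s, x$ci_low_s, x$ci_high_s))
  invisible(x)
}

#' Keep only IUs that follow a short inter-IU interval
#'
#' The robustness filter: retains an IU only when the silent gap since the
#' immediately preceding IU in the same recording (regardless of speaker, by
#' default) is below `max_gap_s`. Gaps are computed on the original
#' sequence, so the filter is a single pass and reapplying it to its own
#' output changes nothing further only if predecessors survived; by
#' contract, gaps always refer to the unfiltered sequence. The first IU of a
#' recording has no predecessor and is excluded.
#'
#' @param ann An [iu_annotation()] sorted by onset.
#' @param max_gap_s Maximum inter-IU interval in seconds (default 1).
#' @param same_speaker_only If `TRUE`, the preceding IU must be by the same
#'   speaker (default `FALSE`: turn-taking gaps count too).
#' @return The filtered [iu_annotation()], with attribute
#'   `retained_fraction` (share of the original records kept).
#' @export
filter_recent_iu <- function(ann, max_gap_s = 1.0,
                             same_speaker_only = FALSE) {
  keep <- logical(nrow(ann))
  for (r in unique(ann$recording_id)) {
    sel <- which(ann$recording_id == r)
    if (length(sel) < 2) next
    if (same_speaker_only) {
      for (sp in unique(ann$speaker_id[sel])) {
        s2 <- sel[ann$speaker_id[sel] == sp]
        if (length(s2) < 2) next
        gaps <- ann$onset_s[s2[-1]] - ann$offset_s[s2[-length(s2)]]
        keep[s2[-1]] <- gaps < max_gap_s
      }
    } else {
      gaps <- ann$onset_s[sel[-1]] - ann$offset_s[sel[-length(sel)]]
      keep[sel[-1]] <- gaps < max_gap_s
    }
  }
  out <- ann[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(ann)
  attr(out, "retained_fraction") <- mean(keep)
  out
}
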