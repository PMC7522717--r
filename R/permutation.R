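#' Detect envelope troughs
#'
#' Local minima of the (unit-normalized) envelope whose prominence — depth
#' relative to the surrounding envelope, measured to the lower of the two
#' key saddles — is at least `min_magnitude`, thinned greedily (deepest
#' first) so that no two retained troughs are closer than
#' `min_separation_s`. Troughs are where syllable boundaries live, so the
#' defaults (magnitude 0.01 on a 0-1 scale, separation 200 ms) reflect
#' average syllable spacing.
#'
#' @param env An [envelope_signal()], expected on a 0-1 scale
#'   (`unit_max` normalization).
#' @param min_magnitude Minimum trough prominence (default 0.01).
#' @param min_separation_s Minimum time between retained troughs
#'   (default 0.2 s).
#' @return An object of class `trough_set`: list with `times_s` (increasing),
#'   `indices` (1-based envelope sample indices), `recording_id`, `params`.
#'   A constant envelope yields an empty set.
#' @export
detect_troughs <- function(env, min_magnitude = 0.01,
                           min_separation_s = 0.2) {
  x <- env$values
  n <- length(x)
  d <- diff(x)
  # strict sign change from falling to rising
  cand <- which(d[-(n - 1)] < 0 & d[-1] > 0) + 1L
  if (!length(cand)) {
    return(empty_trough_set(env, min_magnitude, min_separation_s))
  }
  prom <- minima_prominence(x, cand)
  keep <- prom >= min_magnitude - 1e-12
  cand <- cand[keep]
  prom <- prom[keep]
  if (!length(cand)) {
    return(empty_trough_set(env, min_magnitude, min_separation_s))
  }
  # greedy deepest-first thinning under the separation constraint
  min_gap <- min_separation_s * env$sample_rate_hz - 1e-6
  ord <- order(-prom, cand)
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(accepted - cand[i]) >= min_gap)) {
      accepted <- c(accepted, cand[i])
    }
  }
  accepted <- sort(accepted)
  structure(
    list(times_s = (accepted - 1) / env$sample_rate_hz,
         indices = accepted,
         recording_id = env$recording_id,
         params = list(min_magnitude = min_magnitude,
                       min_separation_s = min_separation_s)),
    class = "trough_set"
  )
}

empty_trough_set <- function(env, min_magnitude, min_separation_s) {
  structure(
    list(times_s = numeric(0), indices = integer(0),
         recording_id = env$recording_id,
         params = list(min_magnitude = min_magnitude,
                       min_separation_s = min_separation_s)),
    class = "trough_set"
  )
}

#' @export
print.trough_set <- function(x, ...) {
  cat(sprintf("<trough set '%s'> %d troughs (magnitude >= %g, separation >= %g s)\n",
              x$recording_id, length(x$times_s), x$params$min_magnitude,
              x$params$min_separation_s))
  invisible(x)
}

# Prominence of each local minimum: min(left reference, right reference)
# minus the minimum's value, where each side's reference is the highest
# envelope value between the minimum and the nearest strictly deeper
# minimum (or the signal edge). Works on the reduced sequence of
# alternating extrema for speed.
minima_prominence <- function(x, mins) {
  k <- length(mins)
  v <- x[mins]
  # segment maxima between consecutive minima, plus the two edge segments
  bounds <- c(1L, mins, length(x))
  seg_max <- vapply(seq_len(k + 1), function(j) {
    max(x[bounds[j]:bounds[j + 1]])
  }, numeric(1))
  prom <- numeric(k)
  for (i in seq_len(k)) {
    ref_l <- seg_max[i]          # segment just left of minimum i
    j <- i - 1L
    while (j >= 1L && v[j] >= v[i]) {
      ref_l <- max(ref_l, seg_max[j])
      j <- j - 1L
    }
    ref_r <- seg_max[i + 1]      # segment just right of minimum i
    j <- i + 1L
    while (j <= k && v[j] >= v[i]) {
      ref_r <- max(ref_r, seg_max[j + 1])
      j <- j + 1L
    }
    prom[i] <- min(ref_l, ref_r) - v[i]
  }
  prom
}

#' Draw surrogate IU onsets on envelope troughs
#'
#' Samples `n_onsets` trough times uniformly without replacement, preserving
#' the association of onsets with envelope troughs that real IU onsets have
#' (every IU onset is also a syllable boundary).
#'
#' @param troughs A [detect_troughs()] result.
#' @param n_onsets Number of onsets to draw; must not exceed the number of
#'   troughs.
#' @param seed Optional integer seed.
#' @return Sorted numeric vector of onset times (s).
#' @export
surrogate_onsets <- function(troughs, n_onsets, seed = NULL) {
  k <- length(troughs$times_s)
  if (n_onsets > k) {
    stop("cannot draw ", n_onsets, " surrogate onsets from ", k,
         " troughs (short by ", n_onsets - k, ")")
  }
  if (!is.null(seed)) set.seed(seed)
  sort(troughs$times_s[sample.int(k, n_onsets)])
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up procedure: sort p-values ascending, find the largest k with
#' p_(k) <= k q / m, reject all hypotheses with p <= p_(k).
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param q Target false discovery rate.
#' @return Logical rejection mask aligned with `p_values` (empty input gives
#'   an empty mask). `NA` p-values are never rejected.
#' @export
bh_fdr <- function(p_values, q) {
  if (!length(p_values)) return(logical(0))
  adj <- stats::p.adjust(p_values, method = "BH")
  out <- !is.na(adj) & adj <= q
  out
}

#' Trough-constrained permutation test of the group consistency spectrum
#'
#' Builds the randomization distribution of the speaker-averaged PPC
#' spectrum by repeatedly replacing every speaker's IU onsets with the same
#' number of onsets drawn uniformly from the envelope troughs of the same
#' recording, and rerunning the spectrum pipeline. The per-bin p-value is
#' the exceedance proportion `(r + 1) / (n_perm + 1)`, where `r` counts
#' surrogate group means at least as large as the observed one; significance
#' is assessed with Benjamini-Hochberg FDR control across the analyzed bins.
#'
#' Speakers whose recording lacks enough eligible troughs for their onset
#' count are excluded from both the observed and the surrogate spectra, so
#' the observed statistic and its null are computed on identical data.
#'
#' @param envs An [envelope_signal()] or a list of them (one per recording;
#'   names or `recording_id` fields must match the annotation).
#' @param ann An [iu_annotation()] covering all speakers.
#' @param window_s Analysis window length in seconds (default 2).
#' @param n_perm Number of surrogate spectra (default 1000).
#' @param fdr_q FDR level across frequency bins (default 0.01).
#' @param max_freq_hz Highest analyzed frequency (default 10 Hz).
#' @param min_magnitude,min_separation_s Trough parameters, see
#'   [detect_troughs()].
#' @param min_events Speakers with `<= min_events` retained onsets are
#'   excluded (default 5).
#' @param seed Optional integer seed for the surrogate draws.
#' @return An object of class `permutation_result`: list with
#'   `frequency_hz`, `observed_mean_ppc`, `surrogate_means`
#'   (`n_perm` x bins matrix), `p_value`, `significant`, `fdr_threshold`,
#'   `n_perm`, `n_speakers`, `excluded_speakers`, `seed`.
#' @export
permutation_test <- function(envs, ann, window_s = 2.0, n_perm = 1000,
                             fdr_q = 0.01, max_freq_hz = 10,
                             min_magnitude = 0.01, min_separation_s = 0.2,
                             min_events = 5L, seed = NULL) {
  if (inherits(envs, "envelope_signal")) envs <- list(envs)
  names(envs) <- vapply(envs, `[[`, character(1), "recording_id")

  recs <- intersect(unique(ann$recording_id), names(envs))
  if (!length(recs)) stop("no recording in the annotation has an envelope")

  # per recording: trough phase matrix restricted to troughs whose window
  # fits the recording, computed once and reused by every surrogate
  trough_u <- list()
  freqs <- NULL
  for (r in recs) {
    env <- envs[[r]]
    n_win <- round(window_s * env$sample_rate_hz)
    tr <- detect_troughs(env, min_magnitude, min_separation_s)
    ok <- window_in_bounds(tr$indices, n_win, length(env$values))
    idx <- tr$indices[ok]
    if (length(idx)) {
      w <- vapply(idx - n_win %/% 2,
                  function(s) env$values[s:(s + n_win - 1)],
                  numeric(n_win))
      u <- unit_phase_matrix(matrix(w, nrow = n_win), window_s, max_freq_hz)
      trough_u[[r]] <- u
      freqs <- attr(u, "frequencies")
    } else {
      trough_u[[r]] <- NULL
    }
  }
  if (is.null(freqs)) stop("no recording has any eligible trough")

  # observed per-speaker phase matrices; eligibility filtering
  pairs <- unique(ann[ann$recording_id %in% recs,
                      c("recording_id", "speaker_id")])
  obs_u <- list()
  excluded <- character(0)
  for (i in seq_len(nrow(pairs))) {
    r <- pairs$recording_id[i]
    sp <- pairs$speaker_id[i]
    env <- envs[[r]]
    n_win <- round(window_s * env$sample_rate_hz)
    idx <- onset_sample_index(speaker_onsets(ann, sp, r),
                              env$sample_rate_hz)
    idx <- idx[window_in_bounds(idx, n_win, length(env$values))]
    n_tr <- if (is.null(trough_u[[r]])) 0L else nrow(trough_u[[r]])
    if (length(idx) <= min_events || n_tr < length(idx)) {
      excluded <- c(excluded, paste0(r, "/", sp))
      next
    }
    w <- vapply(idx - n_win %/% 2,
                function(s) env$values[s:(s + n_win - 1)], numeric(n_win))
    obs_u[[paste0(r, "/", sp)]] <- list(
      rec = r,
      u = unit_phase_matrix(matrix(w, nrow = n_win), window_s, max_freq_hz))
  }
  if (length(excluded)) {
    message("excluded speaker(s): ", paste(excluded, collapse = ", "))
  }
  if (!length(obs_u)) stop("no eligible speaker for the permutation test")

  obs_ppc <- do.call(rbind, lapply(obs_u, function(s) ppc_columns(s$u)))
  observed <- colMeans(obs_ppc, na.rm = TRUE)

  if (!is.null(seed)) set.seed(seed)
  n_bins <- length(freqs)
  surr <- matrix(NA_real_, n_perm, n_bins)
  for (b in seq_len(n_perm)) {
    acc <- matrix(NA_real_, length(obs_u), n_bins)
    for (i in seq_along(obs_u)) {
      tu <- trough_u[[obs_u[[i]]$rec]]
      pick <- sample.int(nrow(tu), nrow(obs_u[[i]]$u))
      acc[i, ] <- ppc_columns(tu[pick, , drop = FALSE])
    }
    surr[b, ] <- colMeans(acc, na.rm = TRUE)
  }

  r_exceed <- colSums(sweep(surr, 2, observed, `>=`), na.rm = TRUE)
  p <- (r_exceed + 1) / (n_perm + 1)
  p[is.na(observed)] <- NA_real_
  structure(
    list(frequency_hz = freqs, observed_mean_ppc = observed,
         surrogate_means = surr, p_value = p,
         significant = bh_fdr(p, fdr_q), fdr_threshold = fdr_q,
         n_perm = as.integer(n_perm), n_speakers = length(obs_u),
         excluded_speakers = excluded, seed = seed),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  sig <- x$frequency_hz[x$significant]
  cat(sprintf("<permutation result> %d speakers, %d surrogates, %d bins\n",
              x$n_speakers, x$n_perm, length(x$frequency_hz)))
  if (length(sig)) {
    cat("  significant bins (FDR ", x$fdr_threshold, "): ",
        paste(sig, collapse = ", "), " Hz\n", sep = "")
  } else {
    cat("  no significant bins at FDR ", x$fdr_threshold, "\n", sep = "")
  }
  invisible(x)
}
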