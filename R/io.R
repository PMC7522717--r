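#' Read a mono waveform from a PCM WAV file
#'
#' Parses RIFF/WAVE files with 8/16/24/32-bit integer PCM or 32/64-bit IEEE
#' float samples. Multi-channel files are down-mixed to mono by averaging
#' channels, with a warning. Samples are returned on a [-1, 1] scale.
#'
#' @param path Path to a `.wav` file.
#' @param recording_id Label for the returned waveform; defaults to the file
#'   name without extension.
#' @return A [waveform()].
#' @export
read_waveform <- function(path, recording_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(recording_id)) {
    recording_id <- sub("\\.[^.]*$", "", basename(path))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(body[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(body[3:4], "integer", 1, 2, endian = "little"),
        rate = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(body[15:16], "integer", 1, 2, endian = "little")
      )
      if (fmt$format == -2L) {  # WAVE_FORMAT_EXTENSIBLE: subformat at byte 25
        fmt$format <- readBin(body[25:26], "integer", 1, 2, endian = "little")
      }
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV (missing fmt or data chunk): ", path)
  }

  bytes <- fmt$bits %/% 8
  n <- length(data_raw) %/% bytes
  x <- switch(
    as.character(fmt$format),
    "1" = {  # integer PCM
      if (fmt$bits == 8) {
        (as.numeric(readBin(data_raw, "integer", n, 1, signed = FALSE)) -
           128) / 128
      } else if (fmt$bits == 16) {
        readBin(data_raw, "integer", n, 2, signed = TRUE,
                endian = "little") / 2^15
      } else if (fmt$bits == 24) {
        m <- matrix(as.integer(data_raw[seq_len(n * 3)]), nrow = 3)
        v <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536
        v <- ifelse(v >= 2^23, v - 2^24, v)
        v / 2^23
      } else if (fmt$bits == 32) {
        readBin(data_raw, "integer", n, 4, endian = "little") / 2^31
      } else {
        stop("unsupported PCM bit depth: ", fmt$bits)
      }
    },
    "3" = readBin(data_raw, "double", n, bytes, endian = "little"),
    stop("unsupported WAV encoding (format tag ", fmt$format,
         "); only integer PCM and IEEE float are supported")
  )

  if (fmt$channels > 1L) {
    warning("down-mixing ", fmt$channels, " channels to mono by averaging")
    nf <- length(x) %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(nf * fmt$channels)], nrow = fmt$channels))
  }
  waveform(x, fmt$rate, recording_id)
}

#' Write a waveform to a PCM WAV file
#'
#' @param w A [waveform()]; samples are clipped to [-1, 1].
#' @param path Output path.
#' @param bit_depth Bits per sample: 16 (default) or 24 integer PCM, or 32
#'   for IEEE float.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, bit_depth = 16) {
  stopifnot(inherits(w, "waveform"), bit_depth %in% c(16, 24, 32))
  x <- pmin(1, pmax(-1, w$samples))
  bytes <- bit_depth %/% 8
  fmt_tag <- if (bit_depth == 32) 3L else 1L
  n_data <- length(x) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n_data), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_tag, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  rate <- as.integer(round(w$sample_rate_hz))
  writeBin(rate, con, 4, endian = "little")
  writeBin(as.integer(rate * bytes), con, 4, endian = "little")
  writeBin(as.integer(bytes), con, 2, endian = "little")
  writeBin(as.integer(bit_depth), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_data), con, 4, endian = "little")
  if (bit_depth == 16) {
    q <- as.integer(pmin(2^15 - 1, round(x * 2^15)))
    writeBin(q, con, 2, endian = "little")
  } else if (bit_depth == 24) {
    q <- pmin(2^23 - 1, round(x * 2^23))
    q <- ifelse(q < 0, q + 2^24, q)
    m <- rbind(q %% 256, (q %/% 256) %% 256, q %/% 65536)
    writeBin(as.raw(as.integer(m)), con)
  } else {
    writeBin(x, con, 4, endian = "little")
  }
  invisible(path)
}

#' Read IU annotations from CSV or Praat TextGrid
#'
#' The CSV dialect expects a header with columns `onset_s`, `offset_s`,
#' `speaker_id` (and optionally `recording_id`); times are seconds with a
#' decimal point, measured from the recording start. The TextGrid dialect
#' reads every interval tier, treating each tier as one speaker (the tier
#' name) and every non-empty interval as one IU.
#'
#' @param path Path to the annotation file.
#' @param dialect `"csv"` or `"textgrid"`; guessed from the file extension
#'   by default.
#' @param recording_id Recording label used when the file does not carry one.
#' @return An [iu_annotation()] table sorted by onset.
#' @export
read_annotations <- function(path, dialect = NULL, recording_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.textgrid$", tolower(path))) "textgrid" else "csv"
  }
  dialect <- match.arg(dialect, c("csv", "textgrid"))
  if (is.null(recording_id)) {
    recording_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          comment.char = "#")
    need <- c("onset_s", "offset_s", "speaker_id")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("annotation CSV lacks column(s): ", paste(miss, collapse = ", "))
    }
    if (is.null(df$recording_id)) df$recording_id <- recording_id
    iu_annotation(df$onset_s, df$offset_s, df$speaker_id, df$recording_id)
  } else {
    tg <- parse_textgrid(readLines(path, warn = FALSE))
    if (nrow(tg) == 0) stop("TextGrid has no labeled intervals: ", path)
    iu_annotation(tg$onset_s, tg$offset_s, tg$speaker_id, recording_id)
  }
}

# Minimal parser for Praat's long TextGrid text format: interval tiers only,
# empty-text intervals discarded.
parse_textgrid <- function(lines) {
  num <- function(l) as.numeric(sub(".*=\\s*", "", l))
  str <- function(l) {
    m <- regmatches(l, regexpr('"[^"]*"', l))
    if (length(m)) substr(m, 2, nchar(m) - 1) else ""
  }
  out <- list()
  tier_name <- NULL
  is_interval_tier <- FALSE
  xmin <- NA_real_
  for (l in lines) {
    t <- trimws(l)
    if (grepl('^class\\s*=', t)) {
      is_interval_tier <- identical(str(t), "IntervalTier")
    } else if (grepl('^name\\s*=', t)) {
      tier_name <- str(t)
    } else if (grepl('^xmin\\s*=', t)) {
      xmin <- num(t)
    } else if (grepl('^xmax\\s*=', t)) {
      # paired with the preceding xmin inside an interval block
      xmax <- num(t)
    } else if (grepl('^text\\s*=', t) && is_interval_tier) {
      lab <- str(t)
      if (nzchar(trimws(lab))) {
        out[[length(out) + 1L]] <- data.frame(
          onset_s = xmin, offset_s = xmax, speaker_id = tier_name,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(onset_s = numeric(), offset_s = numeric(),
                      speaker_id = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Write IU annotations to CSV
#'
#' Full float precision, so that [read_annotations()] round-trips exactly.
#'
#' @param ann An [iu_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  df <- data.frame(
    recording_id = ann$recording_id,
    speaker_id = ann$speaker_id,
    onset_s = sprintf("%.17g", ann$onset_s),
    offset_s = sprintf("%.17g", ann$offset_s),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a consistency spectrum, group spectrum or permutation result
#'
#' Per-speaker spectra get columns `frequency_hz`, `ppc`; group spectra add
#' `ci_low`, `ci_high`; permutation results add `p_value` and a 0/1
#' `significant` mask. Values are written at full float precision so a
#' read-back is lossless.
#'
#' @param x A `consistency_spectrum`, `iu_group_spectrum` or
#'   `permutation_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  fg <- function(v) sprintf("%.17g", v)
  if (inherits(x, "consistency_spectrum")) {
    df <- data.frame(frequency_hz = fg(x$frequency_hz), ppc = fg(x$ppc))
  } else if (inherits(x, "iu_group_spectrum")) {
    df <- data.frame(frequency_hz = fg(x$frequency_hz),
                     ppc = fg(x$mean_ppc),
                     ci_low = fg(x$ci_low), ci_high = fg(x$ci_high))
  } else if (inherits(x, "permutation_result")) {
    df <- data.frame(frequency_hz = fg(x$frequency_hz),
                     ppc = fg(x$observed_mean_ppc),
                     p_value = fg(x$p_value),
                     significant = as.integer(x$significant))
  } else {
    stop("write_spectrum: unsupported object of class ",
         paste(class(x), collapse = "/"))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum file written by [write_spectrum()]
#'
#' @param path Path to the CSV.
#' @return A data frame with the columns present in the file.
#' @export
read_spectrum <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Write an envelope signal as delimited text
#'
#' Columns `time_s`, `value`, full float precision.
#'
#' @param env An [envelope_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_envelope <- function(env, path) {
  df <- data.frame(time_s = sprintf("%.17g", envelope_times(env)),
                   value = sprintf("%.17g", env$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an envelope written by [write_envelope()]
#'
#' The sample rate is recovered from the time column spacing.
#'
#' @param path Path to the CSV.
#' @param recording_id Label for the envelope; defaults to the file name.
#' @param normalization Normalization tag to attach (the file itself does not
#'   record it).
#' @return An [envelope_signal()].
#' @export
read_envelope <- function(path, recording_id = NULL,
                          normalization = "unit_max") {
  if (is.null(recording_id)) {
    recording_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (nrow(df) < 2) stop("envelope file has fewer than 2 samples: ", path)
  rate <- 1 / stats::median(diff(df$time_s))
  envelope_signal(df$value, rate, recording_id, normalization)
}
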