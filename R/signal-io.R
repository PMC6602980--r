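#' Read a heart-rate CSV
#'
#' Reads a comma-separated file with mandatory header columns `time_s`
#' (seconds from recording start) and `hr_bpm`. Rows are sorted by time;
#' duplicate timestamps are rejected rather than averaged, since they
#' usually indicate a corrupted export.
#'
#' @param path Path to an existing CSV file.
#' @return An [hr_samples()] object, `source_label` set to `path`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("time_s,hr_bpm", "0,60", "1,61", "2,62"), f)
#' read_hr_csv(f)
read_hr_csv <- function(path) {
  if (!file.exists(path)) hrv_io_error(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) hrv_format_error(sprintf("cannot parse CSV %s: %s",
                                                 path, conditionMessage(e)))
  )
  needed <- c("time_s", "hr_bpm")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    hrv_format_error(sprintf("missing required column(s): %s",
                             paste(missing, collapse = ", ")))
  }
  t <- suppressWarnings(as.numeric(df$time_s))
  v <- suppressWarnings(as.numeric(df$hr_bpm))
  if (anyNA(t) || anyNA(v)) {
    hrv_format_error("non-numeric entries in time_s/hr_bpm")
  }
  ord <- order(t)
  t <- t[ord]; v <- v[ord]
  if (anyDuplicated(t)) {
    hrv_validation_error(sprintf("duplicate timestamps in %s", path))
  }
  hr_samples(t, v, source_label = path)
}

#' Write heart-rate samples to CSV
#'
#' Inverse of [read_hr_csv()]: writes columns `time_s`, `hr_bpm` with a
#' header, values formatted to 6 decimal places.
#'
#' @param samples An [hr_samples()] or [hr_series()] (invalid samples of a
#'   series are dropped).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hr_csv <- function(samples, path) {
  if (inherits(samples, "hr_series")) {
    keep <- samples$valid
    samples <- hr_samples(hr_times(samples)[keep], samples$values[keep])
  }
  stopifnot(inherits(samples, "hr_samples"))
  lines <- c("time_s,hr_bpm",
             sprintf("%.6f,%.6f", samples$times, samples$values))
  write_lines_checked(lines, path)
  invisible(path)
}

# WFDB annotation type codes that denote beats (QRS detections), per the
# standard annotation code table; everything else (rhythm changes, signal
# quality, comments) is dropped by the reader.
.wfdb_beat_codes <- c(1:13, 25L, 34L, 35L, 38L, 41L)
.wfdb_code_symbols <- local({
  s <- rep("Q", 49)
  s[c(1:13, 25, 34, 35, 38, 41)] <-
    c("N", "L", "R", "a", "V", "F", "J", "A", "S", "E", "j", "/", "Q",
      "B", "e", "n", "f", "r")
  s
})

#' Read beat annotations
#'
#' Parses beat occurrence times either from a plain text file (one beat time
#' in seconds per line) or from a binary WFDB (MIT-format) annotation file.
#' WFDB support is read-only and limited to beat-time extraction: beat-type
#' annotations are kept (with their symbols as labels), all non-beat
#' annotations (rhythm changes, quality markers, comments) are dropped.
#'
#' WFDB annotation files store times as cumulative sample counts, so the
#' recording's sampling frequency `fs` is required to convert to seconds.
#'
#' @param path Path to the annotation file.
#' @param dialect `"plain"` or `"wfdb"`.
#' @param fs Sampling frequency in Hz of the annotated recording; required
#'   for the `"wfdb"` dialect, ignored for `"plain"`.
#' @return A [beat_series()].
#' @export
read_beat_annotations <- function(path, dialect = c("plain", "wfdb"),
                                  fs = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) hrv_io_error(sprintf("file not found: %s", path))
  if (dialect == "plain") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) hrv_insufficient("empty beat-annotation file")
    t <- suppressWarnings(as.numeric(lines))
    if (anyNA(t)) hrv_format_error("non-numeric beat time in plain annotation file")
    if (length(t) > 1 && any(diff(t) <= 0)) {
      hrv_validation_error("beat times must be strictly increasing")
    }
    return(beat_series(t))
  }
  if (is.null(fs) || !is_number(fs) || fs <= 0) {
    hrv_config_error("the wfdb dialect requires a positive sampling frequency `fs`")
  }
  ann <- read_wfdb_annotation_file(path)
  keep <- ann$code %in% .wfdb_beat_codes
  if (!any(keep)) hrv_insufficient("annotation file contains no beat annotations")
  t <- ann$sample[keep] / fs
  if (length(t) > 1 && any(diff(t) <= 0)) {
    hrv_validation_error("beat annotation times are not strictly increasing")
  }
  beat_series(t, labels = .wfdb_code_symbols[ann$code[keep]])
}

# Minimal MIT-format annotation parser. The format is a stream of 16-bit
# little-endian words: the top 6 bits are the annotation type code, the low
# 10 bits the time increment in samples since the previous annotation.
# Pseudo-codes: 59 = SKIP (next two words hold a 32-bit increment, high word
# first), 60/61/62 = NUM/SUB/CHN modifiers (no time), 63 = AUX (low bits =
# byte count of an attached string, padded to even), 0 = end of file.
read_wfdb_annotation_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  nb <- length(raw)
  if (nb < 2) hrv_insufficient("empty annotation file")
  t <- 0
  samples <- integer(0)
  codes <- integer(0)
  i <- 1L
  while (i + 1L <= nb) {
    lo <- as.integer(raw[i]); hi <- as.integer(raw[i + 1L]); i <- i + 2L
    word <- lo + 256L * hi
    if (word == 0L) break
    code <- word %/% 1024L
    field <- word %% 1024L
    if (code == 59L) {
      if (i + 3L > nb) hrv_format_error("truncated SKIP annotation")
      w1 <- as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
      w2 <- as.integer(raw[i + 2L]) + 256L * as.integer(raw[i + 3L])
      i <- i + 4L
      t <- t + w1 * 65536 + w2
    } else if (code %in% c(60L, 61L, 62L)) {
      # annotation modifiers carry no time increment
    } else if (code == 63L) {
      i <- i + field + (field %% 2L)
    } else {
      t <- t + field
      samples <- c(samples, t)
      codes <- c(codes, code)
    }
  }
  list(sample = samples, code = codes)
}

#' Write / read a sliding-window trace CSV
#'
#' The trace CSV has header `t_end_s,sd1_bpm,sd2_bpm,n_pairs`, one row per
#' emission. Windows with too few valid pairs are written with empty
#' `sd1_bpm`/`sd2_bpm` fields (the time grid stays regular). Values are
#' written with 6 decimal places, so a write-read-write cycle is
#' byte-identical.
#'
#' @param trace A [sliding_trace()] result.
#' @param path Output (input) file path.
#' @param spec Optional [window_spec()] to attach to the trace read back.
#' @return `write_trace_csv()`: `path` invisibly; `read_trace_csv()`: a
#'   `sliding_window_trace` data frame.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "sliding_window_trace"))
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))
  lines <- "t_end_s,sd1_bpm,sd2_bpm,n_pairs"
  if (nrow(trace) > 0) {
    lines <- c(lines, sprintf("%s,%s,%s,%d",
                              fmt(trace$t_end), fmt(trace$sd1),
                              fmt(trace$sd2), as.integer(trace$n_pairs)))
  }
  write_lines_checked(lines, path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path, spec = NULL) {
  if (!file.exists(path)) hrv_io_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("numeric", "numeric", "numeric",
                                       "integer"))
  needed <- c("t_end_s", "sd1_bpm", "sd2_bpm", "n_pairs")
  if (!identical(names(df), needed)) {
    hrv_format_error("trace CSV must have columns t_end_s,sd1_bpm,sd2_bpm,n_pairs")
  }
  new_trace(t_end = df$t_end_s, sd1 = df$sd1_bpm, sd2 = df$sd2_bpm,
            n_pairs = df$n_pairs, spec = spec)
}

write_lines_checked <- function(lines, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) hrv_io_error(sprintf(
                    "cannot open %s for writing: %s", path,
                    conditionMessage(e))),
                  warning = function(w) hrv_io_error(sprintf(
                    "cannot open %s for writing: %s", path,
                    conditionMessage(w))))
  on.exit(close(con))
  writeLines(lines, con)
}
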