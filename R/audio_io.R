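#' Waveform container
#'
#' A `pam_wave` holds a single-channel waveform normalized to full scale
#' (+/- 1), its sample rate, an absolute UTC start time (or `NA` when the
#' epoch is unknown) and a recorder/site identifier.
#'
#' @param samples numeric vector of samples in \[-1, 1\].
#' @param rate_hz sampling rate in Hz (> 0).
#' @param start_time `POSIXct` start of the recording (UTC), or `NA`.
#' @param source_id recorder/site identifier string.
#' @return an object of class `pam_wave`.
#' @export
pam_wave <- function(samples, rate_hz, start_time = NA, source_id = "unknown") {
  stopifnot(is.numeric(samples), length(rate_hz) == 1L, rate_hz > 0)
  if (length(samples) && !all(is.finite(samples)))
    stop("waveform samples must be finite")
  if (!inherits(start_time, "POSIXct")) {
    start_time <- if (is.na(start_time[1L])) as.POSIXct(NA) else
      as.POSIXct(start_time, tz = "UTC")
  }
  structure(
    list(samples = as.numeric(samples), rate_hz = as.numeric(rate_hz),
         start_time = start_time, source_id = as.character(source_id)),
    class = "pam_wave")
}

#' @export
print.pam_wave <- function(x, ...) {
  dur <- length(x$samples) / x$rate_hz
  cat(sprintf("<pam_wave> %s: %.3f s at %g Hz (%d samples), start %s\n",
              x$source_id, dur, x$rate_hz, length(x$samples),
              if (is.na(x$start_time)) "unknown epoch" else
                format(x$start_time, "%Y-%m-%d %H:%M:%S", tz = "UTC")))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w a `pam_wave`.
#' @return duration in seconds.
#' @export
wave_duration <- function(w) length(w$samples) / w$rate_hz

# ---- WAV file I/O ----------------------------------------------------------

#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for 16- and 24-bit integer PCM (the formats
#' written by the autonomous recorders this pipeline targets).  Samples are
#' normalized to full scale +/- 1.  For multi-channel files the first
#' channel is used and a warning is issued.  The recording start time is
#' parsed from the file name with `timestamp_regex`/`timestamp_format`; when
#' no timestamp is found the wave carries `NA` ("unknown epoch") and a
#' warning.
#'
#' @param path path to a `.wav` file.
#' @param source_id recorder/site identifier; defaults to the file name stem.
#' @param timestamp_regex regular expression with one capture group
#'   extracting the timestamp token from the file name.
#' @param timestamp_format `strptime` format for the captured token.
#' @return a [pam_wave].
#' @export
read_wav <- function(path, source_id = NULL,
                     timestamp_regex = "(\\d{8}[_-]\\d{6})",
                     timestamp_format = "%Y%m%d_%H%M%S") {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (length(sz) == 0L) break
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      if (length(raw) < 16L) stop("truncated fmt chunk: ", path)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1L, 2L, signed = FALSE,
                               endian = "little"),
        n_channels = readBin(raw[3:4], "integer", 1L, 2L, signed = FALSE,
                             endian = "little"),
        sample_rate = readBin(raw[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1L, 2L, signed = FALSE,
                       endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (length(data_raw) < sz) stop("truncated WAV data chunk: ", path)
      break
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
  }
  if (is.null(fmt)) stop("missing fmt chunk: ", path)
  if (is.null(data_raw)) stop("missing data chunk: ", path)
  if (!fmt$audio_format %in% c(1L, 65534L))
    stop("unsupported WAV encoding (need integer PCM): ", path)
  if (!fmt$bits %in% c(16L, 24L))
    stop("unsupported bit depth ", fmt$bits, " (need 16 or 24): ", path)

  if (fmt$bits == 16L) {
    v <- readBin(data_raw, "integer", length(data_raw) %/% 2L, 2L,
                 signed = TRUE, endian = "little") / 32768
  } else {
    n <- length(data_raw) %/% 3L
    b <- as.integer(data_raw[seq_len(n * 3L)])
    lo <- b[seq(1L, by = 3L, length.out = n)]
    mi <- b[seq(2L, by = 3L, length.out = n)]
    hi <- b[seq(3L, by = 3L, length.out = n)]
    v <- lo + 256 * mi + 65536 * hi
    v <- ifelse(v >= 8388608, v - 16777216, v) / 8388608
  }
  if (fmt$n_channels > 1L) {
    warning("multi-channel WAV: using channel 1 of ", fmt$n_channels)
    v <- v[seq(1L, length(v), by = fmt$n_channels)]
  }

  fn <- basename(path)
  if (is.null(source_id)) source_id <- sub("\\.wav$", "", fn, ignore.case = TRUE)
  st <- as.POSIXct(NA)
  m <- regmatches(fn, regexec(timestamp_regex, fn))[[1L]]
  if (length(m) >= 2L) {
    tok <- gsub("-", "_", m[2L])
    st <- as.POSIXct(strptime(tok, timestamp_format, tz = "UTC"))
  }
  if (is.na(st)) warning("no timestamp in file name '", fn, "': unknown epoch")
  pam_wave(v, fmt$sample_rate, st, source_id)
}

#' Write a waveform as 16-bit PCM WAV
#'
#' @param w a [pam_wave]; samples are clipped to \[-1, 1\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "pam_wave"))
  x <- pmin(pmax(w$samples, -1), 32767 / 32768)
  pcm <- as.integer(round(x * 32768))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(c(1L, 1L), con, 2L, endian = "little")                 # PCM, mono
  writeBin(as.integer(w$rate_hz), con, 4L, endian = "little")
  writeBin(as.integer(w$rate_hz * 2), con, 4L, endian = "little") # byte rate
  writeBin(c(2L, 16L), con, 2L, endian = "little")                # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, 4L, endian = "little")
  writeBin(pcm, con, 2L, endian = "little")
  invisible(path)
}

# ---- resampling ------------------------------------------------------------

#' Resample a waveform to the 96 kHz working rate
#'
#' Rational polyphase resampling (anti-alias filtered) to exactly 96 kHz.
#' 192 kHz input reduces to plain decimation by 2; 128 kHz and 512 kHz use
#' ratios 3/4 and 3/16.  Content above 48 kHz is suppressed by the low-pass
#' stage.  Upsampling (input below 96 kHz) is refused: the classifier band
#' extends to 48 kHz and upsampled recordings would have an empty top band.
#'
#' @param w a [pam_wave].
#' @return a [pam_wave] at 96,000 Hz of the same duration (within one
#'   output sample).
#' @export
resample_to_96k <- function(w) {
  stopifnot(inherits(w, "pam_wave"))
  target <- 96000
  if (w$rate_hz == target) return(w)
  if (w$rate_hz < target)
    stop("refusing to upsample ", w$rate_hz, " Hz to 96 kHz")
  if (!w$rate_hz %in% c(128000, 192000, 512000))
    warning("unusual input rate ", w$rate_hz, " Hz; resampling anyway")
  g <- .gcd(as.integer(target), as.integer(w$rate_hz))
  p <- target / g
  q <- w$rate_hz / g
  y <- .upfirdn(w$samples, p, q, w$rate_hz)
  pam_wave(pmin(pmax(y, -1), 1), target, w$start_time, w$source_id)
}

# rational resampling by p/q: zero-stuff, FIR low-pass (Hamming-windowed,
# cutoff at the tighter of the two Nyquists, ~20% transition), decimate.
.upfirdn <- function(x, p, q, fs_in) {
  cutoff <- min(fs_in, fs_in * p / q) / 2
  wc <- cutoff / (fs_in * p / 2)
  N <- 2L * ceiling(3.5 / (0.2 * wc) / 2)
  h <- signal::fir1(N, wc * 0.98) * p
  u <- if (p > 1) {
    z <- numeric(length(x) * p)
    z[seq(1L, length(z), by = p)] <- x
    z
  } else x
  yf <- signal::fftfilt(h, c(u, numeric(N)))
  n_out <- round(length(x) * p / q)
  yf[N / 2 + 1 + (0:(n_out - 1L)) * q]
}

.gcd <- function(a, b) if (b == 0L) a else .gcd(b, a %% b)

# ---- segmentation ----------------------------------------------------------

#' Cut a 96 kHz waveform into non-overlapping 5-s segments
#'
#' Consecutive 480,000-sample windows; a trailing remainder shorter than 5 s
#' is dropped (the classifier contract is a fixed-length input, and padding
#' would distort class statistics).  Segment `i` (0-based) starts at the
#' recording start time plus `5 * i` seconds.
#'
#' @param w a [pam_wave] at 96,000 Hz.
#' @param segment_s segment duration in seconds (default 5).
#' @return a list of `pam_segment` objects (possibly empty), each with
#'   fields `samples`, `index`, `start_time`, `source_id`, `segment_id`.
#' @export
segment_waveform <- function(w, segment_s = 5) {
  stopifnot(inherits(w, "pam_wave"))
  if (w$rate_hz != 96000) stop("segment_waveform expects a 96 kHz waveform")
  n_seg_samp <- as.integer(segment_s * w$rate_hz)
  n <- length(w$samples) %/% n_seg_samp
  if (n == 0L) return(list())
  lapply(seq_len(n) - 1L, function(i) {
    s <- w$samples[(i * n_seg_samp + 1L):((i + 1L) * n_seg_samp)]
    st <- if (is.na(w$start_time)) as.POSIXct(NA) else
      w$start_time + segment_s * i
    structure(
      list(samples = s, index = i, start_time = st, source_id = w$source_id,
           rate_hz = w$rate_hz,
           segment_id = sprintf("%s_seg%05d", w$source_id, i)),
      class = "pam_segment")
  })
}

#' @export
print.pam_segment <- function(x, ...) {
  cat(sprintf("<pam_segment> %s (index %d, %d samples)\n",
              x$segment_id, x$index, length(x$samples)))
  invisible(x)
}

#' Read a recording-schedule table
#'
#' CSV with columns `source_id, date, recorded_minutes, duty_on_min,
#' duty_off_min` describing how much audio each recorder captured per day
#' under its duty cycle (e.g. 1 min on / 9 min off).
#'
#' @param path CSV path.
#' @return a `data.frame` with `date` parsed to `Date`.
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("source_id", "date", "recorded_minutes", "duty_on_min",
            "duty_off_min")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("schedule is missing columns: ",
                         paste(miss, collapse = ", "))
  df$date <- as.Date(df$date)
  bad <- df$duty_on_min <= 0 | df$duty_off_min < 0
  if (any(bad)) stop("invalid duty cycle in schedule rows ",
                     paste(which(bad), collapse = ", "))
  df
}
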