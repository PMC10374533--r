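#' Front-end configuration
#'
#' Parameters of the spectrogram front end: a 2048-sample Hamming window
#' with 1112 samples of overlap (hop 936) over a 5-s, 96 kHz segment gives
#' 511 raw frames of 1024 positive-frequency bins; the frames are mapped to
#' 128 Mel bands, right-padded to 512 frames and median-equalized per band.
#'
#' @param window_samples analysis window length (samples).
#' @param overlap_samples window overlap (samples).
#' @param n_mels number of Mel bands.
#' @param n_frames_out time frames presented to the classifier.
#' @param log_floor floor applied to linear power before `log10` (relative
#'   to full-scale power).
#' @param mel_variant Mel scale variant; `"htk"` (2595 log10(1 + f/700)) is
#'   the default, `"linear1000"` switches to the Slaney-style scale that is
#'   linear below 1 kHz.
#' @return a list of class `pam_frontend_config`.
#' @export
frontend_config <- function(window_samples = 2048L, overlap_samples = 1112L,
                            n_mels = 128L, n_frames_out = 512L,
                            log_floor = 1e-12, mel_variant = c("htk", "linear1000")) {
  mel_variant <- match.arg(mel_variant)
  stopifnot(window_samples > 0, overlap_samples >= 0,
            overlap_samples < window_samples, n_mels > 0, log_floor > 0)
  structure(list(window_samples = as.integer(window_samples),
                 overlap_samples = as.integer(overlap_samples),
                 n_mels = as.integer(n_mels),
                 n_frames_out = as.integer(n_frames_out),
                 log_floor = log_floor, mel_variant = mel_variant),
            class = "pam_frontend_config")
}

#' Log power spectral density of a 5-s segment
#'
#' Hamming-windowed short-time Fourier transform: hop
#' `window - overlap = 936` samples, 1024 positive-frequency bins from the
#' 2048-point transform (DC retained, Nyquist dropped).  Power is floored
#' at `log_floor` and `log10`-transformed.
#'
#' @param seg a `pam_segment` (480,000 samples at 96 kHz) or a bare numeric
#'   vector of that length.
#' @param config a [frontend_config].
#' @return a `n_frames x n_bins` matrix (rows = time) of log10 power, with
#'   attributes `rate_hz`, `hop_samples`, `bin_hz`.
#' @export
compute_psd <- function(seg, config = frontend_config()) {
  x <- if (inherits(seg, "pam_segment")) seg$samples else as.numeric(seg)
  nw <- config$window_samples
  hop <- nw - config$overlap_samples
  if (length(x) != 480000L)
    stop("segment must hold exactly 480000 samples (5 s at 96 kHz), got ",
         length(x))
  n_frames <- (length(x) - nw) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(nw), starts, `+`)   # nw x n_frames
  frames <- matrix(x[idx], nrow = nw)
  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(nw) - 1L) / (nw - 1L))
  sp <- stats::mvfft(frames * win)
  nb <- nw %/% 2L                          # 1024: DC .. bin below Nyquist
  pow <- Mod(sp[seq_len(nb), , drop = FALSE])^2 / sum(win^2)
  out <- t(log10(pmax(pow, config$log_floor)))
  attr(out, "rate_hz") <- 96000
  attr(out, "hop_samples") <- hop
  attr(out, "bin_hz") <- 96000 / nw
  out
}

# Mel scale forward/backward
.hz_to_mel <- function(f, variant = "htk") {
  if (variant == "htk") return(2595 * log10(1 + f / 700))
  # linear below 1 kHz, log-spaced above
  ifelse(f < 1000, 3 * f / 200,
         15 + 27 * log(f / 1000) / log(6.4))
}
.mel_to_hz <- function(m, variant = "htk") {
  if (variant == "htk") return(700 * (10^(m / 2595) - 1))
  ifelse(m < 15, 200 * m / 3, 1000 * exp(log(6.4) * (m - 15) / 27))
}

#' Triangular Mel filterbank matrix
#'
#' @param n_bins number of linear frequency bins.
#' @param n_mels number of Mel bands.
#' @param fmin,fmax band edges in Hz.
#' @param bin_hz width of a linear bin in Hz.
#' @param variant Mel scale variant (see [frontend_config]).
#' @param norm `"unit_sum"` (default) scales each triangle to sum to one,
#'   so a band is the weighted average of its bins -- the natural choice
#'   when projecting an already log-transformed matrix; `"none"` keeps
#'   peak-one triangles.
#' @return `n_bins x n_mels` weight matrix with attribute `band_edges_hz`
#'   (length `n_mels + 1`).
#' @export
mel_filterbank <- function(n_bins = 1024L, n_mels = 128L, fmin = 0,
                           fmax = 48000, bin_hz = 96000 / 2048,
                           variant = "htk", norm = c("unit_sum", "none")) {
  norm <- match.arg(norm)
  mlo <- .hz_to_mel(fmin, variant)
  mhi <- .hz_to_mel(fmax, variant)
  edges <- .mel_to_hz(seq(mlo, mhi, length.out = n_mels + 2L), variant)
  freqs <- (seq_len(n_bins) - 1L) * bin_hz
  fb <- matrix(0, n_bins, n_mels)
  for (j in seq_len(n_mels)) {
    lo <- edges[j]; ce <- edges[j + 1L]; hi <- edges[j + 2L]
    up <- (freqs - lo) / (ce - lo)
    dn <- (hi - freqs) / (hi - ce)
    fb[, j] <- pmax(0, pmin(up, dn))
  }
  # ensure each filter captures at least its nearest bin (narrow low bands)
  for (j in seq_len(n_mels)) {
    if (sum(fb[, j]) == 0) {
      k <- which.min(abs(freqs - edges[j + 1L]))
      fb[k, j] <- 1
    }
  }
  if (norm == "unit_sum")
    fb <- sweep(fb, 2L, colSums(fb), "/")
  attr(fb, "band_edges_hz") <- edges[-(n_mels + 2L)]
  attr(fb, "band_centers_hz") <- edges[2:(n_mels + 1L)]
  fb
}

#' Project a log-PSD matrix onto Mel bands and pad to 512 frames
#'
#' The 1024 linear bins of each frame are combined with peak-one triangular
#' Mel filters into 128 log-spaced bands.  The raw 511-frame matrix is
#' right-padded with one floor-valued frame so the classifier input is
#' exactly `n_frames_out x n_mels` (512 x 128).
#'
#' @param psd matrix from [compute_psd] (time x 1024).
#' @param config a [frontend_config].
#' @return `512 x 128` matrix (time x Mel band), with attribute
#'   `band_centers_hz`.
#' @export
mel_project <- function(psd, config = frontend_config()) {
  nb <- ncol(psd)
  fb <- mel_filterbank(nb, config$n_mels, 0, 48000,
                       bin_hz = attr(psd, "bin_hz") %||% (96000 / config$window_samples),
                       variant = if (config$mel_variant == "htk") "htk" else "linear1000")
  m <- psd %*% fb
  nfo <- config$n_frames_out
  if (nrow(m) > nfo) m <- m[seq_len(nfo), , drop = FALSE]
  if (nrow(m) < nfo) {
    floor_frame <- as.numeric(rep(log10(config$log_floor), nb) %*% fb)
    pad <- matrix(floor_frame, nrow = nfo - nrow(m), ncol = config$n_mels,
                  byrow = TRUE)
    m <- rbind(m, pad)
  }
  attr(m, "band_centers_hz") <- attr(fb, "band_centers_hz")
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Median-equalize a Mel matrix over time
#'
#' For every Mel band the median over the time frames is subtracted, so
#' time-constant narrowband interference (e.g. stridulating insects) is
#' removed and every output band has median zero.
#'
#' @param m time x band matrix.
#' @return matrix of the same shape with per-band medians subtracted.
#' @export
equalize <- function(m) {
  med <- apply(m, 2L, stats::median)
  out <- sweep(m, 2L, med)
  attr(out, "band_centers_hz") <- attr(m, "band_centers_hz")
  out
}

#' Full front end: 5-s segment to 512 x 128 classifier input
#'
#' @param seg a `pam_segment` or 480,000-sample vector at 96 kHz.
#' @param config a [frontend_config].
#' @return `512 x 128` median-equalized log-Mel matrix.
#' @export
segment_features <- function(seg, config = frontend_config()) {
  equalize(mel_project(compute_psd(seg, config), config))
}

#' Plot a Mel matrix as a spectrogram image
#'
#' @param m time x band matrix (as from [segment_features]).
#' @param ... passed to [graphics::image].
#' @export
plot_mel <- function(m, ...) {
  graphics::image(x = seq_len(nrow(m)) * 936 / 96000,
                  y = seq_len(ncol(m)), z = m,
                  xlab = "time (s)", ylab = "Mel band",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
}
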