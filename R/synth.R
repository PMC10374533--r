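#' Band-limited RMS of a waveform
#'
#' FFT-based estimate of the RMS contributed by frequencies in
#' `[f_lo, f_hi]`; used to express event SNR against the background bed
#' within the event's own band.
#'
#' @param x numeric samples.
#' @param rate_hz sampling rate.
#' @param f_lo,f_hi band limits in Hz.
#' @return band RMS (same units as `x`).
#' @export
band_rms <- function(x, rate_hz, f_lo, f_hi) {
  n <- min(length(x), 2^17)
  x <- x[seq_len(n)]
  sp <- Mod(stats::fft(x))^2 / n^2
  f <- (seq_len(n) - 1) * rate_hz / n
  half <- seq_len(n %/% 2L)
  keep <- half[f[half] >= f_lo & f[half] <= f_hi]
  sqrt(2 * sum(sp[keep]))
}

#' Synthesize a dolphin-like echolocation click train
#'
#' Broadband odontocete-like transients: exponentially damped band-limited
#' sinusoids of ~0.1-0.3 ms, repeated at a regular inter-click interval
#' (ICI) with +/-10 percent jitter.  No species realism is claimed; the
#' clicks are generic impulsive biosonar signals with energy up to the
#' 48 kHz band edge.
#'
#' @param n_clicks number of clicks.
#' @param ici_ms inter-click interval in milliseconds (must exceed the
#'   click duration).
#' @param peak_freq_hz spectral peak of each click (< 48 kHz).
#' @param snr_db click peak amplitude relative to `ref_rms` in dB
#'   (`-Inf` yields silence).
#' @param ref_rms reference RMS (background bed in the click band).
#' @param rate_hz sampling rate.
#' @param tau_s damping time constant of a click.
#' @return numeric fragment containing the train, with attributes
#'   `duration_s`, `f_low`, `f_high`.
#' @export
synth_click_train <- function(n_clicks = 25L, ici_ms = 50, peak_freq_hz = 38000,
                              snr_db = 20, ref_rms = 1, rate_hz = 96000,
                              tau_s = 6e-5) {
  if (peak_freq_hz >= rate_hz / 2)
    stop("click peak frequency must lie below Nyquist")
  click_dur_s <- 8 * tau_s
  if (ici_ms / 1000 <= click_dur_s)
    stop("inter-click interval must exceed the click duration")
  amp <- if (is.infinite(snr_db) && snr_db < 0) 0 else
    10^(snr_db / 20) * ref_rms
  nc <- round(click_dur_s * rate_hz)
  tt <- (seq_len(nc) - 1) / rate_hz
  proto <- exp(-tt / tau_s) * sin(2 * pi * peak_freq_hz * tt)
  icis <- (ici_ms / 1000) * (1 + stats::runif(n_clicks, -0.1, 0.1))
  starts <- cumsum(c(0, icis[-n_clicks]))
  n <- ceiling((starts[n_clicks] + click_dur_s) * rate_hz) + 1L
  y <- numeric(n)
  for (s in starts) {
    i0 <- round(s * rate_hz) + 1L
    y[i0:(i0 + nc - 1L)] <- y[i0:(i0 + nc - 1L)] + amp * proto
  }
  attr(y, "duration_s") <- n / rate_hz
  attr(y, "f_low") <- max(0, peak_freq_hz - 12000)
  attr(y, "f_high") <- min(rate_hz / 2, peak_freq_hz + 12000)
  y
}

#' Synthesize boat engine noise
#'
#' Cavitation-like low-frequency-weighted broadband noise plus stable
#' engine harmonics, amplitude-modulated at a few Hz with a rise/fall
#' passage envelope, so that the signature survives per-band median
#' equalization (a real boat passage is never time-constant within 5 s).
#'
#' @param duration_s fragment duration.
#' @param tonal_hz harmonic frequencies (Hz).
#' @param snr_db band RMS relative to `ref_rms` in dB.
#' @param ref_rms reference RMS (bed in the boat band).
#' @param rate_hz sampling rate.
#' @return numeric fragment with attributes `f_low`, `f_high`.
#' @export
synth_boat <- function(duration_s = 60, tonal_hz = c(250, 500, 1000, 2000),
                       snr_db = 15, ref_rms = 1, rate_hz = 96000) {
  if (any(tonal_hz >= rate_hz / 2)) stop("tonal above Nyquist")
  n <- round(duration_s * rate_hz)
  tt <- (seq_len(n) - 1) / rate_hz
  bf <- signal::butter(4, 4000 / (rate_hz / 2), type = "low")
  broad <- signal::filter(bf, stats::rnorm(n))
  tone <- rowSums(vapply(tonal_hz, function(f)
    sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi)), numeric(n)))
  y <- as.numeric(broad) + 0.3 * tone
  am <- 1 + 0.5 * sin(2 * pi * stats::runif(1, 1, 3) * tt +
                        stats::runif(1, 0, 2 * pi))
  edge <- pmin(1, pmin(tt, duration_s - tt) / (0.1 * duration_s))
  y <- y * am * edge
  cur <- band_rms(y, rate_hz, 50, 4000)
  amp <- 10^(snr_db / 20) * ref_rms
  y <- y * if (cur > 0) amp / cur else 0
  attr(y, "f_low") <- 50
  attr(y, "f_high") <- 4000
  y
}

#' Synthesize rain
#'
#' A dense Poisson process of short broadband micro-impulses (droplet
#' impacts) covering the full band.
#'
#' @param duration_s fragment duration.
#' @param impulses_per_s mean impulse rate (0 yields silence).
#' @param snr_db band RMS relative to `ref_rms` in dB.
#' @param ref_rms reference RMS.
#' @param rate_hz sampling rate.
#' @return numeric fragment with attributes `f_low`, `f_high`.
#' @export
synth_rain <- function(duration_s = 60, impulses_per_s = 300, snr_db = 10,
                       ref_rms = 1, rate_hz = 96000) {
  n <- round(duration_s * rate_hz)
  y <- numeric(n)
  k <- stats::rpois(1, impulses_per_s * duration_s)
  if (k > 0) {
    pos <- sort(sample.int(n, min(k, n), replace = FALSE))
    amp <- stats::rlnorm(length(pos), 0, 0.5)
    nimp <- round(3e-4 * rate_hz)          # ~0.3 ms droplet transient
    proto_t <- (seq_len(nimp) - 1) / rate_hz
    for (i in seq_along(pos)) {
      imp <- stats::rnorm(nimp) * exp(-proto_t / 8e-5) * amp[i]
      i1 <- min(n, pos[i] + nimp - 1L)
      y[pos[i]:i1] <- y[pos[i]:i1] + imp[seq_len(i1 - pos[i] + 1L)]
    }
    cur <- sqrt(mean(y^2))
    amp_target <- 10^(snr_db / 20) * ref_rms
    if (cur > 0) y <- y * amp_target / cur
  }
  attr(y, "f_low") <- 200
  attr(y, "f_high") <- rate_hz / 2
  y
}

#' Synthesize the background bed
#'
#' Stationary ambient noise plus continuous narrowband insect-like tones
#' (stridulation); the tones are time-constant on purpose, which is what
#' the per-band median equalization removes.
#'
#' @param duration_s bed duration.
#' @param insect_tones_hz tone frequencies.
#' @param level RMS of the ambient noise (full scale = 1).
#' @param tone_level amplitude of each tone.
#' @param rate_hz sampling rate.
#' @return numeric bed.
#' @export
synth_background <- function(duration_s = 60,
                             insect_tones_hz = c(5200, 7300),
                             level = 0.02, tone_level = 0.01,
                             rate_hz = 96000) {
  n <- round(duration_s * rate_hz)
  y <- stats::rnorm(n, sd = level)
  tt <- (seq_len(n) - 1) / rate_hz
  for (f in insect_tones_hz)
    y <- y + tone_level * sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
  y
}

#' Scene plan for a synthetic soundscape
#'
#' @param duration_s total scene duration.
#' @param events data.frame with columns `class` (`click`, `boat`,
#'   `rain`), `t_start`, `t_end` (s) and `snr_db`; extra per-class
#'   parameters use generator defaults.
#' @param sample_rate_hz output rate.
#' @param background list of [synth_background] arguments.
#' @param seed integer; fixes the realization.
#' @return a validated list of class `pam_scene_plan`.
#' @export
scene_plan <- function(duration_s, events = NULL, sample_rate_hz = 96000,
                       background = list(), seed = 1L) {
  if (is.null(events))
    events <- data.frame(class = character(), t_start = numeric(),
                         t_end = numeric(), snr_db = numeric())
  stopifnot(all(events$t_start >= 0), all(events$t_end > events$t_start))
  if (any(events$t_end > duration_s))
    stop("event extends beyond the scene duration")
  if (any(!is.finite(events$snr_db) & events$snr_db > 0))
    stop("event SNR must be finite or -Inf")
  structure(list(duration_s = duration_s, events = events,
                 sample_rate_hz = sample_rate_hz, background = background,
                 seed = as.integer(seed)),
            class = "pam_scene_plan")
}

#' Render a scene plan into audio plus ground truth
#'
#' Mixes the background bed and every planned event linearly; event SNR is
#' defined against the bed's RMS within the event's band.  The ground
#' truth is an annotation table (same schema as the labelling store) with
#' each event's true time and frequency extent.  Rendering is reproducible
#' from the plan's seed.
#'
#' @param plan a [scene_plan].
#' @param path optional path: write the mixture as 16-bit WAV.
#' @param source_id identifier stamped on the wave and annotations.
#' @param start_time recording start (UTC).
#' @return list with `wave` (a [pam_wave]) and `truth` (an
#'   [annotations] table).
#' @export
render_scene <- function(plan, path = NULL, source_id = "synthetic",
                         start_time = as.POSIXct("2020-01-01 00:00:00",
                                                 tz = "UTC")) {
  stopifnot(inherits(plan, "pam_scene_plan"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(plan$seed)
  fs <- plan$sample_rate_hz
  bed <- do.call(synth_background,
                 c(list(duration_s = plan$duration_s, rate_hz = fs),
                   plan$background))
  y <- bed
  ev <- plan$events
  truth <- list()
  for (i in seq_len(nrow(ev))) {
    cl <- ev$class[i]
    t0 <- ev$t_start[i]; t1 <- ev$t_end[i]
    dur <- t1 - t0
    frag <- switch(
      cl,
      click = {
        ici <- if (!is.null(ev$ici_ms)) ev$ici_ms[i] else 50
        ncl <- max(2L, floor(dur * 1000 / ici))
        ref <- band_rms(bed, fs, 26000, 48000)
        synth_click_train(ncl, ici, snr_db = ev$snr_db[i], ref_rms = ref,
                          rate_hz = fs)
      },
      boat = {
        ref <- band_rms(bed, fs, 50, 4000)
        synth_boat(dur, snr_db = ev$snr_db[i], ref_rms = ref, rate_hz = fs)
      },
      rain = {
        ref <- sqrt(mean(bed^2))
        synth_rain(dur, snr_db = ev$snr_db[i], ref_rms = ref, rate_hz = fs)
      },
      stop("unknown event class: ", cl))
    i0 <- round(t0 * fs) + 1L
    i1 <- min(length(y), i0 + length(frag) - 1L)
    y[i0:i1] <- y[i0:i1] + frag[seq_len(i1 - i0 + 1L)]
    truth[[i]] <- data.frame(
      source_id = source_id, class = cl, t_start_s = t0,
      t_end_s = t0 + min(dur, length(frag) / fs),
      f_low_hz = attr(frag, "f_low") %||% 0,
      f_high_hz = attr(frag, "f_high") %||% (fs / 2),
      annotator = "generator", created_at = "synthetic",
      stringsAsFactors = FALSE)
  }
  peak <- max(abs(y), 1)
  if (peak > 0.99) y <- y * 0.99 / peak
  wave <- pam_wave(y, fs, start_time, source_id)
  if (!is.null(path)) write_wav(wave, path)
  tr <- if (length(truth)) annotations(do.call(rbind, truth)) else
    annotations(data.frame(source_id = character(), class = character(),
                           t_start_s = numeric(), t_end_s = numeric(),
                           f_low_hz = numeric(), f_high_hz = numeric()))
  list(wave = wave, truth = tr)
}

#' Generate a labeled training corpus of 5-s segments
#'
#' Emulates the structure of a field annotation campaign at desk scale:
#' imbalanced classes (clicks common, boat and rain rare, background
#' dominant) with a share of multi-label segments (click trains recorded
#' during a boat passage).  Every segment is rendered as audio, passed
#' through the full front end, and labeled through the bounding-box
#' overlap rule, so the ground truth is exactly consistent with the
#' annotation machinery.
#'
#' @param n_click,n_boat,n_rain,n_background per-class segment counts
#'   (segments *containing* the class; multi-label segments count toward
#'   every class they contain).
#' @param multi_frac fraction of click segments that also carry a boat
#'   passage (capped by `n_boat`).
#' @param snr_db named list of SNR ranges per class (dB).
#' @param seed integer seed.
#' @param config a [frontend_config].
#' @param classes class order of the targets.
#' @param site site identifier stamped on the segments.
#' @param keep_audio keep the rendered samples (memory-heavy; default
#'   drops them after feature extraction).
#' @return list of class `pam_corpus`: `features` (512 x 128 x N array),
#'   `labels` (list of class vectors), `targets` (N x 16 x K array),
#'   `truth` (combined annotation table), `meta` (segment_id, classes),
#'   `manifest` (per-class segment counts).
#' @export
make_training_corpus <- function(n_click = 200L, n_boat = 60L, n_rain = 40L,
                                 n_background = 300L, multi_frac = 0.15,
                                 snr_db = list(click = c(15, 30),
                                               boat = c(10, 20),
                                               rain = c(8, 15)),
                                 seed = 1L, config = frontend_config(),
                                 classes = c("click", "boat", "rain"),
                                 site = "synthcorp", keep_audio = FALSE) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_multi <- min(round(multi_frac * n_click), n_boat)
  kinds <- c(rep("click", n_click - n_multi),
             rep("click+boat", n_multi),
             rep("boat", n_boat - n_multi),
             rep("rain", n_rain),
             rep("background", n_background))
  kinds <- sample(kinds)
  N <- length(kinds)
  feats <- array(NA_real_, c(config$n_frames_out, config$n_mels, N))
  labels <- vector("list", N)
  targets <- array(0L, c(N, 16L, length(classes)))
  truth <- vector("list", N)
  audio <- if (keep_audio) vector("list", N) else NULL
  meta <- data.frame(segment_id = sprintf("%s_%04d", site, seq_len(N)),
                     site = site, stringsAsFactors = FALSE)
  fs <- 96000
  for (i in seq_len(N)) {
    want <- strsplit(kinds[i], "+", fixed = TRUE)[[1L]]
    want <- setdiff(want, "background")
    ev <- NULL
    if ("click" %in% want) {
      t0 <- stats::runif(1, 0.2, 1.8)
      dur <- stats::runif(1, 1.0, 3.0)
      ev <- rbind(ev, data.frame(class = "click", t_start = t0,
                                 t_end = min(4.9, t0 + dur),
                                 snr_db = stats::runif(1, snr_db$click[1],
                                                       snr_db$click[2])))
    }
    if ("boat" %in% want) {
      t0 <- stats::runif(1, 0, 0.8)
      t1 <- stats::runif(1, 3.8, 5.0)
      ev <- rbind(ev, data.frame(class = "boat", t_start = t0, t_end = t1,
                                 snr_db = stats::runif(1, snr_db$boat[1],
                                                       snr_db$boat[2])))
    }
    if ("rain" %in% want) {
      t0 <- stats::runif(1, 0, 0.5)
      t1 <- stats::runif(1, 4.0, 5.0)
      ev <- rbind(ev, data.frame(class = "rain", t_start = t0, t_end = t1,
                                 snr_db = stats::runif(1, snr_db$rain[1],
                                                       snr_db$rain[2])))
    }
    plan <- scene_plan(5, ev, sample_rate_hz = fs,
                       seed = sample.int(2^30, 1))
    sc <- render_scene(plan, source_id = meta$segment_id[i])
    seg <- structure(list(samples = sc$wave$samples[seq_len(480000L)],
                          index = 0L, start_time = sc$wave$start_time,
                          source_id = meta$segment_id[i], rate_hz = fs,
                          segment_id = meta$segment_id[i]),
                     class = "pam_segment")
    feats[, , i] <- segment_features(seg, config)
    truth[[i]] <- as.data.frame(sc$truth)
    lab <- derive_segment_labels(sc$truth,
                                 data.frame(segment_id = meta$segment_id[i],
                                            source_id = meta$segment_id[i],
                                            t_start_s = 0),
                                 classes)
    labels[[i]] <- lab$labels[[1L]]
    targets[i, , ] <- derive_column_targets(
      sc$truth, list(source_id = meta$segment_id[i], t_start_s = 0),
      classes)
    if (keep_audio) audio[[i]] <- seg
  }
  meta$classes <- vapply(labels, function(l)
    if (length(l)) paste(l, collapse = ";") else "background", "")
  manifest <- c(vapply(classes, function(cl)
    sum(vapply(labels, function(l) cl %in% l, TRUE)), 0L),
    background = sum(lengths(labels) == 0L))
  names(manifest)[seq_along(classes)] <- classes
  out <- list(features = feats, labels = labels, targets = targets,
              truth = do.call(rbind, truth), meta = meta,
              manifest = manifest, classes = classes, seed = seed)
  if (keep_audio) out$audio <- audio
  class(out) <- "pam_corpus"
  out
}

#' @export
print.pam_corpus <- function(x, ...) {
  cat("Synthetic labeled corpus:", dim(x$features)[3], "segments\n")
  print(x$manifest)
  invisible(x)
}
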