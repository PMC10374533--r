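test_that("click trains place clicks at the requested ICI with jitter", {
  set.seed(80)
  fs <- 96000
  y <- synth_click_train(n_clicks = 10, ici_ms = 50, snr_db = 20,
                         ref_rms = 0.01, rate_hz = fs)
  # envelope oracle: supra-threshold clusters spaced 50 +/- 5 ms
  env <- abs(y)
  above <- which(env > 0.5 * max(env))
  gaps <- which(diff(above) > round(0.01 * fs))
  starts <- above[c(1, gaps + 1)]
  expect_length(starts, 10)
  icis <- diff(starts) / fs * 1000
  expect_true(all(icis > 45 & icis < 55))
})

test_that("zero-amplitude clicks are silent; bad parameters rejected", {
  y <- synth_click_train(5, 50, snr_db = -Inf, ref_rms = 0.01)
  expect_true(all(y == 0))
  expect_error(synth_click_train(5, 50, peak_freq_hz = 60000), "Nyquist")
  expect_error(synth_click_train(5, ici_ms = 0.1), "interval")
})

test_that("click spectral centroid sits near the design peak frequency", {
  set.seed(81)
  for (pf in c(30000, 38000)) {
    y <- synth_click_train(20, 50, peak_freq_hz = pf, snr_db = 20,
                           ref_rms = 0.01)
    n <- length(y)
    sp <- Mod(stats::fft(y))[1:(n %/% 2)]^2
    f <- (seq_len(n %/% 2) - 1) * 96000 / n
    centroid <- sum(f * sp) / sum(sp)
    expect_lt(abs(centroid - pf), 5000)
  }
})

test_that("rain at zero rate is silence; boat tones elevate their band", {
  expect_true(all(synth_rain(2, impulses_per_s = 0) == 0))
  set.seed(82)
  boat <- synth_boat(5, tonal_hz = c(2000), snr_db = 15, ref_rms = 0.01)
  pad <- c(boat, numeric(480000))[1:480000]
  pre <- mel_project(compute_psd(pad))
  centers <- attr(pre, "band_centers_hz")
  b2k <- which.min(abs(centers - 2000))
  b20k <- which.min(abs(centers - 20000))
  expect_gt(mean(pre[1:400, b2k]), mean(pre[1:400, b20k]) + 1)
})

test_that("scene rendering is seed-reproducible down to the WAV bytes", {
  ev <- data.frame(class = c("click", "boat"), t_start = c(1, 4),
                   t_end = c(3, 9), snr_db = c(20, 15))
  plan <- scene_plan(10, ev, seed = 5)
  p1 <- file.path(tempdir(), "scene1.wav")
  p2 <- file.path(tempdir(), "scene2.wav")
  render_scene(plan, p1)
  render_scene(plan, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("ground truth lists every planned event with its class", {
  ev <- data.frame(class = c("click", "click", "click", "boat", "rain"),
                   t_start = c(5, 120, 300, 60, 400),
                   t_end = c(8, 124, 303, 180, 460),
                   snr_db = c(20, 22, 18, 15, 10))
  plan <- scene_plan(600, ev, seed = 9)
  sc <- render_scene(plan)
  expect_equal(nrow(sc$truth), 5)
  expect_equal(sort(table(sc$truth$class), decreasing = TRUE)[["click"]], 3)
  expect_true(all(sc$truth$t_start_s == ev$t_start))
  expect_error(scene_plan(10, data.frame(class = "boat", t_start = 5,
                                         t_end = 15, snr_db = 10)),
               "beyond")
})

test_that("scene ground truth agrees with the annotation overlap rule", {
  ev <- data.frame(class = c("click", "boat"), t_start = c(2, 11),
                   t_end = c(7, 14), snr_db = c(20, 15))
  plan <- scene_plan(20, ev, seed = 11)
  sc <- render_scene(plan, source_id = "scn")
  segs <- segment_waveform(sc$wave)
  lab <- derive_segment_labels(sc$truth, segs)
  expect_equal(lab$labels[[1]], "click")   # 0-5 s
  expect_equal(lab$labels[[2]], "click")   # 5-10 s (event ends at 7)
  expect_equal(lab$labels[[3]], "boat")    # 10-15 s
  expect_true(lab$is_background[4])
})

test_that("background-only scenes label every segment background", {
  plan <- scene_plan(15, seed = 13)
  sc <- render_scene(plan, source_id = "bg")
  segs <- segment_waveform(sc$wave)
  lab <- derive_segment_labels(sc$truth, segs)
  expect_true(all(lab$is_background))
})

test_that("rendered events are recoverable above the background bed", {
  # clicks are sparse sub-frame transients, so compare the upper tail of
  # the click band's per-frame maxima inside vs outside the event window,
  # aggregated over seeds (the event is a statistical, not a pointwise,
  # feature of the image)
  diffs <- vapply(17:21, function(s) {
    ev <- data.frame(class = "click", t_start = 1, t_end = 4, snr_db = 25)
    sc <- render_scene(scene_plan(5, ev, seed = s), source_id = "snr")
    m <- segment_features(sc$wave$samples[1:480000])
    frame_t <- (seq_len(512) - 1) * 936 / 96000
    stripe <- apply(m[, 100:128], 1, max)    # click band, upper Mel range
    inside <- frame_t >= 1 & frame_t <= 4
    mean(sort(stripe[inside], decreasing = TRUE)[1:10]) -
      mean(sort(stripe[!inside], decreasing = TRUE)[1:10])
  }, 0)
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.5)
  # a boat event, in contrast, is a sustained band elevation
  ev2 <- data.frame(class = "boat", t_start = 0.5, t_end = 4.5, snr_db = 15)
  sc2 <- render_scene(scene_plan(5, ev2, seed = 23), source_id = "snr2")
  pre <- mel_project(compute_psd(sc2$wave$samples[1:480000]))
  centers <- attr(pre, "band_centers_hz")
  lo <- which(centers > 200 & centers < 3000)
  hi <- which(centers > 20000)
  expect_gt(mean(pre[1:400, lo]), mean(pre[1:400, hi]) + 0.5)
})

test_that("the corpus manifest matches the requested class structure", {
  corp <- fixture_corpus()
  expect_equal(unname(corp$manifest["click"]), 24L)
  expect_equal(unname(corp$manifest["boat"]), 10L)
  expect_equal(unname(corp$manifest["rain"]), 8L)
  expect_equal(unname(corp$manifest["background"]), 26L)
  # multi-label segments exist (clicks during boat passages)
  expect_gt(sum(grepl(";", corp$meta$classes)), 0)
  expect_equal(dim(corp$features), c(512L, 128L, length(corp$labels)))
})

test_that("column targets in the corpus line up with the segment labels", {
  corp <- fixture_corpus()
  # the column-wise OR recovers exactly the segment's label set
  for (i in seq_along(corp$labels)) {
    tg <- corp$targets[i, , ]
    pos <- corp$classes[colSums(tg) > 0]
    expect_setequal(pos, corp$labels[[i]])
  }
})

test_that("an imbalanced corpus triggers oversampling to the policy minimum", {
  corp <- fixture_corpus()
  idx <- oversample(corp$labels, augment_policy(min_labels_per_epoch = 20))
  counts <- attr(idx, "counts")
  expect_true(all(counts >= 20))
  expect_gt(length(idx), length(corp$labels))
})

test_that("a seeded split of the corpus preserves class presence", {
  corp <- fixture_corpus()
  sp <- split_train_test(data.frame(segment_id = corp$meta$segment_id),
                         "random", seed = 3)
  for (part in sp) {
    labs <- corp$labels[match(part, corp$meta$segment_id)]
    for (cl in corp$classes)
      expect_gt(sum(vapply(labs, function(l) cl %in% l, TRUE)), 0)
  }
})

test_that("band RMS tracks the energy of a band-limited tone", {
  t <- (0:95999) / 96000
  x <- 0.2 * sin(2 * pi * 5000 * t)
  expect_equal(band_rms(x, 96000, 4000, 6000), 0.2 / sqrt(2),
               tolerance = 0.01)
  expect_lt(band_rms(x, 96000, 20000, 40000), 0.01)
})
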