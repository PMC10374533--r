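toy_thresholds <- function() {
  threshold_table(data.frame(
    site = rep(c("Rato", "Boca"), each = 3),
    class = rep(c("click", "boat", "rain"), 2),
    threshold = c(0.85, 0.98, 0.85, 0.85, 0.97, 0.85),
    rain_filter_threshold = c(0.90, 0.90, 0.90, 0.99, 0.99, 0.99)))
}

toy_scores <- function(n = 12, site = "Rato", seed = 3) {
  set.seed(seed)
  data.frame(segment_id = sprintf("s%03d", seq_len(n)), site = site,
             start_time = as.POSIXct("2020-03-01", tz = "UTC") + 5 * seq_len(n),
             q75_click = runif(n), q75_boat = runif(n), q75_rain = runif(n),
             stringsAsFactors = FALSE)
}

test_that("thresholding flags exactly score >= threshold (closed bound)", {
  sc <- toy_scores(12)
  sc$q75_click[1] <- 0.85          # exactly at the threshold
  sc$q75_click[2] <- 0.8499
  rec <- threshold_detections(sc, toy_thresholds())
  expect_equal(nrow(rec), 12)
  expect_identical(rec$segment_id, sc$segment_id)  # order preserved
  expect_true(rec$flag_click[1])
  expect_false(rec$flag_click[2])
  expect_equal(rec$flag_click, rec$q75_click >= 0.85)
  expect_equal(rec$flag_boat, rec$q75_boat >= 0.98)
  # all-low scores flag nothing
  sc0 <- toy_scores(3); sc0$q75_click <- sc0$q75_boat <- sc0$q75_rain <- 0.01
  expect_false(any(unlist(threshold_detections(sc0, toy_thresholds())[
    , c("flag_click", "flag_boat", "flag_rain")])))
})

test_that("a site missing from the threshold table fails before processing", {
  sc <- toy_scores(3, site = "Mystery")
  expect_error(threshold_detections(sc, toy_thresholds()),
               "no click threshold.*Mystery")
})

test_that("the rain filter clears clicks when both scores are high", {
  sc <- toy_scores(4)
  sc$q75_click <- c(0.90, 0.90, 0.10, 0.95)
  sc$q75_rain <- c(0.95, 0.50, 0.95, 0.89)
  sc$q75_boat <- c(0.99, 0.99, 0.10, 0.10)
  rec <- apply_rain_filter(threshold_detections(sc, toy_thresholds()),
                           toy_thresholds())
  expect_false(rec$flag_click[1])      # click 0.90, rain 0.95 >= 0.90
  expect_true(rec$rain_attributed[1])
  expect_true(rec$flag_click[2])       # rain 0.50 below the filter
  expect_false(rec$flag_click[3])      # was never click-positive
  expect_false(rec$rain_attributed[3])
  expect_true(rec$flag_click[4])       # rain 0.89 stays below the filter
  # boat flags are untouched by the filter
  expect_equal(rec$flag_boat,
               threshold_detections(sc, toy_thresholds())$flag_boat)
})

test_that("rain-filter clearing matches a brute-force counter and never adds", {
  set.seed(64)
  thr <- toy_thresholds()
  for (i in 1:20) {
    sc <- toy_scores(40, seed = i)
    rec0 <- threshold_detections(sc, thr)
    rec1 <- apply_rain_filter(rec0, thr)
    cleared <- sum(rec0$flag_click) - sum(rec1$flag_click)
    oracle <- sum(rec0$flag_click & sc$q75_rain >= 0.90)
    expect_equal(cleared, oracle)
    expect_equal(sum(rec1$rain_attributed), oracle)
    expect_lte(sum(rec1$flag_click), sum(rec0$flag_click))
    expect_identical(rec1$flag_boat, rec0$flag_boat)
    # flag implies threshold for the surviving clicks
    expect_true(all(rec1$q75_click[rec1$flag_click] >= 0.85))
  }
})

test_that("sites without a rain-filter threshold are skipped, not broken", {
  thr <- threshold_table(data.frame(site = "Plain", class = c("click", "boat"),
                                    threshold = c(0.5, 0.5)))
  sc <- toy_scores(5, site = "Plain")
  sc$q75_click <- 0.9; sc$q75_rain <- 0.99
  rec <- threshold_detections(sc, thr, classes = c("click", "boat"))
  rec$q75_rain <- sc$q75_rain
  expect_message(out <- apply_rain_filter(rec, thr), "skipped")
  expect_equal(out$flag_click, rec$flag_click)
})

test_that("review sampling is seeded, capped, and seed-sensitive", {
  rec <- fixture_records(seed = 6, n = 200, p_click = 0.5)
  a <- sample_for_review(rec, "click", n = 10, seed = 3)
  b <- sample_for_review(rec, "click", n = 10, seed = 3)
  expect_identical(a$segment_id, b$segment_id)
  expect_equal(nrow(a), 10)
  expect_true(all(a$flag_click))
  distinct <- vapply(1:20, function(s)
    !identical(sample_for_review(rec, "click", n = 10,
                                 seed = s)$segment_id, a$segment_id), TRUE)
  expect_gte(sum(distinct), 19)
  # more requested than available: return all with a warning
  few <- rec[which(rec$flag_click)[1:3], ]
  expect_warning(out <- sample_for_review(few, "click", n = 10, seed = 1),
                 "returning all")
  expect_equal(nrow(out), 3)
})

test_that("merging corrections grows the train set once and only once", {
  train <- data.frame(segment_id = c("a", "b"), stringsAsFactors = FALSE)
  train$labels <- list("click", character(0))
  reviewed <- data.frame(segment_id = c("c", "d", "e", "f", "g", "h", "i",
                                        "j"),
                         verdict = c(rep("click", 5), rep("rain", 3)),
                         stringsAsFactors = FALSE)
  merged <- merge_corrections(train, reviewed)
  expect_equal(nrow(merged), 10)        # 5 confirmed + 3 corrected
  # ledger oracle: per-class counts after = before + verdicts
  count <- function(ts, cl) sum(vapply(ts$labels, function(l) cl %in% l, TRUE))
  expect_equal(count(merged, "click"), count(train, "click") + 5)
  expect_equal(count(merged, "rain"), count(train, "rain") + 3)
  # idempotence
  again <- suppressMessages(merge_corrections(merged, reviewed))
  expect_equal(nrow(again), nrow(merged))
  # missing verdicts are skipped with a warning
  reviewed$verdict[1] <- NA
  expect_warning(merge_corrections(train, reviewed), "lack a verdict")
})

test_that("detections round-trip through CSV", {
  rec <- fixture_records(seed = 8, n = 30)
  class(rec) <- c("pam_detections", "data.frame")
  p <- file.path(tempdir(), "det.csv")
  write_detections(rec, p)
  back <- read_detections(p)
  expect_equal(back$segment_id, rec$segment_id)
  expect_equal(back$flag_click, rec$flag_click)
  expect_equal(as.numeric(back$start_time), as.numeric(rec$start_time))
})

test_that("threshold YAML mirrors the per-site table layout", {
  p <- file.path(tempdir(), "thr.yml")
  writeLines(c("Rato:",
               "  click: 0.85", "  boat: 0.98", "  rain_filter: 0.90",
               "Boca:",
               "  click: 0.85", "  boat: 0.97", "  rain_filter: 0.99"), p)
  tt <- read_threshold_table(p)
  expect_equal(pamscape:::.lookup_threshold(tt, "Rato", "click"), 0.85)
  expect_equal(pamscape:::.lookup_threshold(tt, "Boca", "boat"), 0.97)
  expect_equal(pamscape:::.lookup_rain_filter(tt, "Rato"), 0.90)
})
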