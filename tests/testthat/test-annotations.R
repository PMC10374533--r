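mk_ann <- function(...) {
  rows <- list(...)
  annotations(do.call(rbind, lapply(rows, function(r)
    data.frame(source_id = r[[1]], class = r[[2]],
               t_start_s = as.numeric(r[[3]]), t_end_s = as.numeric(r[[4]]),
               f_low_hz = 0, f_high_hz = 48000,
               stringsAsFactors = FALSE))))
}

mk_seg <- function(src, n) {
  data.frame(segment_id = sprintf("%s_%02d", src, seq_len(n) - 1L),
             source_id = src, t_start_s = 5 * (seq_len(n) - 1L),
             stringsAsFactors = FALSE)
}

test_that("any positive-duration overlap labels a segment", {
  ann <- mk_ann(list("r", "click", 2.0, 3.0))
  lab <- derive_segment_labels(ann, mk_seg("r", 2))
  expect_equal(lab$labels[[1]], "click")
  expect_true(lab$is_background[2])
})

test_that("an annotation straddling a boundary labels both segments", {
  ann <- mk_ann(list("r", "boat", 4.5, 5.5))
  lab <- derive_segment_labels(ann, mk_seg("r", 2))
  expect_equal(lab$labels[[1]], "boat")
  expect_equal(lab$labels[[2]], "boat")
})

test_that("no annotations means background everywhere", {
  ann <- mk_ann(list("other", "click", 0, 1))
  expect_warning(lab <- derive_segment_labels(ann, mk_seg("r", 3)),
                 "overlap no segment")
  expect_true(all(lab$is_background))
})

test_that("label derivation is order-independent and idempotent", {
  ann <- mk_ann(list("r", "click", 1, 2), list("r", "boat", 0.5, 9),
                list("r", "rain", 7, 8), list("r", "click", 6, 7))
  segs <- mk_seg("r", 2)
  a <- derive_segment_labels(ann, segs)
  b <- derive_segment_labels(ann[rev(seq_len(nrow(ann))), ], segs)
  expect_identical(a$labels, b$labels)
  expect_identical(a$labels, derive_segment_labels(ann, segs)$labels)
  expect_setequal(a$labels[[2]], c("click", "boat", "rain"))
})

test_that("per-class positives match a brute-force interval oracle", {
  set.seed(31)
  classes <- c("click", "boat", "rain")
  for (rep in 1:20) {
    n_seg <- sample(3:8, 1)
    n_ann <- sample(1:12, 1)
    ann <- annotations(data.frame(
      source_id = "r", class = sample(classes, n_ann, replace = TRUE),
      t_start_s = ts <- runif(n_ann, 0, 5 * n_seg - 0.2),
      t_end_s = ts + runif(n_ann, 0.05, 4),
      f_low_hz = 0, f_high_hz = 48000, stringsAsFactors = FALSE))
    segs <- mk_seg("r", n_seg)
    lab <- suppressWarnings(derive_segment_labels(ann, segs))
    for (i in seq_len(n_seg)) {
      lo <- 5 * (i - 1); hi <- 5 * i
      for (cl in classes) {
        expected <- FALSE
        for (j in seq_len(n_ann)) {
          if (ann$class[j] == cl &&
              min(hi, ann$t_end_s[j]) - max(lo, ann$t_start_s[j]) > 0)
            expected <- TRUE
        }
        expect_equal(cl %in% lab$labels[[i]], expected)
      }
    }
  }
})

test_that("column targets resolve 5/16-s spans and broadcast NA times", {
  seg <- list(source_id = "r", t_start_s = 0)
  full <- derive_column_targets(mk_ann(list("r", "click", 0, 5)), seg)
  expect_equal(unname(full[, "click"]), rep(1L, 16))
  short <- derive_column_targets(mk_ann(list("r", "click", 0, 0.3)), seg)
  expect_equal(unname(short[, "click"]), c(1L, rep(0L, 15)))  # 5/16 = 0.3125 s
  none <- derive_column_targets(mk_ann(list("r", "boat", 20, 25)), seg)
  expect_true(all(none == 0L))
  # segment-level annotation (NA times) broadcasts
  ann_na <- annotations(data.frame(source_id = "r", class = "rain",
                                   t_start_s = NA_real_, t_end_s = NA_real_,
                                   f_low_hz = 0, f_high_hz = 48000))
  bc <- derive_column_targets(ann_na, seg)
  expect_equal(unname(bc[, "rain"]), rep(1L, 16))
  # row-wise OR over columns equals the segment label
  ann2 <- mk_ann(list("r", "click", 1.0, 1.4), list("r", "boat", 2, 5))
  ct <- derive_column_targets(ann2, seg)
  lab <- derive_segment_labels(ann2, mk_seg("r", 1))
  expect_setequal(colnames(ct)[colSums(ct) > 0], lab$labels[[1]])
})

test_that("random 50/50 split is disjoint, seeded, and seed-sensitive", {
  segs <- data.frame(segment_id = sprintf("v%03d", 1:100))
  sp <- split_train_test(segs, "random", seed = 4)
  expect_length(sp$train, 50)
  expect_length(sp$test, 50)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_train_test(segs, "random", seed = 4))
  different <- vapply(1:20, function(s)
    !identical(sort(split_train_test(segs, "random", seed = s)$train),
               sort(sp$train)), TRUE)
  expect_gte(sum(different), 19)   # collisions are overwhelmingly unlikely
})

test_that("unit-based splits keep sessions and days intact", {
  segs <- data.frame(segment_id = sprintf("s%03d", 1:40),
                     session = rep(c("a", "b", "c", "d"), each = 10),
                     date = rep(as.Date("2020-01-01") + 0:3, each = 10))
  for (pol in c("by_session", "by_day")) {
    sp <- split_train_test(segs, pol, seed = 2)
    unit <- if (pol == "by_session") segs$session else as.character(segs$date)
    tr_units <- unique(unit[segs$segment_id %in% sp$train])
    te_units <- unique(unit[segs$segment_id %in% sp$test])
    expect_length(intersect(tr_units, te_units), 0)
  }
  expect_error(split_train_test(segs[, "segment_id", drop = FALSE],
                                "by_session", seed = 1), "session")
})

test_that("annotation tables validate their invariants", {
  expect_error(annotations(data.frame(source_id = "r", class = "click",
                                      t_start_s = 2, t_end_s = 1,
                                      f_low_hz = 0, f_high_hz = 100)),
               "t_start")
  expect_error(annotations(data.frame(source_id = "r", class = "click",
                                      t_start_s = 0, t_end_s = 1,
                                      f_low_hz = 100, f_high_hz = 50)),
               "f_low")
  expect_error(annotations(data.frame(source_id = "r")), "missing columns")
})

test_that("labels_to_matrix encodes multi-label sets", {
  m <- labels_to_matrix(list(c("click", "boat"), character(0), "rain"))
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(unname(m[1, ]), c(1L, 1L, 0L))
  expect_equal(unname(m[2, ]), c(0L, 0L, 0L))
  expect_equal(unname(m[3, ]), c(0L, 0L, 1L))
})

test_that("the annotation store is append-only", {
  p <- file.path(tempdir(), "car.csv")
  unlink(p)
  a1 <- mk_ann(list("r", "click", 0, 1))
  a2 <- mk_ann(list("r", "boat", 2, 3))
  append_annotations(a1, p)
  append_annotations(a2, p)
  back <- read_annotations(p)
  expect_equal(nrow(back), 2)
  expect_equal(back$class, c("click", "boat"))
})
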