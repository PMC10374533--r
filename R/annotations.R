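#' Construct / validate an annotation table
#'
#' Annotations are time-frequency bounding boxes drawn on spectrograms:
#' each row labels one sound event with a single class (`click`, `boat`,
#' `rain`, or a background subtype).  A 5-s segment inherits every class
#' whose box overlaps it in time, so segments are multi-label.
#'
#' @param df data.frame with columns `source_id, class, t_start_s, t_end_s,
#'   f_low_hz, f_high_hz` and optionally `annotator, created_at`.
#' @return the validated data.frame (class `pam_annotations`).
#' @export
annotations <- function(df) {
  need <- c("source_id", "class", "t_start_s", "t_end_s", "f_low_hz",
            "f_high_hz")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation table is missing columns: ",
                         paste(miss, collapse = ", "))
  if (!"annotator" %in% names(df))
    df$annotator <- rep("unknown", nrow(df))
  if (!"created_at" %in% names(df))
    df$created_at <- rep(format(Sys.time(), tz = "UTC"), nrow(df))
  timed <- !is.na(df$t_start_s) & !is.na(df$t_end_s)
  if (any(timed & df$t_start_s >= df$t_end_s))
    stop("annotations must have t_start_s < t_end_s")
  if (any(df$f_low_hz < 0 | df$f_high_hz > 48000 |
          df$f_low_hz >= df$f_high_hz, na.rm = TRUE))
    stop("annotations must have 0 <= f_low_hz < f_high_hz <= 48000")
  class(df) <- c("pam_annotations", "data.frame")
  df
}

#' Read / append annotation CSV (flat, append-only store)
#' @param path CSV path.
#' @return a `pam_annotations` data.frame.
#' @export
read_annotations <- function(path) {
  annotations(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_annotations
#' @param ann annotations to append; rows are only ever added, mimicking an
#'   incremental annotation repository.
#' @export
append_annotations <- function(ann, path) {
  ann <- annotations(as.data.frame(ann))
  if (file.exists(path)) {
    old <- utils::read.csv(path, stringsAsFactors = FALSE)
    ann <- annotations(rbind(old[, names(ann)], as.data.frame(ann)))
  }
  utils::write.csv(as.data.frame(ann), path, row.names = FALSE)
  invisible(path)
}

# segment metadata table from a list of pam_segment
.segment_table <- function(segments) {
  if (is.data.frame(segments)) {
    stopifnot(all(c("segment_id", "source_id", "t_start_s") %in% names(segments)))
    segments$t_end_s <- segments$t_start_s + 5
    return(segments)
  }
  data.frame(
    segment_id = vapply(segments, `[[`, "", "segment_id"),
    source_id = vapply(segments, `[[`, "", "source_id"),
    t_start_s = vapply(segments, function(s) 5 * s$index, 0),
    t_end_s = vapply(segments, function(s) 5 * s$index + 5, 0),
    stringsAsFactors = FALSE)
}

#' Derive multi-label segment labels from bounding boxes
#'
#' A segment carries class `c` iff some annotation of class `c` on the same
#' recording overlaps it in time by more than 0 s.  Background subtypes
#' (classes outside `classes`) never produce a label; a segment with no
#' labels is background.
#'
#' @param ann a [annotations] table.
#' @param segments list of `pam_segment` or a data.frame with `segment_id`,
#'   `source_id`, `t_start_s` (segment start within its recording).
#' @param classes target classes.
#' @return data.frame `segment_id, labels` (list column of character
#'   vectors), `is_background`.
#' @export
derive_segment_labels <- function(ann, segments,
                                  classes = c("click", "boat", "rain")) {
  seg <- .segment_table(segments)
  ann <- as.data.frame(ann)
  keep <- ann$class %in% classes
  ann <- ann[keep & !is.na(ann$t_start_s) & !is.na(ann$t_end_s), , drop = FALSE]
  # warn about annotations that overlap no segment of their recording
  labels <- vector("list", nrow(seg))
  hit <- rep(FALSE, nrow(ann))
  for (i in seq_len(nrow(seg))) {
    ok <- ann$source_id == seg$source_id[i] &
      ann$t_start_s < seg$t_end_s[i] & ann$t_end_s > seg$t_start_s[i]
    hit <- hit | ok
    labels[[i]] <- sort(unique(ann$class[ok]))
  }
  if (any(!hit) && nrow(ann))
    warning(sum(!hit), " annotation(s) overlap no segment and were skipped")
  out <- data.frame(segment_id = seg$segment_id, stringsAsFactors = FALSE)
  out$labels <- labels
  out$is_background <- lengths(labels) == 0L
  out
}

#' Per-column training targets for one segment
#'
#' The classifier emits 16 outputs per class per 5-s segment, one per
#' 5/16-s column.  Column `j` (0-based, spanning `[5j/16, 5(j+1)/16)`
#' seconds within the segment) is positive for class `c` iff an annotation
#' of class `c` overlaps that span.  Annotations with `NA` times
#' (segment-level labels) are broadcast to all 16 columns.
#'
#' @param ann a [annotations] table (rows for this segment's recording).
#' @param segment a `pam_segment`, or a list with `source_id` and
#'   `t_start_s` (start within recording).
#' @param classes target classes (column order of the result).
#' @param n_columns number of output columns (16).
#' @return `n_columns x length(classes)` binary matrix.
#' @export
derive_column_targets <- function(ann, segment,
                                  classes = c("click", "boat", "rain"),
                                  n_columns = 16L) {
  t0 <- if (!is.null(segment$t_start_s)) segment$t_start_s else 5 * segment$index
  src <- segment$source_id
  ann <- as.data.frame(ann)
  ann <- ann[ann$source_id == src & ann$class %in% classes, , drop = FALSE]
  out <- matrix(0L, n_columns, length(classes),
                dimnames = list(NULL, classes))
  if (!nrow(ann)) return(out)
  col_w <- 5 / n_columns
  col_lo <- t0 + (seq_len(n_columns) - 1L) * col_w
  col_hi <- col_lo + col_w
  for (r in seq_len(nrow(ann))) {
    k <- match(ann$class[r], classes)
    if (is.na(ann$t_start_s[r]) || is.na(ann$t_end_s[r])) {
      out[, k] <- 1L                      # segment-level label: broadcast
    } else {
      ov <- ann$t_start_s[r] < col_hi & ann$t_end_s[r] > col_lo
      out[ov, k] <- 1L
    }
  }
  out
}

#' Train/test split policies
#'
#' Splits a segment table into disjoint train and test partitions.  Policy
#' `"random"` performs a seeded 50/50 split by segment (the treatment of
#' floodplain-lake data); `"by_session"` and `"by_day"` keep whole
#' recording sessions / calendar days together (boat-survey and fixed-lodge
#' data), alternating units between partitions after a seeded shuffle.
#'
#' @param segments data.frame with `segment_id` and, per policy, `session`
#'   or `date` columns.
#' @param policy one of `"random"`, `"by_session"`, `"by_day"`.
#' @param seed integer seed; the split is deterministic given the seed.
#' @param train_frac fraction assigned to training under `"random"`.
#' @return list with character vectors `train` and `test` of segment ids.
#' @export
split_train_test <- function(segments, policy = c("random", "by_session",
                                                  "by_day"),
                             seed = 1L, train_frac = 0.5) {
  policy <- match.arg(policy)
  seg <- if (is.data.frame(segments)) segments else .segment_table(segments)
  ids <- seg$segment_id
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (policy == "random") {
    n_tr <- round(length(ids) * train_frac)
    tr <- sample(ids, n_tr)
    return(list(train = tr, test = setdiff(ids, tr)))
  }
  unit_col <- if (policy == "by_session") "session" else "date"
  if (!unit_col %in% names(seg))
    stop("policy '", policy, "' needs a '", unit_col, "' column")
  units <- sample(unique(as.character(seg[[unit_col]])))
  tr_units <- units[seq_along(units) %% 2L == 1L]
  tr <- ids[as.character(seg[[unit_col]]) %in% tr_units]
  list(train = tr, test = setdiff(ids, tr))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Binary label matrix from per-segment label lists
#'
#' @param labels list of character vectors (classes per segment).
#' @param classes column order.
#' @return segments x classes 0/1 matrix.
#' @export
labels_to_matrix <- function(labels, classes = c("click", "boat", "rain")) {
  out <- vapply(classes, function(cl)
    as.integer(vapply(labels, function(l) cl %in% l, TRUE)),
    integer(length(labels)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(labels))
  colnames(out) <- classes
  out
}
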