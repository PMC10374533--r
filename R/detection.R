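#' Per-site decision thresholds
#'
#' Each monitored site carries one decision threshold per class and,
#' optionally, a rain-filter threshold used by the posterior rain filter.
#'
#' @param df data.frame with columns `site, class, threshold` and
#'   optionally `rain_filter_threshold` (one value per site; `NA` disables
#'   the filter there).
#' @return data.frame of class `pam_thresholds`.
#' @export
threshold_table <- function(df) {
  need <- c("site", "class", "threshold")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("threshold table is missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$threshold < 0 | df$threshold > 1))
    stop("thresholds must lie in [0, 1]")
  if (!"rain_filter_threshold" %in% names(df))
    df$rain_filter_threshold <- NA_real_
  class(df) <- c("pam_thresholds", "data.frame")
  df
}

#' Read a per-site threshold configuration (YAML)
#'
#' Expected layout: one block per site with per-class thresholds and an
#' optional `rain_filter`:
#' ```yaml
#' Rato:    {click: 0.85, boat: 0.98, rain_filter: 0.90}
#' Boca:    {click: 0.85, boat: 0.97, rain_filter: 0.99}
#' ```
#' @param path YAML file path.
#' @return a [threshold_table].
#' @export
read_threshold_table <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- do.call(rbind, lapply(names(y), function(site) {
    b <- y[[site]]
    cls <- setdiff(names(b), "rain_filter")
    data.frame(site = site, class = cls,
               threshold = as.numeric(unlist(b[cls])),
               rain_filter_threshold =
                 if (!is.null(b$rain_filter)) as.numeric(b$rain_filter)
               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  threshold_table(rows)
}

.lookup_threshold <- function(thresholds, site, class) {
  i <- thresholds$site == site & thresholds$class == class
  if (!any(i)) stop("no ", class, " threshold configured for site '", site,
                    "'")
  thresholds$threshold[which(i)[1L]]
}

.lookup_rain_filter <- function(thresholds, site) {
  i <- which(thresholds$site == site)
  if (!length(i)) return(NA_real_)
  v <- thresholds$rain_filter_threshold[i]
  v <- v[!is.na(v)]
  if (length(v)) v[1L] else NA_real_
}

#' Apply class thresholds to segment scores
#'
#' @param scores data.frame with `segment_id, site, start_time` and one
#'   `q75_<class>` column per class.
#' @param thresholds a [threshold_table] covering every site present.
#' @param classes classes to threshold.
#' @return `pam_detections` data.frame: the input plus logical
#'   `flag_<class>` columns (`q75 >= threshold`, closed bound) and a
#'   `rain_attributed` column (all `FALSE` until [apply_rain_filter]).
#' @export
threshold_detections <- function(scores, thresholds,
                                 classes = c("click", "boat", "rain")) {
  stopifnot(all(c("segment_id", "site") %in% names(scores)))
  sites <- unique(scores$site)
  for (s in sites) for (cl in intersect(classes, c("click", "boat")))
    .lookup_threshold(thresholds, s, cl)    # fail before processing
  out <- scores
  for (cl in classes) {
    qcol <- paste0("q75_", cl)
    if (!qcol %in% names(scores)) stop("scores lack column ", qcol)
    th <- vapply(out$site, function(s)
      tryCatch(.lookup_threshold(thresholds, s, cl),
               error = function(e) NA_real_), 0)
    out[[paste0("flag_", cl)]] <- !is.na(th) & out[[qcol]] >= th
  }
  out$rain_attributed <- FALSE
  class(out) <- c("pam_detections", "data.frame")
  out
}

#' Classify an archive of segments with a trained model
#'
#' Runs the classifier over every segment, pools each class's 16 outputs
#' with the Q75 summary, and applies the per-site decision thresholds.
#' One record per segment, order preserved.
#'
#' @param object a fitted [fit_pam_cnn] model.
#' @param x `512 x 128 x N` feature array.
#' @param meta data.frame with `segment_id, site, start_time` (N rows).
#' @param thresholds a [threshold_table].
#' @param classes class names matching the model outputs.
#' @return a `pam_detections` data.frame.
#' @export
classify_archive <- function(object, x, meta, thresholds,
                             classes = c("click", "boat", "rain")) {
  stopifnot(nrow(meta) == dim(x)[3])
  q <- segment_scores(object, x, classes = classes)
  sc <- meta
  for (k in seq_along(classes)) sc[[paste0("q75_", classes[k])]] <- q[, k]
  threshold_detections(sc, thresholds, classes)
}

#' Posterior rain filter
#'
#' Rain is classified more reliably than clicks, so a segment whose click
#' flag is set *and* whose rain score reaches the site's rain-filter
#' threshold is attributed to rain: the click flag is cleared and
#' `rain_attributed` set.  Boat flags are untouched.  Sites without a
#' configured rain-filter threshold are skipped (logged via message).
#'
#' @param records a `pam_detections` data.frame.
#' @param thresholds a [threshold_table] carrying
#'   `rain_filter_threshold` per site.
#' @return the filtered records.
#' @export
apply_rain_filter <- function(records, thresholds) {
  stopifnot(all(c("flag_click", "q75_rain", "site") %in% names(records)))
  for (s in unique(records$site)) {
    rf <- .lookup_rain_filter(thresholds, s)
    if (is.na(rf)) {
      message("site '", s, "': no rain-filter threshold, filter skipped")
      next
    }
    i <- records$site == s & records$flag_click & records$q75_rain >= rf
    records$flag_click[i] <- FALSE
    records$rain_attributed[i] <- TRUE
  }
  records
}

#' Sample positively classified segments for manual review
#'
#' Draws `n` segments uniformly without replacement from the records
#' classified positive for `class` (score at or above `threshold`), for
#' the active-learning review step.  Optionally exports a 5-s WAV snippet
#' and a rendered spectrogram per sampled segment.
#'
#' @param records a `pam_detections` data.frame.
#' @param class class under review.
#' @param threshold review threshold (defaults to using the existing
#'   flags).
#' @param n number of segments to draw.
#' @param seed RNG seed.
#' @param export_dir optional directory for WAV + PNG exports.
#' @param audio optional named list of `pam_segment`s (by `segment_id`)
#'   used for the exports.
#' @return the sampled rows, with attribute `exported` listing files.
#' @export
sample_for_review <- function(records, class = "click", threshold = NULL,
                              n = 10L, seed = 1L, export_dir = NULL,
                              audio = NULL) {
  qcol <- paste0("q75_", class)
  pos <- if (is.null(threshold)) which(records[[paste0("flag_", class)]])
  else which(records[[qcol]] >= threshold)
  if (!length(pos)) stop("no positively classified segments for ", class)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (length(pos) < n) {
    warning("only ", length(pos), " positives available; returning all")
    sel <- pos
  } else sel <- sample(pos, n)
  out <- records[sel, , drop = FALSE]
  exported <- character()
  if (!is.null(export_dir) && !is.null(audio)) {
    dir.create(export_dir, showWarnings = FALSE, recursive = TRUE)
    for (id in out$segment_id) {
      seg <- audio[[id]]
      if (is.null(seg)) next
      wv <- pam_wave(seg$samples, seg$rate_hz, seg$start_time, seg$source_id)
      wp <- file.path(export_dir, paste0(id, ".wav"))
      write_wav(wv, wp)
      pp <- file.path(export_dir, paste0(id, ".png"))
      grDevices::png(pp, width = 800, height = 300)
      plot_mel(segment_features(seg), main = id)
      grDevices::dev.off()
      exported <- c(exported, wp, pp)
    }
  }
  attr(out, "exported") <- exported
  out
}

#' Merge reviewed verdicts back into a training set
#'
#' Confirmed detections keep their class; misclassifications enter with
#' their corrected classes (e.g. rain).  Records whose `segment_id` is
#' already in the training set are rejected, so merging the same review
#' batch twice adds nothing.  Rows without a verdict are skipped with a
#' warning.
#'
#' @param train_set data.frame `segment_id, labels` (list column).
#' @param reviewed data.frame `segment_id, verdict` where `verdict` is a
#'   list column (or `;`-separated string) of true classes; empty =
#'   background.
#' @return the expanded train_set.
#' @export
merge_corrections <- function(train_set, reviewed) {
  stopifnot(all(c("segment_id", "labels") %in% names(train_set)),
            all(c("segment_id", "verdict") %in% names(reviewed)))
  verd <- reviewed$verdict
  if (!is.list(verd))
    verd <- lapply(strsplit(as.character(verd), ";", fixed = TRUE),
                   function(v) v[nzchar(v)])
  missing_verdict <- vapply(seq_len(nrow(reviewed)), function(i)
    is.null(verd[[i]]) || anyNA(verd[[i]]), TRUE)
  if (any(missing_verdict))
    warning(sum(missing_verdict), " reviewed record(s) lack a verdict; skipped")
  keep <- !missing_verdict & !(reviewed$segment_id %in% train_set$segment_id)
  dup <- !missing_verdict & !keep
  if (any(dup))
    message(sum(dup), " record(s) already in the training set; skipped")
  if (!any(keep)) return(train_set)
  add <- data.frame(segment_id = reviewed$segment_id[keep],
                    stringsAsFactors = FALSE)
  add$labels <- verd[keep]
  rbind(train_set, add)
}

#' Write detections to CSV
#' @param records a `pam_detections` data.frame.
#' @param path output CSV.
#' @export
write_detections <- function(records, path) {
  out <- as.data.frame(records)
  if (inherits(out$start_time, "POSIXct"))
    out$start_time <- format(out$start_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read detections CSV written by [write_detections]
#' @param path CSV path.
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("start_time" %in% names(df))
    df$start_time <- as.POSIXct(df$start_time, format = "%Y-%m-%dT%H:%M:%SZ",
                                tz = "UTC")
  class(df) <- c("pam_detections", "data.frame")
  df
}
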