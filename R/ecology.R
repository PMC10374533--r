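#' Daily acoustic presence
#'
#' Converts thresholded detection records into a per-site, per-day
#' proportion: the daily duration with acoustic occurrences (5 s per
#' positive segment, segments are non-overlapping by construction) divided
#' by the total daily recording duration.  Reporting a proportion
#' compensates for differences in recording duty cycles between sites.
#'
#' @param records a `pam_detections` data.frame with `site`, `start_time`
#'   and `flag_<class>` columns.
#' @param schedule data.frame (see [read_schedule]) with `source_id, date,
#'   recorded_minutes`; `source_id` matches `site`.
#' @param classes classes to report.
#' @return data.frame `site, date, class, recorded_min, positive_min,
#'   proportion`; days with zero recorded minutes but detections raise an
#'   error, days with recording and no detections report 0.
#' @export
daily_presence <- function(records, schedule,
                           classes = c("click", "boat", "rain")) {
  stopifnot(all(c("site", "start_time") %in% names(records)))
  rec_date <- as.Date(records$start_time, tz = "UTC")
  out <- list()
  for (i in seq_len(nrow(schedule))) {
    site <- schedule$source_id[i]; day <- schedule$date[i]
    rm_min <- schedule$recorded_minutes[i]
    sub <- records[records$site == site & rec_date == day, , drop = FALSE]
    if (rm_min <= 0 && nrow(sub) > 0)
      stop("site ", site, " on ", day,
           " has detections but zero scheduled recording")
    for (cl in classes) {
      fcol <- paste0("flag_", cl)
      npos <- if (nrow(sub)) sum(sub[[fcol]]) else 0L
      pos_min <- npos * 5 / 60
      out[[length(out) + 1L]] <- data.frame(
        site = site, date = day, class = cl,
        recorded_min = rm_min, positive_min = pos_min,
        proportion = if (rm_min > 0) pos_min / rm_min else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("pam_presence", "data.frame")
  res
}

#' Positive minutes per hour
#'
#' Counts, per site / date / hour-of-day, the calendar minutes containing
#' at least one positive segment of a class.  Under a 1-min-on/9-min-off
#' duty cycle at most 6 recorded minutes exist per hour, which caps this
#' count.
#'
#' @param records a `pam_detections` data.frame.
#' @param class class to count.
#' @return data.frame `site, date, hour, positive_min, recorded_min`
#'   (recorded minutes = minutes containing any segment).
#' @export
positive_minutes <- function(records, class = "click") {
  fcol <- paste0("flag_", class)
  stopifnot(fcol %in% names(records))
  minute <- trunc(records$start_time, "mins")
  key <- data.frame(site = records$site,
                    date = as.Date(records$start_time, tz = "UTC"),
                    hour = as.integer(format(records$start_time, "%H",
                                             tz = "UTC")),
                    minute = as.numeric(minute))
  agg_rec <- stats::aggregate(minute ~ site + date + hour,
                              data = cbind(key, minute = key$minute),
                              FUN = function(m) length(unique(m)))
  pos <- key[records[[fcol]], , drop = FALSE]
  if (nrow(pos)) {
    agg_pos <- stats::aggregate(minute ~ site + date + hour, data = pos,
                                FUN = function(m) length(unique(m)))
  } else {
    agg_pos <- agg_rec[0, ]
  }
  names(agg_rec)[4] <- "recorded_min"
  names(agg_pos)[4] <- "positive_min"
  out <- merge(agg_rec, agg_pos, by = c("site", "date", "hour"),
               all.x = TRUE)
  out$positive_min[is.na(out$positive_min)] <- 0L
  out[order(out$site, out$date, out$hour), ]
}

#' Dolphin-boat co-occurrence minutes
#'
#' A calendar minute co-occurs when at least one click-positive segment
#' and at least one boat-positive segment start within it.  Returns the
#' per (site, date, hour) co-occurrence minutes together with the recorded
#' minutes, plus summary statistics (mean and SD of per-hour co-occurrence
#' minutes and the percentage of recorded minutes with co-occurrence).
#'
#' @param records a `pam_detections` data.frame with click and boat flags.
#' @return list with `by_hour` (data.frame `site, date, hour, cooccur_min,
#'   recorded_min`), `mean`, `sd`, `percent_of_recorded`.
#' @export
cooccurrence_minutes <- function(records) {
  stopifnot(all(c("flag_click", "flag_boat") %in% names(records)))
  minute <- as.numeric(trunc(records$start_time, "mins"))
  df <- data.frame(site = records$site,
                   date = as.Date(records$start_time, tz = "UTC"),
                   hour = as.integer(format(records$start_time, "%H",
                                            tz = "UTC")),
                   minute = minute,
                   click = records$flag_click, boat = records$flag_boat)
  per_min <- stats::aggregate(cbind(click, boat) ~ site + date + hour + minute,
                              data = df, FUN = any)
  per_min$cooccur <- as.integer(per_min$click & per_min$boat)
  per_min$one <- 1L
  by_hour <- stats::aggregate(cbind(cooccur_min = cooccur, recorded_min = one)
                              ~ site + date + hour, data = per_min, FUN = sum)
  by_hour <- by_hour[order(by_hour$site, by_hour$date, by_hour$hour), ]
  total_min <- sum(by_hour$recorded_min)
  co_min <- sum(by_hour$cooccur_min)
  list(by_hour = by_hour,
       mean = mean(by_hour$cooccur_min),
       sd = stats::sd(by_hour$cooccur_min),
       percent_of_recorded = if (total_min > 0) 100 * co_min / total_min
       else NA_real_)
}

#' Day/night activity comparison (rank-sum test)
#'
#' For each day in one calendar month, counts positive segments in the day
#' period (dawn to dusk) and the night period, scales each count by the
#' period duration in minutes (day length changes over the year), and
#' compares the two per-day rate distributions with a two-sided Wilcoxon
#' rank-sum test (exact for small samples without ties, normal
#' approximation with tie correction otherwise).
#'
#' @param records a `pam_detections` data.frame.
#' @param class class to test.
#' @param dawn,dusk either `"HH:MM"` strings applied to every day or a
#'   data.frame `date, dawn, dusk` of per-day boundary times (UTC).
#' @param month month to test, `"YYYY-MM"`; default: all records.
#' @param alpha significance level for the reported decision.
#' @return list of class `pam_daynight`: `month, n_days, day_rates,
#'   night_rates, statistic, p_value, significant`; or a skip reason when
#'   a period has no recording.
#' @export
day_night_test <- function(records, class = "click", dawn = "06:00",
                           dusk = "18:00", month = NULL, alpha = 0.05) {
  fcol <- paste0("flag_", class)
  stopifnot(fcol %in% names(records))
  tt <- records$start_time
  if (!is.null(month)) {
    keep <- format(tt, "%Y-%m", tz = "UTC") == month
    records <- records[keep, , drop = FALSE]
    tt <- records$start_time
  }
  if (!nrow(records))
    return(structure(list(month = month, skipped = "no records"),
                     class = "pam_daynight"))
  dates <- as.Date(tt, tz = "UTC")
  bounds <- function(d) {
    if (is.data.frame(dawn)) {
      i <- match(d, as.Date(dawn$date))
      c(dawn$dawn[i], dawn$dusk[i])
    } else c(dawn, dusk)
  }
  day_rates <- night_rates <- numeric(0)
  for (d in sort(unique(dates))) {
    d <- as.Date(d, origin = "1970-01-01")
    b <- bounds(d)
    t_dawn <- as.POSIXct(paste(d, b[1]), tz = "UTC")
    t_dusk <- as.POSIXct(paste(d, b[2]), tz = "UTC")
    day_min <- as.numeric(difftime(t_dusk, t_dawn, units = "mins"))
    night_min <- 1440 - day_min
    sub <- records[dates == d, , drop = FALSE]
    in_day <- sub$start_time >= t_dawn & sub$start_time < t_dusk
    # a day participates only when both periods were recorded
    if (!any(in_day) && !any(!in_day)) next
    if (sum(in_day) + sum(!in_day) == 0) next
    if (!any(in_day) || !any(!in_day)) next
    day_rates <- c(day_rates, sum(sub[[fcol]][in_day]) / day_min)
    night_rates <- c(night_rates, sum(sub[[fcol]][!in_day]) / night_min)
  }
  if (length(day_rates) < 2L)
    return(structure(list(month = month, skipped =
                            "fewer than 2 days with both day and night recording"),
                     class = "pam_daynight"))
  wt <- .ranksum_test(day_rates, night_rates)
  structure(list(month = month, n_days = length(day_rates),
                 day_rates = day_rates, night_rates = night_rates,
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 significant = wt$p.value < alpha, alpha = alpha),
            class = "pam_daynight")
}

# Two-sided rank-sum test. For small samples the p-value is computed by
# complete enumeration of the permutation distribution of the rank sum,
# which handles ties exactly (fully tied data gives p = 1); larger samples
# fall back to the normal approximation with tie correction.
.ranksum_test <- function(x, y, enumerate_max = 20L) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  rk <- rank(c(x, y))
  w_obs <- sum(rk[seq_len(n1)])
  u_obs <- w_obs - n1 * (n1 + 1) / 2          # Mann-Whitney statistic
  if (N <= enumerate_max) {
    mu <- n1 * (N + 1) / 2
    sets <- utils::combn(N, n1)
    ws <- colSums(matrix(rk[sets], nrow = n1))
    p <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
  } else {
    p <- suppressWarnings(stats::wilcox.test(x, y,
                                             alternative = "two.sided",
                                             exact = FALSE,
                                             correct = TRUE))$p.value
    if (is.nan(p)) p <- 1                     # fully tied large samples
  }
  list(statistic = u_obs, p.value = p)
}

#' @export
print.pam_daynight <- function(x, ...) {
  if (!is.null(x$skipped)) {
    cat("day/night test", if (!is.null(x$month)) paste0(" (", x$month, ")"),
        ": skipped - ", x$skipped, "\n", sep = "")
  } else {
    cat(sprintf(
      "day/night rank-sum test%s: N = %d days, W = %g, p = %.4f (%s at alpha %.2f)\n",
      if (!is.null(x$month)) paste0(" (", x$month, ")") else "",
      x$n_days, x$statistic, x$p_value,
      if (x$significant) "significant" else "not significant", x$alpha))
  }
  invisible(x)
}

#' Sunrise/sunset from latitude, longitude and date
#'
#' Standard solar-elevation sunrise equation (zenith 90.83 degrees);
#' adequate for tropical study sites where civil day length varies little.
#'
#' @param date a `Date`.
#' @param lat,lon site coordinates in degrees.
#' @return list with `dawn` and `dusk` `POSIXct` (UTC).
#' @export
solar_daylight <- function(date, lat, lon) {
  n <- as.numeric(date - as.Date("2000-01-01")) + 0.5
  jstar <- n - lon / 360
  M <- (357.5291 + 0.98560028 * jstar) %% 360
  C <- 1.9148 * sin(M * pi / 180) + 0.02 * sin(2 * M * pi / 180) +
    0.0003 * sin(3 * M * pi / 180)
  lambda <- (M + C + 180 + 102.9372) %% 360
  jtransit <- jstar + 0.0053 * sin(M * pi / 180) -
    0.0069 * sin(2 * lambda * pi / 180)
  delta <- asin(sin(lambda * pi / 180) * sin(23.44 * pi / 180))
  cosw <- (sin(-0.83 * pi / 180) - sin(lat * pi / 180) * sin(delta)) /
    (cos(lat * pi / 180) * cos(delta))
  cosw <- pmin(pmax(cosw, -1), 1)
  w <- acos(cosw) * 180 / pi
  rise <- jtransit - w / 360
  set <- jtransit + w / 360
  epoch <- as.POSIXct("2000-01-01 12:00:00", tz = "UTC")
  list(dawn = epoch + rise * 86400, dusk = epoch + set * 86400)
}
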