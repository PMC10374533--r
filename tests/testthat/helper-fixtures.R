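# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

# small labeled corpus used across module tests (~30 s to build)
fixture_corpus <- function() {
  if (is.null(.fixture_env$corpus)) {
    .fixture_env$corpus <- make_training_corpus(
      n_click = 24L, n_boat = 10L, n_rain = 8L, n_background = 26L,
      seed = 202L)
  }
  .fixture_env$corpus
}

# deterministic toy detection records spanning two days at one site
fixture_records <- function(seed = 5L, n = 240L, site = "toysite",
                            p_click = 0.3, p_boat = 0.2, p_rain = 0.1) {
  set.seed(seed)
  start <- as.POSIXct("2020-02-01 00:00:00", tz = "UTC")
  # one 5-s segment per minute start (duty-style sampling)
  times <- start + 60 * seq_len(n)
  data.frame(
    segment_id = sprintf("%s_%04d", site, seq_len(n)),
    site = site,
    start_time = times,
    q75_click = runif(n), q75_boat = runif(n), q75_rain = runif(n),
    flag_click = runif(n) < p_click,
    flag_boat = runif(n) < p_boat,
    flag_rain = runif(n) < p_rain,
    rain_attributed = FALSE,
    stringsAsFactors = FALSE)
}

# brute-force median of a vector by explicit sorting (independent of
# stats::median internals beyond ordering)
oracle_median <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

# independent AP oracle: explicit confusion counting at every unique
# threshold (descending recall ordering) and rectangle summation
oracle_average_precision <- function(labels, scores) {
  labels <- as.integer(labels != 0)
  th <- sort(unique(scores))
  pts <- t(vapply(th, function(t) {
    pred <- scores >= t
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(labels)) {
      if (pred[i] && labels[i] == 1) tp <- tp + 1
      if (pred[i] && labels[i] == 0) fp <- fp + 1
      if (!pred[i] && labels[i] == 1) fn <- fn + 1
    }
    c(tpr = tp / (tp + fn), ppv = if (tp + fp > 0) tp / (tp + fp) else 1)
  }, c(tpr = 0, ppv = 0)))
  tpr <- c(pts[, "tpr"], 0)
  ap <- 0
  for (t in seq_len(nrow(pts)))
    ap <- ap + (tpr[t] - tpr[t + 1]) * pts[t, "ppv"]
  unname(ap)
}
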