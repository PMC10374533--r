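#' Augmentation policy
#'
#' Controls training-set expansion: oversampling duplicates whole segments
#' containing under-represented classes until every class has at least
#' `min_labels_per_epoch` labels (default 300), and four on-the-fly
#' spectrogram transforms perturb each duplicated matrix every epoch.
#'
#' @param min_labels_per_epoch minimum per-class label count after
#'   oversampling.
#' @param max_freq_shift_bands maximum circular shift along the Mel axis.
#' @param max_time_shift_frames maximum circular shift along the time axis.
#' @param contrast_exponent_range range of the power-scaling exponent
#'   applied to the (log-domain) matrix.
#' @param time_warp_factor_range range of the time-stretch factor.
#' @return a list of class `pam_augment_policy`.
#' @export
augment_policy <- function(min_labels_per_epoch = 300L,
                           max_freq_shift_bands = 4L,
                           max_time_shift_frames = 16L,
                           contrast_exponent_range = c(0.8, 1.2),
                           time_warp_factor_range = c(0.9, 1.1)) {
  stopifnot(max_freq_shift_bands >= 0, max_time_shift_frames >= 0,
            all(time_warp_factor_range > 0),
            diff(contrast_exponent_range) >= 0,
            diff(time_warp_factor_range) >= 0)
  structure(list(min_labels_per_epoch = as.integer(min_labels_per_epoch),
                 max_freq_shift_bands = as.integer(max_freq_shift_bands),
                 max_time_shift_frames = as.integer(max_time_shift_frames),
                 contrast_exponent_range = contrast_exponent_range,
                 time_warp_factor_range = time_warp_factor_range),
            class = "pam_augment_policy")
}

#' Oversample under-represented classes
#'
#' Whole segments containing a class with fewer than
#' `min_labels_per_epoch` labels are duplicated cyclically until the class
#' reaches the minimum.  Because segments are multi-label, duplication may
#' also raise other classes' counts; classes are processed from rarest to
#' most common so earlier duplication is taken into account.
#'
#' @param labels list of character vectors: classes present per segment
#'   (empty = background).
#' @param policy an [augment_policy].
#' @param classes classes subject to the minimum.
#' @return integer vector of segment indices (original order first, then
#'   duplicates), with attribute `counts` holding the final per-class label
#'   counts.
#' @export
oversample <- function(labels, policy = augment_policy(),
                       classes = c("click", "boat", "rain")) {
  idx <- seq_along(labels)
  counts <- vapply(classes, function(cl)
    sum(vapply(labels, function(l) cl %in% l, TRUE)), 0L)
  zero <- classes[counts == 0L]
  if (length(zero))
    stop("cannot oversample class(es) with zero labels: ",
         paste(zero, collapse = ", "))
  min_n <- policy$min_labels_per_epoch
  out <- idx
  for (cl in classes[order(counts)]) {
    cur <- sum(vapply(labels[out], function(l) cl %in% l, TRUE))
    if (cur >= min_n) next
    members <- idx[vapply(labels, function(l) cl %in% l, TRUE)]
    need <- min_n - cur
    reps <- rep(members, length.out = need)
    out <- c(out, reps)
  }
  final <- vapply(classes, function(cl)
    sum(vapply(labels[out], function(l) cl %in% l, TRUE)), 0L)
  attr(out, "counts") <- final
  out
}

#' On-the-fly spectrogram transforms
#'
#' Applies, in fixed order, (1) time-warp: linear stretch along the time
#' axis by a factor drawn from `time_warp_factor_range`, clipped or
#' circularly continued back to the original length; (2) circular time
#' shift; (3) circular frequency shift; (4) contrast: scaling of the
#' (log-power, equalized) matrix by an exponent drawn from
#' `contrast_exponent_range`.  Parameters are drawn from R's RNG, so
#' results are reproducible under `set.seed`.
#'
#' @param m `512 x 128` (time x Mel) matrix.
#' @param policy an [augment_policy].
#' @return transformed matrix of identical shape.
#' @export
transform_mel <- function(m, policy = augment_policy()) {
  nt <- nrow(m); nf <- ncol(m)
  # 1. time warp
  f <- stats::runif(1, policy$time_warp_factor_range[1],
                    policy$time_warp_factor_range[2])
  if (abs(f - 1) > 1e-12) {
    L <- max(2L, round(nt * f))
    src <- seq(1, nt, length.out = L)
    i0 <- pmin(floor(src), nt - 1L); frac <- src - i0
    w <- m[i0, , drop = FALSE] * (1 - frac) + m[i0 + 1L, , drop = FALSE] * frac
    if (L >= nt) m <- w[seq_len(nt), , drop = FALSE]
    else m <- rbind(w, w[seq_len(nt - L), , drop = FALSE])
  }
  # 2. circular time shift
  if (policy$max_time_shift_frames > 0) {
    k <- sample(-policy$max_time_shift_frames:policy$max_time_shift_frames, 1L)
    if (k != 0) m <- m[((seq_len(nt) - 1L - k) %% nt) + 1L, , drop = FALSE]
  }
  # 3. circular frequency shift
  if (policy$max_freq_shift_bands > 0) {
    k <- sample(-policy$max_freq_shift_bands:policy$max_freq_shift_bands, 1L)
    if (k != 0) m <- m[, ((seq_len(nf) - 1L - k) %% nf) + 1L, drop = FALSE]
  }
  # 4. contrast (power-law on linear power = scaling in the log domain)
  g <- stats::runif(1, policy$contrast_exponent_range[1],
                    policy$contrast_exponent_range[2])
  m * g
}

#' Circularly shift a matrix (exposed for testing)
#' @param m matrix; `k` shift (positive = toward higher indices);
#'   `axis` 1 = time (rows), 2 = frequency (columns).
#' @keywords internal
#' @export
circular_shift <- function(m, k, axis = 1L) {
  n <- dim(m)[axis]
  pos <- ((seq_len(n) - 1L - k) %% n) + 1L
  if (axis == 1L) m[pos, , drop = FALSE] else m[, pos, drop = FALSE]
}
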