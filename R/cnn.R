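#' CNN architecture specification
#'
#' Five identical convolution blocks (two 3x3 convolutions with ReLU, each
#' preceded by batch normalisation, then non-overlapping 2x2 max pooling)
#' with per-block filter counts, followed by a head of two 1x1
#' ("kernel size 1") convolutions over the resulting 16-step sequence and a
#' sigmoid output layer.  A 512 x 128 input is reduced by the five poolings
#' to 16 x 4; the 4 x `filters[5]` feature maps at each of the 16 time
#' steps are flattened into the head, which emits 16 sigmoid values per
#' class.
#'
#' @param filters filter counts of the five blocks (reference model:
#'   32, 64, 96, 128, 160).
#' @param head_filters filters of the two head convolutions (reference
#'   model: 256).
#' @param n_classes number of output classes.
#' @param input_frames,input_bands input image size; both must be
#'   divisible by 32.
#' @return a list of class `pam_network_spec`.
#' @export
network_spec <- function(filters = c(32L, 64L, 96L, 128L, 160L),
                         head_filters = 256L, n_classes = 3L,
                         input_frames = 512L, input_bands = 128L) {
  stopifnot(length(filters) == 5L, all(filters > 0), head_filters > 0,
            n_classes >= 1L, input_frames %% 32L == 0L,
            input_bands %% 32L == 0L)
  structure(list(filters = as.integer(filters),
                 head_filters = as.integer(head_filters),
                 n_classes = as.integer(n_classes),
                 input_frames = as.integer(input_frames),
                 input_bands = as.integer(input_bands)),
            class = "pam_network_spec")
}

#' Reduced specification for desk-scale experiments
#' @param ... overrides passed to [network_spec].
#' @export
network_spec_small <- function(...) {
  network_spec(filters = c(8L, 16L, 24L, 32L, 40L), head_filters = 64L, ...)
}

#' @export
print.pam_network_spec <- function(x, ...) {
  cat(sprintf(paste0("<network spec> %dx%d input, blocks (%s) x2 conv 3x3 + ",
                     "2x2 pool, head 2x%d (1x1) -> %d sigmoid outputs x %d steps\n"),
              x$input_frames, x$input_bands,
              paste(x$filters, collapse = ","), x$head_filters, x$n_classes,
              x$input_frames %/% 32L))
  invisible(x)
}

# build the native network and return its pointer
.build_net <- function(spec) {
  .cnn_new(spec$filters, spec$head_filters, spec$n_classes,
           spec$input_frames, spec$input_bands)
}

# lazily (re)materialize the native pointer of a fitted model
.net_ptr <- function(object) {
  ptr <- object$env$ptr
  if (is.null(ptr) || isTRUE(tryCatch(.cnn_n_weights(ptr) < 0,
                                      error = function(e) TRUE))) {
    ptr <- .build_net(object$spec)
    .cnn_set_state(ptr, object$state)
    object$env$ptr <- ptr
  }
  ptr
}

#' Number of trainable parameters implied by a spec
#' @param spec a [network_spec].
#' @return parameter count (weights, biases, batch-norm scales/offsets).
#' @export
n_parameters <- function(spec) {
  ptr <- .build_net(spec)
  .cnn_n_params(ptr)
}

#' Fit the spectrogram CNN
#'
#' Trains with summed binary cross-entropy (over the 16 output columns, the
#' classes, and the batch) and the Adam optimizer (lr 1e-3 by default).
#' Oversampling and the four on-the-fly transforms of `policy` are applied
#' per epoch when a policy is supplied; the whole (expanded) training set
#' passes through freshly drawn transforms each epoch.  All randomness
#' (init, shuffling, augmentation) flows from `seed`, so a fit is
#' reproducible.
#'
#' @param x `512 x 128 x N` array of equalized log-Mel matrices.
#' @param y `N`-list of `16 x n_classes` binary target matrices, or an
#'   `N x 16 x n_classes` array.
#' @param spec a [network_spec].
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate: a scalar, or a vector of per-epoch rates
#'   (recycled to `epochs`) for stepped decay schedules.
#' @param recalibrate_bn refresh the batch-norm running statistics with a
#'   pass over the (unaugmented) training set after the last epoch, so
#'   inference statistics reflect the final weights.
#' @param swa_last average the weights of the last `swa_last` epoch-end
#'   snapshots (stochastic weight averaging) before the batch-norm
#'   refresh; 0 disables. Averaging flattens the epoch-to-epoch
#'   oscillation of a constant-rate Adam trajectory.
#' @param policy optional [augment_policy]; `labels` (per-segment class
#'   list) must be given for oversampling.
#' @param labels list of per-segment class vectors (for oversampling).
#' @param seed integer seed.
#' @param verbose print per-epoch loss.
#' @return object of class `pam_cnn` with the trained `state`, the `spec`,
#'   and a training `history` (data.frame epoch/loss).
#' @export
fit_pam_cnn <- function(x, y, spec = network_spec(), epochs = 10L,
                        batch_size = 16L, lr = 1e-3, policy = NULL,
                        labels = NULL, seed = 1L, recalibrate_bn = TRUE,
                        swa_last = 0L, verbose = FALSE) {
  stopifnot(length(dim(x)) == 3L,
            dim(x)[1] == spec$input_frames, dim(x)[2] == spec$input_bands)
  N <- dim(x)[3]
  if (N == 0L) stop("empty training set")
  if (is.array(y) && length(dim(y)) == 3L)
    y <- lapply(seq_len(dim(y)[1]), function(i) y[i, , ])
  stopifnot(length(y) == N)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ptr <- .build_net(spec)
  .cnn_init_weights(ptr, stats::rnorm(.cnn_n_weights(ptr)))

  base_idx <- seq_len(N)
  if (!is.null(policy)) {
    if (is.null(labels)) stop("oversampling needs per-segment labels")
    base_idx <- as.integer(oversample(labels, policy))
  }
  lr_sched <- rep_len(lr, epochs)
  snaps <- list()
  hist <- data.frame(epoch = integer(), loss = numeric(), lr = numeric())
  for (ep in seq_len(epochs)) {
    ord <- sample(base_idx)
    ep_loss <- 0
    b0 <- 1L
    while (b0 <= length(ord)) {
      b1 <- min(b0 + batch_size - 1L, length(ord))
      ids <- ord[b0:b1]
      B <- length(ids)
      xb <- x[, , ids, drop = FALSE]
      if (!is.null(policy)) {
        for (j in seq_len(B)) xb[, , j] <- transform_mel(xb[, , j], policy)
      }
      yb <- do.call(rbind, y[ids])
      ep_loss <- ep_loss +
        .cnn_train_batch(ptr, as.numeric(xb), yb, B, lr_sched[ep])
      b0 <- b1 + 1L
    }
    if (!is.finite(ep_loss)) stop("training diverged (non-finite loss)")
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss,
                                   lr = lr_sched[ep]))
    if (swa_last > 0L && ep > epochs - swa_last) {
      snaps[[length(snaps) + 1L]] <- .cnn_get_state(ptr)
    }
    if (verbose) message(sprintf("epoch %d: summed BCE %.2f", ep, ep_loss))
  }
  if (swa_last > 0L && length(snaps) > 1L) {
    avg <- snaps[[length(snaps)]]
    wkeys <- grep("^(W|wb|g|bb)[0-9]+$", names(avg), value = TRUE)
    for (k in wkeys) {
      acc <- snaps[[1L]][[k]]
      for (j in 2:length(snaps)) acc <- acc + snaps[[j]][[k]]
      avg[[k]] <- acc / length(snaps)
    }
    .cnn_set_state(ptr, avg)
  }
  if (recalibrate_bn && epochs > 0L) {
    b0 <- 1L
    while (b0 <= N) {
      b1 <- min(b0 + batch_size - 1L, N)
      .cnn_update_stats(ptr, as.numeric(x[, , b0:b1, drop = FALSE]),
                        b1 - b0 + 1L)
      b0 <- b1 + 1L
    }
  }
  state <- .cnn_get_state(ptr)
  env <- new.env(parent = emptyenv()); env$ptr <- ptr
  structure(list(spec = spec, state = state, history = hist,
                 n_train = N, epochs = epochs, batch_size = batch_size,
                 lr = lr, seed = seed, env = env,
                 n_params = .cnn_n_params(ptr)),
            class = "pam_cnn")
}

#' Forward pass: per-column sigmoid scores
#'
#' Deterministic inference (batch-norm running statistics).  Returns the
#' raw 16 per-class outputs for each segment; pool them with
#' [q75_summarize] (see [segment_scores]) for segment-level decisions.
#'
#' @param object a fitted `pam_cnn` (or one freshly built via
#'   [fit_pam_cnn] with 0 epochs).
#' @param x a single `512 x 128` matrix or a `512 x 128 x N` array.
#' @param batch_size inference batch size.
#' @param ... unused.
#' @return `N x 16 x n_classes` array of scores in (0, 1).
#' @export
predict.pam_cnn <- function(object, x, batch_size = 16L, ...) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  spec <- object$spec
  stopifnot(dim(x)[1] == spec$input_frames, dim(x)[2] == spec$input_bands)
  N <- dim(x)[3]
  ptr <- .net_ptr(object)
  steps <- spec$input_frames %/% 32L
  out <- array(NA_real_, c(N, steps, spec$n_classes))
  b0 <- 1L
  while (b0 <= N) {
    b1 <- min(b0 + batch_size - 1L, N)
    B <- b1 - b0 + 1L
    p <- .cnn_forward(ptr, as.numeric(x[, , b0:b1, drop = FALSE]), B)
    for (j in seq_len(B))
      out[b0 + j - 1L, , ] <- p[((j - 1L) * steps + 1L):(j * steps), ,
                                drop = FALSE]
    b0 <- b1 + 1L
  }
  out
}

#' Segment-level Q75 scores
#'
#' @param object a fitted `pam_cnn`.
#' @param x `512 x 128 x N` feature array.
#' @param classes class names for the result columns.
#' @param ... passed to [predict.pam_cnn].
#' @return `N x n_classes` matrix of Q75 scores.
#' @export
segment_scores <- function(object, x, classes = NULL, ...) {
  raw <- predict(object, x, ...)
  out <- apply(raw, c(1, 3), q75_summarize)
  if (is.null(dim(out))) out <- matrix(out, nrow = dim(raw)[1])
  if (!is.null(classes)) colnames(out) <- classes
  out
}

#' @export
print.pam_cnn <- function(x, ...) {
  cat("Spectrogram CNN classifier\n")
  print(x$spec)
  cat(sprintf("  %s parameters; trained %d epochs on %d segments (seed %d)\n",
              format(x$n_params, big.mark = ","), x$epochs, x$n_train,
              x$seed))
  if (nrow(x$history))
    cat(sprintf("  final summed BCE: %.2f\n", utils::tail(x$history$loss, 1)))
  invisible(x)
}

#' @export
summary.pam_cnn <- function(object, ...) {
  print(object)
  if (nrow(object$history) > 1) {
    cat("  loss by epoch:\n")
    print(object$history, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.pam_cnn <- function(object, ...) {
  st <- object$state
  st[grepl("^(W|wb|g|bb)[0-9]+$", names(st))]
}

#' Save / load a fitted classifier checkpoint
#'
#' The checkpoint is a single RDS file holding the architecture spec, all
#' weights and batch-norm statistics, the optimizer state and the training
#' history; `model_version` is a content hash of the serialized state.
#'
#' @param object a `pam_cnn`.
#' @param path file path.
#' @export
save_pam_cnn <- function(object, path) {
  obj <- object[setdiff(names(object), "env")]
  class(obj) <- "pam_cnn_snapshot"
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_pam_cnn
#' @return the restored `pam_cnn`.
#' @export
load_pam_cnn <- function(path) {
  obj <- readRDS(path)
  obj <- unclass(obj)
  obj$env <- new.env(parent = emptyenv())
  class(obj) <- "pam_cnn"
  obj
}

#' Content hash identifying a model version
#' @param object a `pam_cnn`.
#' @return hex string hash of the serialized weights.
#' @export
model_version <- function(object) {
  raw <- serialize(object$state, NULL, version = 2L)
  # FNV-1a over the serialized state
  h <- 0
  step <- max(1L, length(raw) %/% 4096L)
  for (i in seq(1L, length(raw), by = step)) {
    h <- bitwXor(h, as.integer(raw[i]))
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
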