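# The binary "larger or smaller than 32 pixels" decision behind the scale
# search, as a pluggable contract: an analytic oracle (for testing the
# search) and a small trainable convolutional reference model.

#' Construct a size classifier
#'
#' The contract behind the scale search: a pure function mapping a
#' `lesion_frame` to the probability that the framed lesion exceeds 32
#' pixels.
#'
#' @param predict_prob `function(frame) -> numeric in [0, 1]`.
#' @param metadata Free-text description.
#' @param class Additional S3 classes to prepend.
#' @return A `size_classifier` object.
#' @export
size_classifier <- function(predict_prob, metadata = "", class = character()) {
  stopifnot(is.function(predict_prob))
  structure(list(predict_prob = predict_prob, metadata = metadata),
            class = c(class, "size_classifier"))
}

#' @export
print.size_classifier <- function(x, ...) {
  cat(sprintf("<size_classifier: %s>\n", x$metadata))
  invisible(x)
}

#' Classify one or more frames
#'
#' @param clf A `size_classifier`.
#' @param frames A `lesion_frame` or a list of them.
#' @return Numeric vector of probabilities that each lesion exceeds 32 px.
#' @export
classify_frames <- function(clf, frames) {
  stopifnot(inherits(clf, "size_classifier"))
  if (inherits(frames, "lesion_frame")) frames <- list(frames)
  vapply(frames, clf$predict_prob, numeric(1))
}

#' Analytic oracle classifier
#'
#' A test double for the learned network: given a function reporting each
#' frame's true apparent lesion size, the hard oracle returns probability 1
#' when the size exceeds 32 px and 0 otherwise; the soft variant returns a
#' logistic in `(apparent_size - 32)` with configurable slope (0.5 exactly
#' at 32 px).
#'
#' @param apparent_size_fn `function(frame) -> apparent size in pixels`; must
#'   return a finite value for every queried frame.
#' @param soft Use the logistic variant.
#' @param slope Logistic slope (per pixel) for the soft variant.
#' @return A `size_classifier`.
#' @export
oracle_classifier <- function(apparent_size_fn, soft = FALSE, slope = 2) {
  stopifnot(is.function(apparent_size_fn))
  predict <- function(frame) {
    a <- apparent_size_fn(frame)
    if (is.null(a) || !is.finite(a))
      stop_lesionruler("apparent size unknown for queried frame",
                       "lesionruler_lookup_error")
    if (soft) stats::plogis(slope * (a - TARGET_PX)) else as.numeric(a > TARGET_PX)
  }
  size_classifier(predict,
                  metadata = if (soft) "soft analytic oracle" else "hard analytic oracle",
                  class = "oracle_classifier")
}

#' Oracle classifier for a phantom case
#'
#' Uses the phantom's ground-truth diameter: a frame sampled at
#' magnification `m` shows the lesion at `m * M_px` apparent pixels.
#'
#' @param case A `phantom_case`.
#' @inheritParams oracle_classifier
#' @return A `size_classifier`.
#' @export
phantom_oracle <- function(case, soft = FALSE, slope = 2) {
  stopifnot(inherits(case, "phantom_case"))
  M_px <- cm_to_pixels(case$true_diameter_cm, case$spacing_cm)
  oracle_classifier(function(frame) frame$magnification * M_px,
                    soft = soft, slope = slope)
}

#' Training protocol
#'
#' @param iterations Mini-batch updates (an "iteration" is one update;
#'   default 500).
#' @param batch_size Samples per update (default 32).
#' @param validation_fraction Fraction of the training frames held out for
#'   validation when no explicit validation set is given.
#' @param rng_seed Seed for initialization, batch sampling and splitting.
#' @param eval_every Validation-accuracy evaluation cadence, in updates.
#' @param learning_rate Peak Adam step size.
#' @param lr_schedule `"cosine"` (default; decays from `learning_rate` to 0
#'   over the run) or `"constant"`.
#' @return A `training_protocol` object.
#' @export
training_protocol <- function(iterations = 500L, batch_size = 32L,
                              validation_fraction = 0.15, rng_seed = 1L,
                              eval_every = 10L, learning_rate = 1.5e-3,
                              lr_schedule = c("cosine", "constant")) {
  lr_schedule <- match.arg(lr_schedule)
  if (iterations < 1 || batch_size < 1 || eval_every < 1)
    stop_lesionruler("iterations, batch_size and eval_every must be >= 1",
                     "lesionruler_parameter_error")
  structure(list(iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 validation_fraction = validation_fraction,
                 rng_seed = as.integer(rng_seed),
                 eval_every = as.integer(eval_every),
                 learning_rate = learning_rate,
                 lr_schedule = lr_schedule),
            class = "training_protocol")
}

protocol_lrs <- function(protocol) {
  t <- seq_len(protocol$iterations)
  switch(protocol$lr_schedule,
         constant = rep(protocol$learning_rate, protocol$iterations),
         cosine = 0.5 * protocol$learning_rate *
           (1 + cos(pi * (t - 1) / protocol$iterations)))
}

# fixed coordinate channels: normalized row/col offsets from the frame
# center and radial distance.  They let the network read *where* bright
# pixels sit, i.e. compute directional extent rather than just area.
cnn_coord_channels <- local({
  u <- (seq_len(64L) - 32.5) / 32
  x <- matrix(u, 64, 64)            # row offset
  y <- t(x)                         # col offset
  r <- sqrt(x^2 + y^2)
  c(as.numeric(x), as.numeric(y), as.numeric(r))
})

# 128x128 patch -> 64x64 mean-pooled intensity channel + coordinate channels
frame_input <- function(patch) {
  g <- rep(seq_len(64L), each = 2L)
  m <- rowsum(patch, g) / 2
  m <- t(rowsum(t(m), g) / 2)
  c(as.numeric(m), cnn_coord_channels)
}

frames_to_matrix <- function(frames) {
  vapply(frames, function(f) frame_input(f$patch), numeric(4L * 4096L))
}

frame_labels <- function(frames) {
  labs <- vapply(frames, function(f) f$label %||% NA_character_, "")
  if (anyNA(labs))
    stop_lesionruler("all frames must carry a label", "lesionruler_contract_error")
  as.numeric(labs == "LARGER")
}

# three batch-normalized conv blocks (8/16/32 channels) on the 64x64
#4-channel input (intensity + coordinates); the 8x8x32 feature map feeds a
# 64-unit head so the dense layer keeps enough spatial resolution to read
# lesion extent
cnn_init_weights <- function() {
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nc)), nr, nc)
  channels <- c(4, 8, 16, 32)
  list(conv_w = lapply(1:3, function(l) he(channels[l + 1], 9 * channels[l])),
       bn_gamma = lapply(1:3, function(l) rep(1, channels[l + 1])),
       bn_beta = lapply(1:3, function(l) numeric(channels[l + 1])),
       bn_rmean = lapply(1:3, function(l) numeric(channels[l + 1])),
       bn_rvar = lapply(1:3, function(l) rep(1, channels[l + 1])),
       W_fc1 = he(64, 8 * 8 * 32), b_fc1 = numeric(64),
       W_fc2 = he(1, 64), b_fc2 = numeric(1))
}

#' Train the convolutional reference classifier
#'
#' A small CNN (128x128 input, five 3x3 conv blocks with ReLU and 2x2 max
#' pooling, a 64-unit dense layer, sigmoid output)
#' trained with Adam on binary cross-entropy for the stated number of
#' mini-batch updates.  Validation accuracy is computed every
#' `protocol$eval_every` updates and at the last update; the checkpoint
#' with the highest validation accuracy is returned (earliest on ties).
#' Fully deterministic given `protocol$rng_seed`.
#'
#' @param train_frames Labeled `lesion_frame` list containing both classes.
#' @param val_frames Labeled validation frames; when `NULL`, a seeded
#'   `validation_fraction` split of `train_frames` is used.
#' @param protocol A [training_protocol()].
#' @return A `cnn_size_classifier` (also a `size_classifier`) carrying the
#'   selected weights, the training trace (iteration, loss, validation
#'   accuracy), `n_updates`, `best_iteration` and `best_val_accuracy`.
#' @export
train_size_classifier <- function(train_frames, val_frames = NULL,
                                  protocol = training_protocol()) {
  stopifnot(inherits(protocol, "training_protocol"))
  y_all <- frame_labels(train_frames)
  if (length(unique(y_all)) < 2)
    stop_lesionruler("training frames must contain both classes",
                     "lesionruler_training_error")
  with_seed(protocol$rng_seed, {
    if (is.null(val_frames)) {
      n <- length(train_frames)
      n_val <- max(1L, round(protocol$validation_fraction * n))
      val_idx <- sort(sample.int(n, n_val))
      val_frames <- train_frames[val_idx]
      train_frames <- train_frames[-val_idx]
      y_all <- y_all[-val_idx]
      if (length(unique(y_all)) < 2)
        stop_lesionruler("training frames must contain both classes after the split",
                         "lesionruler_training_error")
    }
    if (length(val_frames) == 0)
      stop_lesionruler("validation set is empty", "lesionruler_training_error")
    Xtr <- frames_to_matrix(train_frames)
    Xval <- frames_to_matrix(val_frames)
    yval <- frame_labels(val_frames)
    w0 <- cnn_init_weights()
    batches <- matrix(sample.int(ncol(Xtr), protocol$iterations * protocol$batch_size,
                                 replace = TRUE) - 1L,
                      nrow = protocol$batch_size)
    fit <- cpp_cnn_train(w0, Xtr, y_all, Xval, yval, batches,
                         protocol$eval_every, protocol_lrs(protocol))
    # operating-point calibration: the apparent size at which the selected
    # model's probability actually crosses 0.5, estimated on the validation
    # frames (monotone fit over log apparent size)
    boundary_px <- local({
      app <- vapply(val_frames, function(f) f$apparent_size_px %||% NA_real_,
                    numeric(1))
      if (anyNA(app)) return(TARGET_PX)
      pv <- as.numeric(cpp_cnn_predict(fit$best_weights, Xval))
      o <- order(app)
      x <- log(app[o])
      yfit <- stats::isoreg(x, pv[o])$yf
      lo <- which(yfit < 0.5); hi <- which(yfit > 0.5)
      if (length(lo) == 0 || length(hi) == 0) return(TARGET_PX)
      i <- max(lo); j <- min(hi)
      exp(x[i] + (0.5 - yfit[i]) / (yfit[j] - yfit[i]) * (x[j] - x[i]))
    })
  })
  weights <- fit$best_weights
  clf <- size_classifier(
    function(frame) as.numeric(cpp_cnn_predict(weights,
                                               matrix(frame_input(frame$patch)))),
    metadata = sprintf("cnn reference classifier (val acc %.3f at update %d/%d)",
                       fit$best_val_accuracy, fit$best_iteration, fit$n_updates),
    class = "cnn_size_classifier")
  clf$weights <- weights
  clf$protocol <- protocol
  clf$n_updates <- fit$n_updates
  clf$best_iteration <- fit$best_iteration
  clf$best_val_accuracy <- fit$best_val_accuracy
  clf$boundary_px <- boundary_px
  clf$trace <- fit$trace
  clf
}

#' Train a committee of three convolutional classifiers
#'
#' Trains `n_members` independent copies of the reference network (same
#' frames, different seeded initializations and batch orders, each under
#' the full [training_protocol()]) and combines them into one classifier
#' whose probability is the mean of the members' probabilities.  Averaging
#' independently-initialized members substantially reduces the variance of
#' the learned 32-px decision boundary, and mirrors the deep-learning
#' system this package models, which stacked three convolutional networks
#' behind the same binary decision.
#'
#' @inheritParams train_size_classifier
#' @param n_members Number of committee members (default 3).
#' @return A `cnn_committee_classifier` (also a `size_classifier`) with the
#'   trained members in `$members`.
#' @export
train_size_classifier_committee <- function(train_frames, val_frames = NULL,
                                            protocol = training_protocol(),
                                            n_members = 3L) {
  stopifnot(inherits(protocol, "training_protocol"), n_members >= 1)
  members <- lapply(seq_len(n_members), function(k) {
    pk <- protocol
    pk$rng_seed <- as.integer((protocol$rng_seed + (k - 1) * 104729) %%
                                .Machine$integer.max)
    train_size_classifier(train_frames, val_frames, pk)
  })
  clf <- size_classifier(
    function(frame) mean(vapply(members, function(m) m$predict_prob(frame),
                                numeric(1))),
    metadata = sprintf("committee of %d cnn classifiers (val acc %s)",
                       n_members,
                       paste(sprintf("%.3f", vapply(members, `[[`, 0,
                                                    "best_val_accuracy")),
                             collapse = "/")),
    class = c("cnn_committee_classifier"))
  clf$members <- members
  clf$protocol <- protocol
  clf$best_val_accuracy <- mean(vapply(members, `[[`, 0, "best_val_accuracy"))
  clf
}

#' Batch prediction for the CNN classifier
#'
#' Faster equivalent of [classify_frames()] for `cnn_size_classifier`
#' objects (single C++ call).
#'
#' @param clf A `cnn_size_classifier`.
#' @param frames List of `lesion_frame` objects.
#' @return Numeric probability vector.
#' @export
classify_frames_cnn <- function(clf, frames) {
  if (inherits(clf, "cnn_committee_classifier")) {
    X <- frames_to_matrix(frames)
    probs <- vapply(clf$members,
                    function(m) as.numeric(cpp_cnn_predict(m$weights, X)),
                    numeric(length(frames)))
    return(rowMeans(matrix(probs, nrow = length(frames))))
  }
  stopifnot(inherits(clf, "cnn_size_classifier"))
  as.numeric(cpp_cnn_predict(clf$weights, frames_to_matrix(frames)))
}

#' Classification accuracy on labeled frames
#'
#' Fraction of frames where `predict_prob > 0.5` matches the stored label
#' (threshold fixed at 0.5).
#'
#' @param clf A `size_classifier`.
#' @param frames Non-empty list of labeled frames.
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_accuracy <- function(clf, frames) {
  if (length(frames) == 0)
    stop_lesionruler("frames must be non-empty", "lesionruler_contract_error")
  y <- frame_labels(frames)
  p <- if (inherits(clf, c("cnn_size_classifier", "cnn_committee_classifier")))
    classify_frames_cnn(clf, frames)
  else classify_frames(clf, frames)
  mean((p > 0.5) == (y == 1))
}

#' Majority-vote cascade of classifiers
#'
#' Wraps an odd number of classifiers into one whose probability is the
#' fraction of members voting LARGER.
#'
#' @param classifiers List of `size_classifier` objects (odd length).
#' @return A `size_classifier`.
#' @export
majority_vote_classifier <- function(classifiers) {
  stopifnot(length(classifiers) %% 2 == 1)
  lapply(classifiers, function(c) stopifnot(inherits(c, "size_classifier")))
  size_classifier(
    function(frame) mean(vapply(classifiers,
                                function(c) c$predict_prob(frame) > 0.5, logical(1))),
    metadata = sprintf("majority vote of %d classifiers", length(classifiers)))
}

#' Save / load a trained classifier artifact
#'
#' @param clf A `cnn_size_classifier`.
#' @param path Artifact file path.
#' @return `path` invisibly; `load_size_classifier` returns the classifier.
#' @export
save_size_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "cnn_size_classifier"))
  saveRDS(list(weights = clf$weights, protocol = clf$protocol,
               n_updates = clf$n_updates, best_iteration = clf$best_iteration,
               best_val_accuracy = clf$best_val_accuracy,
               boundary_px = clf$boundary_px, trace = clf$trace),
          path)
  invisible(path)
}

#' @rdname save_size_classifier
#' @export
load_size_classifier <- function(path) {
  art <- readRDS(path)
  weights <- art$weights
  clf <- size_classifier(
    function(frame) as.numeric(cpp_cnn_predict(weights,
                                               matrix(frame_input(frame$patch)))),
    metadata = sprintf("cnn reference classifier (val acc %.3f at update %d/%d)",
                       art$best_val_accuracy, art$best_iteration, art$n_updates),
    class = "cnn_size_classifier")
  clf[names(art)] <- art
  clf
}

#' Write the training log as CSV
#'
#' @param clf A trained `cnn_size_classifier`.
#' @param file Output CSV path (columns: iteration, loss, val_accuracy).
#' @export
write_training_log <- function(clf, file) {
  stopifnot(inherits(clf, "cnn_size_classifier"))
  utils::write.csv(clf$trace, file, row.names = FALSE)
  invisible(file)
}
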