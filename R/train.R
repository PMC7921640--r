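# Training loop, prediction, and transfer-learning hooks for hs_cnn models.

#' Training control parameters
#'
#' @param epochs number of passes over the training data.
#' @param batch_size minibatch size.
#' @param learning_rate RMSprop step size.
#' @param class_weights optional named per-class loss weights; when `NULL`
#'   they default to `total / (n_classes * class_count)` (inverse-frequency
#'   weighted loss), so imbalanced classes contribute equally to the loss.
#' @param freeze_blocks number of leading convolutional blocks whose
#'   parameters are held fixed during training (fine-tuning depth after a
#'   transfer; `0` fine-tunes everything).
#' @param seed integer seed governing shuffling, augmentation draws and any
#'   other randomness of one training run.
#' @param augment an [hs_augment_policy()] applied on-the-fly to each
#'   training image every epoch; the all-zero policy disables augmentation.
#' @param verbose print per-epoch loss/accuracy.
#' @return An object of class `"hs_control"`.
#' @export
hs_control <- function(epochs = 50L, batch_size = 32L, learning_rate = 1e-3,
                       class_weights = NULL, freeze_blocks = 0L, seed = 1L,
                       augment = hs_augment_policy(), verbose = FALSE) {
  if (epochs < 1L) hs_stop("epochs must be >= 1", "hs_config_error")
  if (learning_rate <= 0) hs_stop("learning_rate must be > 0", "hs_config_error")
  if (!is.null(class_weights) && any(class_weights <= 0))
    hs_stop("class_weights must be positive", "hs_config_error")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, class_weights = class_weights,
                 freeze_blocks = as.integer(freeze_blocks), seed = as.integer(seed),
                 augment = augment, verbose = isTRUE(verbose)),
            class = "hs_control")
}

#' Train a convolutional classifier
#'
#' Minimises class-weighted cross-entropy with minibatch RMSprop.  The run
#' is fully determined by `control$seed`: shuffling, augmentation draws and
#' updates are reproducible, so identical data, control and seed give
#' identical final weights.
#'
#' @param model an [hs_cnn()] model (trained or untrained; training always
#'   starts from the model's current parameters).
#' @param x training images: a `(pixels x n)` matrix for a single-input
#'   network, or a list of such matrices (one per trunk) for a
#'   multiple-input network.  Pixel values are expected in `[0, 1]`.
#' @param y factor of class labels, one per column of `x`; its levels
#'   define the model's `class_order`.
#' @param control an [hs_control()] object.
#' @return The trained `"hs_cnn"` model with `training_log` (a data frame
#'   of per-epoch loss and training accuracy) and `class_order` filled in.
#' @export
hs_train <- function(model, x, y, control = hs_control()) {
  stopifnot(inherits(model, "hs_cnn"))
  arch <- model$arch
  xs <- as_trunk_input(x, arch)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != arch$n_classes)
    hs_stop(sprintf("y has %d classes but the model expects %d",
                    nlevels(y), arch$n_classes), "hs_input_error")
  n <- ncol(xs[[1L]])
  if (length(y) != n) hs_stop("length(y) != number of images", "hs_input_error")
  cw <- control$class_weights
  if (is.null(cw)) {
    tab <- table(y)
    cw <- as.numeric(n / (nlevels(y) * tab))
    names(cw) <- names(tab)
  }
  if (is.null(names(cw))) names(cw) <- levels(y)
  cw <- cw[levels(y)]
  if (anyNA(cw)) hs_stop("class_weights must cover every class level", "hs_config_error")

  frozen <- character(0)
  if (control$freeze_blocks > 0L)
    frozen <- grep(sprintf("^t[0-9]+\\.b[1-%d]\\.", control$freeze_blocks),
                   names(model$params), value = TRUE)
  params <- model$params
  yi <- as.integer(y)
  K <- arch$n_classes
  h <- arch$input_size[1L]; w <- arch$input_size[2L]
  pol <- control$augment
  do_aug <- !is_identity_policy(pol)

  # RMSprop state
  v <- lapply(params, function(p) p * 0)
  rho <- 0.9; eps <- 1e-8; lr <- control$learning_rate

  log_loss <- numeric(control$epochs); log_acc <- numeric(control$epochs)
  with_seed(control$seed, {
    for (ep in seq_len(control$epochs)) {
      ord <- sample.int(n)
      splits <- split(ord, ceiling(seq_along(ord) / control$batch_size))
      tot_loss <- 0; tot_correct <- 0
      for (idx in splits) {
        xb <- lapply(xs, function(m) m[, idx, drop = FALSE])
        if (do_aug)
          xb <- lapply(xb, function(m) {
            for (j in seq_len(ncol(m)))
              m[, j] <- as.vector(augment_image(matrix(m[, j], h, w), pol))
            m
          })
        nb <- length(idx)
        fw <- net_forward(params, arch, xb, cache = TRUE)
        pick <- (seq_len(nb) - 1L) * K + yi[idx]
        pv <- pmax(fw$probs[pick], 1e-12)
        wv <- cw[yi[idx]]
        loss <- sum(wv * -log(pv)) / sum(wv)
        if (!is.finite(loss))
          hs_stop("training diverged (non-finite loss); lower learning_rate",
                  "hs_divergence_error")
        dL <- fw$probs
        dL[pick] <- dL[pick] - 1
        dL <- dL * rep(wv / sum(wv), each = K)
        gr <- net_backward(params, arch, fw, dL)
        for (nm in names(params)) {
          if (nm %in% frozen) next
          g <- gr[[nm]]
          v[[nm]] <- rho * v[[nm]] + (1 - rho) * g * g
          params[[nm]] <- params[[nm]] - lr * g / sqrt(v[[nm]] + eps)
        }
        tot_loss <- tot_loss + loss * nb
        tot_correct <- tot_correct + sum(max.col(t(fw$probs)) == yi[idx])
      }
      log_loss[ep] <- tot_loss / n
      log_acc[ep] <- tot_correct / n
      if (control$verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep, log_loss[ep], log_acc[ep]))
    }
  })
  model$params <- params
  model$class_order <- levels(y)
  model$trained <- TRUE
  model$training_log <- data.frame(epoch = seq_len(control$epochs),
                                   loss = log_loss, accuracy = log_acc)
  model
}

#' Predict class probabilities
#'
#' @param object a trained [hs_cnn()] model.
#' @param x images as in [hs_train()].
#' @param batch_size evaluation batch size (memory knob only; results are
#'   independent of it).
#' @param ... unused.
#' @return An `(n x n_classes)` matrix of softmax probabilities, columns
#'   named and ordered by the model's `class_order`; every row sums to 1.
#' @export
predict.hs_cnn <- function(object, x, batch_size = 256L, ...) {
  xs <- as_trunk_input(x, object$arch)
  n <- ncol(xs[[1L]])
  out <- matrix(NA_real_, n, object$arch$n_classes)
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    xb <- lapply(xs, function(m) m[, s:e, drop = FALSE])
    out[s:e, ] <- t(net_forward(object$params, object$arch, xb)$probs)
  }
  colnames(out) <- object$class_order %||% paste0("C", seq_len(ncol(out)))
  out
}

#' Extract pre-head feature vectors
#'
#' Returns the concatenated flattened convolutional-trunk features (the
#' representation the dense head sees).  Used to verify that transfer
#' preserves the shared trunk exactly.
#'
#' @param model an [hs_cnn()] model.
#' @param x images as in [hs_train()].
#' @return A `(feature_dim x n)` matrix.
#' @export
hs_features <- function(model, x) {
  xs <- as_trunk_input(x, model$arch)
  net_forward(model$params, model$arch, xs, cache = TRUE)$feats
}

#' Initialise a model by transfer from a source model
#'
#' Copies all convolutional-block parameters of `source` bit-exactly into a
#' new model and re-initialises the dense head for `n_classes_new` outputs.
#' The copied region is exactly the region that [hs_control()]'s
#' `freeze_blocks` can later hold fixed.  When the target has several
#' trunks and the source one, the source trunk is replicated into every
#' target trunk.
#'
#' @param source a (typically trained) `"hs_cnn"` source model.
#' @param n_classes_new number of output classes of the new model.
#' @param seed seed for the head re-initialisation.
#' @param arch optional target architecture; defaults to the source
#'   architecture with the new class count.  Must match the source's block
#'   structure and input size.
#' @return An untrained `"hs_cnn"` whose trunk equals the source's.
#' @export
hs_transfer <- function(source, n_classes_new, seed = 1L, arch = NULL) {
  stopifnot(inherits(source, "hs_cnn"))
  sa <- source$arch
  if (is.null(arch)) {
    arch <- sa
    arch$n_classes <- as.integer(n_classes_new)
  } else {
    stopifnot(inherits(arch, "hs_arch"))
    arch$n_classes <- as.integer(n_classes_new)
  }
  if (arch$n_blocks != sa$n_blocks || !identical(arch$channels, sa$channels) ||
      !identical(arch$input_size, sa$input_size))
    hs_stop(sprintf("incompatible trunk: target block 1 expects %s blocks/%s channels/%sx%s input, source has %s/%s/%sx%s",
                    arch$n_blocks, paste(arch$channels, collapse = ","),
                    arch$input_size[1], arch$input_size[2],
                    sa$n_blocks, paste(sa$channels, collapse = ","),
                    sa$input_size[1], sa$input_size[2]),
            "hs_transfer_error")
  target <- hs_cnn(arch, seed = seed)
  for (k in seq_len(arch$n_trunks)) {
    src_k <- if (sa$n_trunks == arch$n_trunks) k else 1L
    for (b in seq_len(arch$n_blocks))
      for (p in c("W1", "b1", "W2", "b2"))
        target$params[[sprintf("t%d.b%d.%s", k, b, p)]] <-
          source$params[[sprintf("t%d.b%d.%s", src_k, b, p)]]
  }
  target
}

#' Load externally supplied weights into a model
#'
#' Optional hook for substituting real pretrained weights for the synthetic
#' pretext source: assigns parameters by name after a shape check.
#'
#' @param model an `"hs_cnn"` model.
#' @param weights named list of parameter matrices/vectors; names must be a
#'   subset of `names(model$params)` with matching dimensions.
#' @return The model with the given parameters replaced.
#' @export
hs_set_weights <- function(model, weights) {
  stopifnot(inherits(model, "hs_cnn"))
  for (nm in names(weights)) {
    if (is.null(model$params[[nm]]))
      hs_stop(sprintf("unknown parameter '%s'", nm), "hs_transfer_error")
    if (!identical(dim(model$params[[nm]]), dim(weights[[nm]])) ||
        length(model$params[[nm]]) != length(weights[[nm]]))
      hs_stop(sprintf("shape mismatch for parameter '%s'", nm), "hs_transfer_error")
    model$params[[nm]] <- weights[[nm]]
  }
  model
}

#' @export
print.hs_cnn <- function(x, ...) {
  a <- x$arch
  cat(sprintf("Convolutional classifier: %d block(s) [%s ch], dense %d, %d classes, input %dx%d%s\n",
              a$n_blocks, paste(a$channels, collapse = "/"), a$dense_units,
              a$n_classes, a$input_size[1], a$input_size[2],
              if (a$n_trunks > 1L) sprintf(", %d trunks", a$n_trunks) else ""))
  cat(if (isTRUE(x$trained)) sprintf("Trained (%d epochs, final loss %.4f, train acc %.3f)\n",
                                     nrow(x$training_log),
                                     utils::tail(x$training_log$loss, 1),
                                     utils::tail(x$training_log$accuracy, 1))
      else "Untrained\n")
  invisible(x)
}

# --------------------------------------------------------------------------
# pretext pretraining -------------------------------------------------------

#' Generate a synthetic pretext task (generic shapes)
#'
#' A seeded stand-in for large-scale natural-image pretraining: grayscale
#' images of simple geometric shape classes (disc, ring, square, cross,
#' bars, diagonal, dots) at random positions and scales plus noise.
#' Training on it gives a source model with generic edge/blob features
#' that [hs_transfer()] can reuse.
#'
#' @param n total number of images.
#' @param n_classes number of shape classes (2..8).
#' @param image_size `c(height, width)`.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param seed integer seed.
#' @return A list with `x` (`pixels x n` matrix in `[0, 1]`), `y` (factor),
#'   and `image_size`.
#' @export
hs_pretext_data <- function(n = 240L, n_classes = 6L, image_size = c(24L, 24L),
                            noise_sd = 0.1, seed = 1L) {
  if (n_classes < 2L || n_classes > 8L)
    hs_stop("n_classes must be in 2..8", "hs_config_error")
  shapes <- c("disc", "ring", "square", "cross", "hbar", "vbar", "diag", "dots")[seq_len(n_classes)]
  h <- image_size[1L]; w <- image_size[2L]
  yy <- matrix(rep(seq_len(h) / h, w), h, w)
  xx <- matrix(rep(seq_len(w) / w, each = h), h, w)
  draw <- function(shape, cx, cy, r) {
    d <- sqrt((xx - cx)^2 + (yy - cy)^2)
    switch(shape,
      disc   = (d < r) * 1,
      ring   = (abs(d - r) < r / 3) * 1,
      square = (abs(xx - cx) < r & abs(yy - cy) < r) * 1,
      cross  = ((abs(xx - cx) < r / 3 & abs(yy - cy) < r) |
                (abs(yy - cy) < r / 3 & abs(xx - cx) < r)) * 1,
      hbar   = (abs(yy - cy) < r / 2.5) * 1,
      vbar   = (abs(xx - cx) < r / 2.5) * 1,
      diag   = (abs((xx - cx) - (yy - cy)) < r / 2.5 & d < 2 * r) * 1,
      dots   = ((sqrt((xx - cx - r)^2 + (yy - cy - r)^2) < r / 2.2) |
                (sqrt((xx - cx + r)^2 + (yy - cy + r)^2) < r / 2.2)) * 1)
  }
  with_seed(seed, {
    cls <- rep_len(shapes, n)
    X <- matrix(0, h * w, n)
    for (i in seq_len(n)) {
      cx <- stats::runif(1, 0.35, 0.65); cy <- stats::runif(1, 0.35, 0.65)
      r <- stats::runif(1, 0.12, 0.25)
      img <- 0.2 + 0.6 * draw(cls[i], cx, cy, r) +
        stats::rnorm(h * w, 0, noise_sd)
      X[, i] <- pmin(pmax(img, 0), 1)
    }
    list(x = X, y = factor(cls, levels = shapes), image_size = image_size)
  })
}

#' Pretrain a generic-features source model on a pretext task
#'
#' Trains the given architecture on a (by default generated) synthetic
#' shapes task and returns the trained model for use as a transfer source.
#' Skipping pretraining (using a freshly initialised [hs_cnn()] as source,
#' or `source = NULL` in [hierstack()]) remains a selectable baseline.
#'
#' @param arch an [hs_arch()]; its `n_classes` is overridden by the pretext
#'   task's class count.
#' @param data optional pretext dataset from [hs_pretext_data()]; generated
#'   automatically (matching the architecture's input size) when `NULL`.
#' @param control an [hs_control()].
#' @param seed seed for data generation and initial weights.
#' @return A trained `"hs_cnn"` source model.
#' @export
hs_pretext <- function(arch, data = NULL, control = hs_control(epochs = 10L),
                       seed = 1L) {
  if (is.null(data))
    data <- hs_pretext_data(image_size = arch$input_size,
                            seed = child_seed(seed, "pretext_data"))
  if (nlevels(droplevels(as.factor(data$y))) < 2L)
    hs_stop("pretext dataset must contain at least 2 classes", "hs_training_error")
  arch$n_classes <- nlevels(droplevels(as.factor(data$y)))
  arch$n_trunks <- 1L
  model <- hs_cnn(arch, seed = child_seed(seed, "pretext_init"))
  hs_train(model, data$x, data$y, control)
}
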