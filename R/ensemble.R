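# Stacking ensemble across per-modality bundles.

#' Stack per-modality bundles with a superior metamodel
#'
#' Concatenates the per-modality confidence vectors (block order fixed to
#' the order the bundles are supplied in, conventionally projection,
#' en-face, discH, discV) into a stacked vector of length
#' `M * (n_subtypes + 1)` and trains a linear SVM metamodel on it.  The
#' training vectors are the bundles' stored out-of-fold confidences (or
#' in-sample confidences for `meta = "naive"` bundles), so no extra
#' network training is needed.
#'
#' @param bundles list of [hierstack()] fits sharing strategy, classes and
#'   training cases; one per modality (a single bundle is the degenerate
#'   `M = 1` ensemble).  For flat bundles each block is the full softmax.
#' @param data the `"hs_dataset"` the bundles were trained on (labels for
#'   the metamodel).
#' @param cost SVM regularisation parameter.
#' @return An object of class `"hs_stack"`.
#' @export
hs_stack <- function(bundles, data, cost = 1) {
  stopifnot(length(bundles) >= 1L, inherits(data, "hs_dataset"))
  if (!all(vapply(bundles, inherits, TRUE, "hierstack")))
    hs_stop("bundles must be hierstack fits", "hs_input_error")
  strat <- unique(vapply(bundles, `[[`, character(1), "strategy"))
  if (length(strat) != 1L)
    hs_stop("all bundles must share one strategy", "hs_input_error")
  cls <- bundles[[1L]]$classes
  for (b in bundles)
    if (!identical(b$classes, cls))
      hs_stop("all bundles must share the class order", "hs_input_error")
  ids <- bundles[[1L]]$oof$ids
  for (b in bundles)
    if (!setequal(b$oof$ids, ids))
      hs_stop("all bundles must be trained on the same cases", "hs_input_error")
  block_order <- unname(vapply(bundles, function(b)
    paste(b$modality, collapse = "+"), character(1)))
  X <- do.call(cbind, lapply(bundles, function(b)
    b$oof$vectors[ids, , drop = FALSE]))
  y <- hs_labels(data)[ids]
  structure(list(bundles = bundles, block_order = block_order,
                 strategy = strat, classes = cls,
                 metamodel = hs_svm_ovr(X, factor(y, levels = cls), cost = cost),
                 train_ids = ids),
            class = "hs_stack")
}

#' Predict from a stacking ensemble
#'
#' @param object an [hs_stack()] ensemble.
#' @param data an `"hs_dataset"` carrying all member modalities.
#' @param subset optional case ids.
#' @param ... unused.
#' @return As [predict.hierstack()]: `class`, `confidence` (the stacked
#'   vector, `n x M*(n_subtypes + 1)`), and `scores` (metamodel decision
#'   values).
#' @export
predict.hs_stack <- function(object, data, subset = NULL, ...) {
  ids <- subset %||% vapply(data$cases, `[[`, character(1), "case_id")
  X <- do.call(cbind, lapply(object$bundles, function(b)
    predict(b, data, subset = ids)$confidence))
  mm <- predict(object$metamodel, X)
  names(mm$class) <- ids
  rownames(mm$scores) <- ids
  list(class = mm$class, confidence = X, scores = mm$scores)
}

#' @describeIn evaluate Evaluate an [hs_stack()] ensemble.
#' @export
evaluate.hs_stack <- function(object, data, subset = NULL, ...) {
  ids <- subset %||% vapply(data$cases, `[[`, character(1), "case_id")
  pr <- predict(object, data, subset = ids)
  eval_report(hs_labels(data)[ids], pr$class, scores = pr$scores,
              classes = object$classes)
}

#' @export
print.hs_stack <- function(x, ...) {
  cat(sprintf("Stacking ensemble (%s): %d member bundle(s), blocks [%s]\n",
              x$strategy, length(x$bundles), paste(x$block_order, collapse = ", ")))
  cat(sprintf("  stacked vector length %d over classes %s\n",
              x$metamodel$d, paste(x$classes, collapse = ", ")))
  invisible(x)
}
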