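# The central fitting function: one classification strategy (flat,
# hierarchical, or hierarchical + hierarchy transfer learning) for one
# input modality (or a multiple-input network over several modalities).

#' Concatenate low- and high-level confidences
#'
#' Builds the length `n + 1` confidence vector: the low-level model's
#' "normal" probability followed by the high-level model's `n` subtype
#' probabilities in fixed subtype order.  The subtype block sums to 1 (it
#' is a softmax); the full vector deliberately does not.
#'
#' @param low_probs length-2 softmax of the normal-vs-disease model, named
#'   with `"normal"` among the names (or normal first).
#' @param high_probs length-`n` softmax of the subtype model.
#' @return Numeric vector of length `n + 1`.
#' @examples
#' build_confidence_vector(c(normal = 0.9, disease = 0.1), rep(0.25, 4))
#' @export
build_confidence_vector <- function(low_probs, high_probs) {
  if (length(low_probs) != 2L)
    hs_stop("low_probs must have length 2", "hs_input_error")
  if (length(high_probs) < 1L)
    hs_stop("high_probs must have length >= 1", "hs_input_error")
  nrm <- if (!is.null(names(low_probs)) && "normal" %in% names(low_probs))
    low_probs[["normal"]] else low_probs[[1L]]
  c(normal = unname(nrm), high_probs)
}

# stratified fold assignment (round-robin within shuffled classes)
stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Fit a hierarchical / flat classification bundle
#'
#' Trains one complete model bundle for the chosen strategy:
#' \describe{
#'   \item{`"fc"`}{Flat classification: a single `(n + 1)`-class network
#'     initialised by transfer from `source` (or randomly when `source` is
#'     `NULL`).}
#'   \item{`"hc"`}{Hierarchical classification: a 2-class low-level
#'     (normal-vs-disease) network trained on all cases and an `n`-class
#'     high-level subtype network trained on diseased cases only, both
#'     initialised from `source`; a linear SVM metamodel over the
#'     concatenated confidence vector produces the overall label.}
#'   \item{`"hc_htl"`}{As `"hc"`, but the high-level network is
#'     initialised from the *trained low-level network* (hierarchy
#'     transfer learning), reusing the normal-vs-disease features for
#'     subtype discrimination.}
#' }
#' With several modalities a multiple-input network (one convolutional
#' trunk per modality, features concatenated before the dense head) is
#' trained under the same strategy.
#'
#' The metamodel is fitted on out-of-fold confidence vectors by default
#' (`meta = "oof"`: the base networks are refitted on `meta_folds - 1`
#' folds to produce held-out confidences for the remaining fold, then
#' refitted on the full training data), standard stacking hygiene; the
#' in-sample variant is available as `meta = "naive"`.
#'
#' @param data an [hs_simulate()] (or [read_dataset()]) dataset.
#' @param strategy `"fc"`, `"hc"`, or `"hc_htl"`.
#' @param modality modality tag(s); more than one trains a multiple-input
#'   network.
#' @param source optional trained [hs_cnn()] source model for transfer
#'   initialisation (e.g. from [hs_pretext()]); `NULL` trains from random
#'   initialisation.
#' @param arch optional [hs_arch()] template (class count and trunk count
#'   are set per sub-model); defaults to the source's architecture or the
#'   package default sized to the data.
#' @param control an [hs_control()] for network training.
#' @param meta `"oof"` or `"naive"` metamodel confidence generation.
#' @param meta_folds folds for out-of-fold confidence generation.
#' @param seed master seed for this fit; per-stage seeds are derived with
#'   [child_seed()].
#' @param subset optional case ids to train on (default: all cases).
#' @return An object of class `"hierstack"`.
#' @seealso [predict.hierstack()], [evaluate()], [hs_stack()]
#' @export
hierstack <- function(data, strategy = c("hc_htl", "hc", "fc"),
                      modality = "projection", source = NULL, arch = NULL,
                      control = hs_control(), meta = c("oof", "naive"),
                      meta_folds = 5L, seed = 1L, subset = NULL) {
  stopifnot(inherits(data, "hs_dataset"))
  strategy <- match.arg(strategy)
  meta <- match.arg(meta)
  if (!all(modality %in% data$modalities))
    hs_stop(sprintf("unknown modality: %s",
                    paste(setdiff(modality, data$modalities), collapse = ", ")),
            "hs_input_error")
  labs <- hs_labels(data)
  ids <- subset %||% names(labs)
  y <- labs[ids]
  classes <- data$classes
  subtypes <- setdiff(classes, "normal")
  n <- length(subtypes)
  if (!all(classes %in% as.character(y)))
    hs_stop(sprintf("class(es) absent from training data: %s",
                    paste(setdiff(classes, as.character(y)), collapse = ", ")),
            "hs_stratification_error")
  yroot <- factor(ifelse(y == "normal", "normal", "disease"),
                  levels = c("normal", "disease"))
  M <- length(modality)
  if (is.null(arch)) {
    if (!is.null(source)) arch <- source$arch
    else {
      sz <- dim(data$cases[[1L]]$images[[1L]])
      arch <- hs_arch(n_classes = 2L, input_size = sz)
    }
  }
  xs_for <- function(which_ids)
    lapply(modality, function(m) dataset_matrix(data, m, which_ids))

  new_net <- function(n_classes, init_from, tag) {
    a <- arch; a$n_classes <- as.integer(n_classes); a$n_trunks <- M
    s <- child_seed(seed, tag)
    if (is.null(init_from)) hs_cnn(a, seed = s)
    else hs_transfer(init_from, n_classes, seed = s, arch = a)
  }
  ctl_with_seed <- function(tag) { c2 <- control; c2$seed <- child_seed(seed, tag); c2 }

  fit_base <- function(fit_ids, tag) {
    yf <- labs[fit_ids]
    if (!all(classes %in% as.character(yf)))
      hs_stop(sprintf("fold training data lost class(es): %s",
                      paste(setdiff(classes, as.character(yf)), collapse = ", ")),
              "hs_stratification_error")
    xf <- xs_for(fit_ids)
    if (strategy == "fc") {
      flat <- hs_train(new_net(n + 1L, source, paste0(tag, "_flat_init")),
                       xf, factor(yf, levels = classes),
                       ctl_with_seed(paste0(tag, "_flat")))
      list(flat = flat)
    } else {
      yr <- factor(ifelse(yf == "normal", "normal", "disease"),
                   levels = c("normal", "disease"))
      low <- hs_train(new_net(2L, source, paste0(tag, "_low_init")),
                      xf, yr, ctl_with_seed(paste0(tag, "_low")))
      dis_ids <- fit_ids[yf != "normal"]
      high0 <- new_net(n, if (strategy == "hc_htl") low else source,
                       paste0(tag, "_high_init"))
      high_init_trunk <- high0$params[trunk_param_names(high0$arch)]
      high <- hs_train(high0, xs_for(dis_ids),
                       factor(labs[dis_ids], levels = subtypes),
                       ctl_with_seed(paste0(tag, "_high")))
      list(low = low, high = high, high_init_trunk = high_init_trunk,
           n_high_train = length(dis_ids))
    }
  }
  conf_for <- function(models, which_ids) {
    xq <- xs_for(which_ids)
    if (strategy == "fc") {
      pr <- predict(models$flat, xq)
      rownames(pr) <- which_ids
      pr
    } else {
      lp <- predict(models$low, xq)
      hp <- predict(models$high, xq)
      cv <- cbind(normal = lp[, "normal"], hp)
      rownames(cv) <- which_ids
      cv
    }
  }

  # out-of-fold (or in-sample) confidence vectors for metamodel / stacking
  if (meta == "oof") {
    k <- min(meta_folds, min(table(y)))
    if (k < 2L)
      hs_stop("out-of-fold metamodel needs >= 2 cases in every class",
              "hs_stratification_error")
    fold <- stratified_folds(y, k, child_seed(seed, "meta_folds"))
    oof <- matrix(NA_real_, length(ids), n + 1L,
                  dimnames = list(ids, c("normal", subtypes)))
    for (f in seq_len(k)) {
      mods_f <- fit_base(ids[fold != f], sprintf("fold%d", f))
      oof[ids[fold == f], ] <- conf_for(mods_f, ids[fold == f])
    }
  }
  final <- fit_base(ids, "final")
  if (meta == "naive") oof <- conf_for(final, ids)
  colnames(oof) <- c("normal", subtypes)

  metamodel <- if (strategy != "fc")
    hs_svm_ovr(oof, factor(y, levels = classes)) else NULL

  structure(list(strategy = strategy, modality = modality,
                 classes = classes, subtypes = subtypes,
                 flat = final$flat, low = final$low, high = final$high,
                 high_init_trunk = final$high_init_trunk,
                 n_high_train = final$n_high_train,
                 metamodel = metamodel,
                 oof = list(ids = ids, vectors = oof),
                 meta = meta, meta_folds = if (meta == "oof") k else NA_integer_,
                 train_ids = ids, n_train = length(ids),
                 arch = arch, control = control, seed = seed,
                 call = match.call()),
            class = "hierstack")
}

#' Predict from a fitted bundle
#'
#' Flat bundles return the softmax argmax; hierarchical bundles build the
#' confidence vector from the low- and high-level networks and let the
#' metamodel decide.
#'
#' @param object a [hierstack()] fit.
#' @param data an `"hs_dataset"` carrying the bundle's modalities.
#' @param subset optional case ids (default: all cases in `data`).
#' @param ... unused.
#' @return A list with `class` (factor over the bundle's classes),
#'   `confidence` (`n x (n_subtypes + 1)` confidence-vector matrix), and
#'   `scores` (per-class decision scores used for ROC: the softmax for
#'   flat bundles, the metamodel decision values otherwise).
#' @export
predict.hierstack <- function(object, data, subset = NULL, ...) {
  stopifnot(inherits(data, "hs_dataset"))
  ids <- subset %||% vapply(data$cases, `[[`, character(1), "case_id")
  xq <- lapply(object$modality, function(m) dataset_matrix(data, m, ids))
  if (object$strategy == "fc") {
    pr <- predict(object$flat, xq)
    rownames(pr) <- ids
    cls <- factor(object$classes[max.col(pr, ties.method = "first")],
                  levels = object$classes)
    names(cls) <- ids
    return(list(class = cls, confidence = pr, scores = pr))
  }
  lp <- predict(object$low, xq)
  hp <- predict(object$high, xq)
  cv <- cbind(normal = lp[, "normal"], hp)
  rownames(cv) <- ids
  mm <- predict(object$metamodel, cv)
  names(mm$class) <- ids
  rownames(mm$scores) <- ids
  list(class = mm$class, confidence = cv, scores = mm$scores)
}

#' @describeIn evaluate Evaluate a [hierstack()] bundle on (typically
#'   held-out) cases.
#' @param data an `"hs_dataset"`.
#' @param subset optional case ids to evaluate on.
#' @export
evaluate.hierstack <- function(object, data, subset = NULL, ...) {
  ids <- subset %||% vapply(data$cases, `[[`, character(1), "case_id")
  pr <- predict(object, data, subset = ids)
  eval_report(hs_labels(data)[ids], pr$class, scores = pr$scores,
              classes = object$classes)
}

#' @export
print.hierstack <- function(x, ...) {
  lab <- c(fc = "flat classification",
           hc = "hierarchical classification",
           hc_htl = "hierarchical classification + hierarchy transfer learning")[x$strategy]
  cat(sprintf("hierstack bundle: %s\n", lab))
  cat(sprintf("  modality: %s%s\n", paste(x$modality, collapse = " + "),
              if (length(x$modality) > 1L) " (multiple-input network)" else ""))
  cat(sprintf("  classes:  %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  trained on %d cases", x$n_train))
  if (!is.null(x$n_high_train))
    cat(sprintf(" (high-level model: %d diseased cases)", x$n_high_train))
  cat("\n")
  if (!is.null(x$metamodel))
    cat(sprintf("  metamodel: linear SVM over %d-dim confidence vectors (%s)\n",
                x$metamodel$d,
                if (x$meta == "oof") sprintf("%d-fold out-of-fold", x$meta_folds)
                else "in-sample"))
  invisible(x)
}

#' @export
summary.hierstack <- function(object, ...) {
  print(object)
  logs <- Filter(Negate(is.null),
                 list(flat = object$flat, low = object$low, high = object$high))
  for (nm in names(logs)) {
    tl <- logs[[nm]]$training_log
    cat(sprintf("  %s model: %d epochs, final loss %.4f, train acc %.3f\n",
                nm, nrow(tl), utils::tail(tl$loss, 1), utils::tail(tl$accuracy, 1)))
  }
  invisible(object)
}

#' Coefficients of a bundle's metamodel
#'
#' @param object a [hierstack()] fit with a metamodel.
#' @param ... unused.
#' @return The metamodel coefficient matrix (see [coef.hs_svm_ovr()]).
#' @export
coef.hierstack <- function(object, ...) {
  if (is.null(object$metamodel))
    hs_stop("flat bundles have no metamodel", "hs_state_error")
  coef(object$metamodel)
}
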