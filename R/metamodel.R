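# Linear max-margin metamodel over confidence vectors (one-vs-rest).

#' Fit a one-vs-rest linear SVM metamodel
#'
#' One binary linear support-vector machine (via \pkg{e1071}/libsvm,
#' cost 1, no rescaling) per class; prediction is the argmax of the
#' per-class decision scores, which are also exposed for ROC analysis.
#'
#' @param x numeric feature matrix (`n x d`), one confidence vector per
#'   row.
#' @param y class labels (>= 1 example per class, >= 2 classes).
#' @param cost SVM regularisation parameter C.
#' @return An object of class `"hs_svm_ovr"`.
#' @export
hs_svm_ovr <- function(x, y, cost = 1) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L)
    hs_stop("metamodel training needs at least 2 classes", "hs_training_error")
  if (nrow(x) != length(y)) hs_stop("x rows must match length(y)", "hs_input_error")
  fits <- lapply(levels(y), function(cl) {
    yy <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    m <- e1071::svm(x, yy, kernel = "linear", cost = cost, scale = FALSE)
    dv <- attr(stats::predict(m, x, decision.values = TRUE), "decision.values")[, 1]
    # libsvm's decision sign depends on which label it saw first; orient so
    # larger score means "this class"
    flip <- mean(dv[yy == "pos"]) < mean(dv[yy == "neg"])
    list(model = m, flip = flip)
  })
  names(fits) <- levels(y)
  structure(list(fits = fits, classes = levels(y), d = ncol(x), cost = cost),
            class = "hs_svm_ovr")
}

#' Predict from a one-vs-rest SVM metamodel
#'
#' @param object an [hs_svm_ovr()] fit.
#' @param x feature matrix with the training dimensionality.
#' @param ... unused.
#' @return A list with `class` (factor) and `scores` (`n x n_classes`
#'   decision-value matrix, columns named by class).
#' @export
predict.hs_svm_ovr <- function(object, x, ...) {
  x <- as.matrix(x)
  if (ncol(x) != object$d)
    hs_stop(sprintf("metamodel expects %d features, got %d", object$d, ncol(x)),
            "hs_input_error")
  sc <- vapply(object$classes, function(cl) {
    f <- object$fits[[cl]]
    dv <- attr(stats::predict(f$model, x, decision.values = TRUE),
               "decision.values")[, 1]
    if (f$flip) -dv else dv
  }, numeric(nrow(x)))
  if (!is.matrix(sc)) sc <- matrix(sc, nrow = 1L, dimnames = list(NULL, object$classes))
  cls <- factor(object$classes[max.col(sc, ties.method = "first")],
                levels = object$classes)
  list(class = cls, scores = sc)
}

#' Linear coefficients of the metamodel
#'
#' @param object an [hs_svm_ovr()] fit.
#' @param ... unused.
#' @return A matrix (`n_classes x (d + 1)`): per-class weight vector and
#'   intercept of each one-vs-rest decision function.
#' @export
coef.hs_svm_ovr <- function(object, ...) {
  out <- t(vapply(object$classes, function(cl) {
    f <- object$fits[[cl]]
    w <- drop(crossprod(f$model$coefs, f$model$SV))
    b <- -f$model$rho
    v <- c(w, b)
    if (f$flip) -v else v
  }, numeric(object$d + 1L)))
  colnames(out) <- c(paste0("w", seq_len(object$d)), "intercept")
  out
}
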