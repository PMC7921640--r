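# Evaluation statistics: Cohen's kappa, weighted (balanced) accuracy,
# relative kappa / performance reduction, one-vs-rest ROC AUC, paired t.

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, with observed
#' agreement `p_o` and chance agreement `p_e` from the marginal products.
#' When `p_e = 1` (both raters constant on the same class, hence perfect
#' agreement) the value is 1.
#'
#' @param y_true,y_pred equal-length label vectors over a shared finite
#'   label set.
#' @return Kappa in `[-1, 1]`.
#' @examples
#' cohens_kappa(c("A", "A", "B", "B"), c("A", "B", "B", "B"))  # 0.5
#' @export
cohens_kappa <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1L)
    hs_stop("y_true and y_pred must have equal length >= 1", "hs_input_error")
  lev <- union(levels(factor(y_true)), levels(factor(y_pred)))
  t <- factor(y_true, levels = lev); p <- factor(y_pred, levels = lev)
  n <- length(t)
  cm <- table(t, p)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1) return(1)
  (po - pe) / (1 - pe)
}

#' Weighted (balanced) accuracy
#'
#' Unweighted mean over the classes present in `y_true` of per-class
#' recall: correctly predicted instances of a class divided by the number
#' of instances of that class.
#'
#' @inheritParams cohens_kappa
#' @return Balanced accuracy in `[0, 1]`.
#' @export
weighted_accuracy <- function(y_true, y_pred) {
  if (length(y_true) < 1L) hs_stop("empty input", "hs_input_error")
  if (length(y_true) != length(y_pred))
    hs_stop("y_true and y_pred must have equal length", "hs_input_error")
  t <- droplevels(factor(y_true))
  rec <- vapply(levels(t), function(cl) {
    idx <- t == cl
    mean(as.character(y_pred)[idx] == cl)
  }, 1)
  mean(rec)
}

#' Relative Cohen's kappa
#'
#' A strategy's kappa divided by a reference kappa (the hierarchy-transfer
#' strategy at the same training fraction, in the shipped experiments),
#' rounded to 3 decimals for reporting.
#'
#' @param kappa observed kappa.
#' @param reference_kappa reference kappa (> 0).
#' @return `kappa / reference_kappa`, rounded to 3 decimals.
#' @examples
#' relative_kappa(0.727, 0.809)  # 0.899
#' @export
relative_kappa <- function(kappa, reference_kappa) {
  if (any(reference_kappa <= 0))
    hs_stop("reference_kappa must be > 0", "hs_domain_error")
  round(kappa / reference_kappa, 3)
}

#' Performance reduction
#'
#' `(1 - relative_kappa) * 100`, in percent, rounded to 1 decimal for
#' reporting.
#'
#' @param relative_kappa relative kappa in `[0, 1]`.
#' @return Percent reduction.
#' @examples
#' performance_reduction(0.903)  # 9.7
#' @export
performance_reduction <- function(relative_kappa) {
  if (any(relative_kappa < 0 | relative_kappa > 1))
    hs_stop("relative_kappa must be in [0, 1]", "hs_domain_error")
  round((1 - relative_kappa) * 100, 1)
}

#' One-vs-rest ROC AUC with macro average
#'
#' Per-class AUC by the rank (Mann-Whitney) statistic with midranks for
#' ties; the macro AUC is the unweighted mean over classes.  A class
#' absent from `y_true` gets `NA` and is excluded from the macro average
#' with a warning.
#'
#' @param scores numeric matrix (`n x n_classes`) of per-class scores,
#'   columns named by class.
#' @param y_true true labels.
#' @return A list with `per_class` (named numeric) and `macro`.
#' @export
roc_auc_ovr <- function(scores, y_true) {
  stopifnot(is.matrix(scores), !is.null(colnames(scores)))
  if (any(!is.finite(scores))) hs_stop("scores must be finite", "hs_input_error")
  if (nrow(scores) != length(y_true))
    hs_stop("scores and y_true lengths differ", "hs_input_error")
  y <- as.character(y_true)
  auc <- vapply(colnames(scores), function(cl) {
    pos <- y == cl
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    r <- rank(scores[, cl])      # midranks for ties
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, 1)
  if (anyNA(auc))
    warning(sprintf("class(es) absent from y_true, excluded from macro AUC: %s",
                    paste(names(auc)[is.na(auc)], collapse = ", ")))
  list(per_class = auc, macro = mean(auc, na.rm = TRUE))
}

#' Two-tailed paired t-test
#'
#' Standard paired t statistic with `n - 1` degrees of freedom.
#'
#' @param a,b equal-length numeric vectors (length >= 2) of paired
#'   measurements.
#' @return A list with `t`, `df`, and two-tailed `p`.
#' @examples
#' paired_t_test(c(1, 2, 3), c(0, 0, 0))
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    hs_stop("a and b must have equal length >= 2", "hs_input_error")
  d <- a - b
  if (stats::sd(d) == 0)
    hs_stop("degenerate input: all paired differences identical", "hs_degenerate_error")
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Evaluation report
#'
#' Builds the full evaluation report for a set of predictions: confusion
#' matrix (rows = truth), Cohen's kappa, weighted accuracy, and (when
#' per-class scores are supplied) one-vs-rest and macro AUC.
#'
#' @param y_true true labels.
#' @param y_pred predicted labels.
#' @param scores optional `n x n_classes` score matrix for ROC/AUC.
#' @param classes optional class ordering for the confusion matrix.
#' @return An object of class `"hs_eval"` with fields `confusion`, `kappa`,
#'   `weighted_accuracy`, `per_class_auc`, `macro_auc`, `n`.
#' @export
eval_report <- function(y_true, y_pred, scores = NULL, classes = NULL) {
  lev <- classes %||% union(levels(factor(y_true)), levels(factor(y_pred)))
  t <- factor(y_true, levels = lev); p <- factor(y_pred, levels = lev)
  cm <- table(truth = t, predicted = p)
  au <- if (!is.null(scores)) roc_auc_ovr(scores, y_true) else
    list(per_class = NULL, macro = NA_real_)
  structure(list(confusion = cm,
                 kappa = cohens_kappa(t, p),
                 weighted_accuracy = weighted_accuracy(t, p),
                 per_class_auc = au$per_class,
                 macro_auc = au$macro,
                 n = length(t)),
            class = "hs_eval")
}

#' @export
print.hs_eval <- function(x, ...) {
  cat(sprintf("Evaluation on %d cases\n", x$n))
  cat(sprintf("  Cohen's kappa:     %.3f\n", x$kappa))
  cat(sprintf("  Weighted accuracy: %.1f%%\n", 100 * x$weighted_accuracy))
  if (!is.null(x$per_class_auc)) {
    cat(sprintf("  Macro AUC:         %.3f\n", x$macro_auc))
    cat("  Per-class AUC:    ",
        paste(sprintf("%s %.3f", names(x$per_class_auc), x$per_class_auc),
              collapse = ", "), "\n")
  }
  cat("  Confusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' JSON summary plus the confusion matrix as CSV.
#'
#' @param x an `"hs_eval"` report.
#' @param path_prefix file prefix; writes `<prefix>.json` and
#'   `<prefix>_confusion.csv`.
#' @return Invisibly, the JSON path.
#' @export
write_eval <- function(x, path_prefix) {
  stopifnot(inherits(x, "hs_eval"))
  jsonlite::write_json(list(kappa = x$kappa,
                            weighted_accuracy = x$weighted_accuracy,
                            macro_auc = x$macro_auc,
                            per_class_auc = as.list(x$per_class_auc),
                            n = x$n),
                       paste0(path_prefix, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame.matrix(x$confusion),
                   paste0(path_prefix, "_confusion.csv"))
  invisible(paste0(path_prefix, ".json"))
}

#' Evaluate a fitted classifier on data
#'
#' Generic: methods exist for [hierstack()] bundles and [hs_stack()]
#' ensembles.
#'
#' @param object a fitted object.
#' @param ... passed to methods.
#' @return An `"hs_eval"` report.
#' @export
evaluate <- function(object, ...) UseMethod("evaluate")
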