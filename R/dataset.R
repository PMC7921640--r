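# Stratified splitting, fraction subsampling, and image augmentation.

#' On-the-fly augmentation policy
#'
#' Label-preserving geometric augmentation applied to each training image
#' every epoch: an optional horizontal flip (probability 1/2), a rotation
#' drawn uniformly in `[-rotation_deg_max, rotation_deg_max]` degrees, and
#' a shift drawn uniformly within `shift_frac_max` of the image size on
#' each axis.  The all-zero policy is the identity.
#'
#' @param horizontal_flip allow horizontal flips.
#' @param rotation_deg_max maximum absolute rotation, degrees, in `[0, 30]`.
#' @param shift_frac_max maximum absolute shift as a fraction of the image
#'   size, in `[0, 0.2]`.
#' @param per_epoch flag recording that augmentation is applied on the fly
#'   each epoch (informational; the training loop always applies it that
#'   way).
#' @return An object of class `"hs_augment_policy"`.
#' @export
hs_augment_policy <- function(horizontal_flip = TRUE, rotation_deg_max = 10,
                              shift_frac_max = 0.05, per_epoch = TRUE) {
  if (rotation_deg_max < 0 || rotation_deg_max > 30)
    hs_stop("rotation_deg_max must be in [0, 30]", "hs_config_error")
  if (shift_frac_max < 0 || shift_frac_max > 0.2)
    hs_stop("shift_frac_max must be in [0, 0.2]", "hs_config_error")
  structure(list(horizontal_flip = isTRUE(horizontal_flip),
                 rotation_deg_max = rotation_deg_max,
                 shift_frac_max = shift_frac_max,
                 per_epoch = isTRUE(per_epoch)),
            class = "hs_augment_policy")
}

is_identity_policy <- function(pol) {
  !pol$horizontal_flip && pol$rotation_deg_max == 0 && pol$shift_frac_max == 0
}

#' Augment one image
#'
#' Applies a random flip/rotation/shift sampled within the policy bounds.
#' Flips are exact index reversals; rotation and shift are applied as a
#' single bilinear affine resampling (borders filled with the image mean).
#' Output is clipped to `[0, 1]`.  With the all-zero policy the input is
#' returned bit-identically.
#'
#' @param image numeric matrix with values in `[0, 1]`.
#' @param policy an [hs_augment_policy()].
#' @param seed optional seed; when `NULL` the draws come from the current
#'   RNG stream (as inside a seeded training loop).
#' @param force_flip force the flip on (for testing the involution).
#' @return The augmented image matrix, clipped to `[0, 1]`.
#' @export
augment_image <- function(image, policy = hs_augment_policy(), seed = NULL,
                          force_flip = FALSE) {
  stopifnot(is.matrix(image))
  if (!is.null(seed)) return(with_seed(seed, augment_image(image, policy,
                                                           force_flip = force_flip)))
  if (is_identity_policy(policy) && !force_flip) return(image)
  h <- nrow(image); w <- ncol(image)
  if (force_flip || (policy$horizontal_flip && stats::runif(1) < 0.5))
    image <- image[, rev(seq_len(w)), drop = FALSE]
  ang <- if (policy$rotation_deg_max > 0)
    stats::runif(1, -policy$rotation_deg_max, policy$rotation_deg_max) else 0
  sh <- if (policy$shift_frac_max > 0)
    stats::runif(2, -policy$shift_frac_max, policy$shift_frac_max) * c(h, w) else c(0, 0)
  if (ang != 0 || any(sh != 0)) {
    th <- ang * pi / 180
    A <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    ctr <- c(h, w) / 2
    tr <- ctr - as.vector(ctr %*% A) + sh
    m <- rbind(A, tr)
    out <- EBImage::affine(EBImage::Image(image), m, filter = "bilinear",
                           bg.col = mean(image))
    image <- EBImage::imageData(out)[seq_len(h), seq_len(w)]
  }
  pmin(pmax(image, 0), 1)
}

# --------------------------------------------------------------------------
# splitting -----------------------------------------------------------------

check_named_labels <- function(labels) {
  labels <- as.factor(labels)
  if (is.null(names(labels)) || anyDuplicated(names(labels)))
    hs_stop("labels must be a named vector with unique case ids", "hs_input_error")
  droplevels(labels)
}

#' Stratified train/test split
#'
#' Allocates, per class, `round(count * test_fraction)` cases (half away
#' from zero) to the test side and the remainder to training, repairing any
#' stratum that would end up empty on either side, so each class appears on
#' both sides and the per-class test proportion stays within one case of
#' the global test fraction.  Deterministic under `seed`.
#'
#' @param labels factor (or character) of class labels named by case id.
#' @param test_fraction test proportion in `(0, 1)`.
#' @param seed integer seed.
#' @param replicate_index bookkeeping index (1..R) of this shuffle.
#' @return An object of class `"hs_split"` with `train_ids`, `test_ids`,
#'   `replicate_index`, `seed`.
#' @examples
#' labs <- setNames(rep(c("a", "b"), each = 5), paste0("c", 1:10))
#' sp <- stratified_split(labs, 0.2, seed = 1)
#' lengths(sp[c("train_ids", "test_ids")])
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1L,
                             replicate_index = 1L) {
  labels <- check_named_labels(labels)
  if (test_fraction <= 0 || test_fraction >= 1)
    hs_stop("test_fraction must be in (0, 1)", "hs_config_error")
  tab <- table(labels)
  if (any(tab < 2L))
    hs_stop(sprintf("every class needs >= 2 cases; offending class(es): %s",
                    paste(names(tab)[tab < 2L], collapse = ", ")),
            "hs_stratification_error")
  with_seed(seed, {
    test_ids <- character(0)
    for (cl in names(tab)) {
      ids <- names(labels)[labels == cl]
      n_test <- round_half_up(length(ids) * test_fraction)
      n_test <- max(1L, min(length(ids) - 1L, n_test))
      test_ids <- c(test_ids, sample(ids, n_test))
    }
    structure(list(train_ids = setdiff(names(labels), test_ids),
                   test_ids = test_ids,
                   replicate_index = as.integer(replicate_index),
                   seed = as.integer(seed)),
              class = "hs_split")
  })
}

#' Create replicate shuffled splits
#'
#' @param labels named factor of class labels.
#' @param replicates number of independent shuffles.
#' @param test_fraction test proportion.
#' @param seed master seed; each replicate uses [child_seed()].
#' @return A list of [stratified_split()] objects.
#' @export
make_splits <- function(labels, replicates = 3L, test_fraction = 0.2, seed = 1L) {
  lapply(seq_len(replicates), function(r)
    stratified_split(labels, test_fraction,
                     seed = child_seed(seed, "split", r), replicate_index = r))
}

#' Stratified fraction of a training set
#'
#' Keeps, per class, `round(count * fraction)` (half away from zero, at
#' least 1) of the split's training cases; `fraction = 1` keeps everything.
#' Test cases are never touched.
#'
#' @param split an [stratified_split()] object.
#' @param labels named factor of class labels (covering the split's ids).
#' @param fraction fraction in `(0, 1]`.
#' @param seed integer seed.
#' @return An object of class `"hs_fraction"` with `fraction`, `kept_ids`,
#'   `seed`.
#' @export
subsample_fraction <- function(split, labels, fraction, seed = 1L) {
  stopifnot(inherits(split, "hs_split"))
  labels <- check_named_labels(labels)
  if (fraction <= 0 || fraction > 1)
    hs_stop("fraction must be in (0, 1]", "hs_config_error")
  if (length(split$train_ids) == 0L)
    hs_stop("split has an empty training side", "hs_input_error")
  if (fraction == 1)
    return(structure(list(fraction = 1, kept_ids = split$train_ids,
                          seed = as.integer(seed)), class = "hs_fraction"))
  tl <- labels[split$train_ids]
  with_seed(seed, {
    kept <- character(0)
    for (cl in levels(droplevels(tl))) {
      ids <- split$train_ids[tl == cl]
      k <- max(1L, round_half_up(length(ids) * fraction))
      kept <- c(kept, sample(ids, k))
    }
    structure(list(fraction = fraction, kept_ids = kept,
                   seed = as.integer(seed)), class = "hs_fraction")
  })
}

#' Write / read a split as JSON
#'
#' @param split an `"hs_split"` object.
#' @param path output JSON file.
#' @return `write_split` returns `path` invisibly; `read_split` returns the
#'   `"hs_split"` object.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "hs_split"))
  jsonlite::write_json(list(replicate = split$replicate_index, seed = split$seed,
                            train_ids = split$train_ids, test_ids = split$test_ids),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train_ids = as.character(x$train_ids),
                 test_ids = as.character(x$test_ids),
                 replicate_index = as.integer(x$replicate),
                 seed = as.integer(x$seed)),
            class = "hs_split")
}

#' @export
print.hs_split <- function(x, ...) {
  cat(sprintf("Stratified split (replicate %d, seed %d): %d train / %d test\n",
              x$replicate_index, x$seed, length(x$train_ids), length(x$test_ids)))
  invisible(x)
}
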