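# Synthetic multi-modal optic-disc image generator.
#
# Each case carries one grayscale image per modality.  Diseased cases share
# a disease-common signal (a centred disc blob, emulating the altered optic
# disc every subtype exhibits) plus a subtype-specific signal (an angular
# sector of that disc at a subtype-specific orientation, emulating
# subtype-specific rim morphology).  Because the subtype signal modulates the
# same disc structure, features learned for normal-vs-disease detection
# are reusable for subtype discrimination - the property hierarchy
# transfer learning exploits.  Modalities differ in geometry and in
# signal-to-noise ratio; the fourth ("discV") is deliberately weak.

#' Configuration of the synthetic image generator
#'
#' @param n_subtypes number of disease subtypes `n` (classes = `n + 1`).
#' @param class_counts integer vector of length `n + 1`, normal first.
#'   The default mirrors a clinical optic-disc dataset with 156 normal and
#'   118/266/307/107 subtype cases.
#' @param image_size `c(height, width)` in pixels.
#' @param n_modalities number of image modalities per case.
#' @param modalities modality tags, length `n_modalities`.
#' @param disease_signal_strength per-modality amplitude of the
#'   disease-common disc signal (>= 0).  The default makes "discV" 0.4x
#'   the weakest of the others, mirroring a consistently weak modality.
#' @param subtype_signal_strength per-modality amplitude of the
#'   subtype-specific disc-sector signal (>= 0).
#' @param noise_sd standard deviation of the iid Gaussian pixel noise
#'   (> 0); images are clipped to `[0, 1]` after summing.
#' @param background background gray level.
#' @param seed integer seed; identical configuration (including seed)
#'   yields a bit-identical dataset.
#' @return An object of class `"hs_sim_config"`.
#' @export
hs_sim_config <- function(n_subtypes = 4L,
                          class_counts = c(156L, 118L, 266L, 307L, 107L),
                          image_size = c(64L, 64L),
                          n_modalities = 4L,
                          modalities = c("projection", "enface", "discH", "discV"),
                          disease_signal_strength = c(0.30, 0.36, 0.30, 0.10),
                          subtype_signal_strength = c(0.22, 0.30, 0.24, 0.064),
                          noise_sd = 0.25,
                          background = 0.35,
                          seed = 1L) {
  n <- as.integer(n_subtypes)
  if (n < 1L) hs_stop("invalid configuration: n_subtypes must be >= 1", "hs_config_error")
  if (length(class_counts) != n + 1L)
    hs_stop("invalid configuration: class_counts must have length n_subtypes + 1", "hs_config_error")
  if (any(class_counts < 2L))
    hs_stop("invalid configuration: class_counts must all be >= 2", "hs_config_error")
  if (length(modalities) != n_modalities || anyDuplicated(modalities))
    hs_stop("invalid configuration: modalities must be n_modalities unique tags", "hs_config_error")
  if (length(disease_signal_strength) != n_modalities ||
      any(!is.finite(disease_signal_strength)) || any(disease_signal_strength < 0))
    hs_stop("invalid configuration: disease_signal_strength must be n_modalities finite non-negative values", "hs_config_error")
  if (length(subtype_signal_strength) != n_modalities ||
      any(!is.finite(subtype_signal_strength)) || any(subtype_signal_strength < 0))
    hs_stop("invalid configuration: subtype_signal_strength must be n_modalities finite non-negative values", "hs_config_error")
  if (!is.finite(noise_sd) || noise_sd <= 0)
    hs_stop("invalid configuration: noise_sd must be finite and > 0", "hs_config_error")
  subtypes <- if (n == 4L) c("FI", "GE", "MY", "SS") else paste0("S", seq_len(n))
  structure(list(n_subtypes = n,
                 class_counts = as.integer(class_counts),
                 image_size = as.integer(image_size),
                 n_modalities = as.integer(n_modalities),
                 modalities = as.character(modalities),
                 disease_signal_strength = as.numeric(disease_signal_strength),
                 subtype_signal_strength = as.numeric(subtype_signal_strength),
                 noise_sd = noise_sd, background = background,
                 seed = as.integer(seed),
                 classes = c("normal", subtypes), subtypes = subtypes),
            class = "hs_sim_config")
}

# Deterministic noiseless templates, a fixed function of (modality, subtype).
# Returns per modality: disease (disc blob, max 1) and per-subtype angular
# disc sectors (max 1), all unscaled.
hs_templates <- function(config) {
  h <- config$image_size[1L]; w <- config$image_size[2L]
  s <- min(h, w)
  yy <- matrix(rep(seq_len(h) - 0.5, w), h, w) / s
  xx <- matrix(rep(seq_len(w) - 0.5, each = h), h, w) / s
  rfr <- c(0.20, 0.24, 0.17, 0.22)
  oxs <- c(0, 0.03, -0.03, 0)
  oys <- c(0, 0, 0.03, -0.03)
  n <- config$n_subtypes
  lapply(seq_len(config$n_modalities), function(m) {
    i <- (m - 1L) %% 4L + 1L
    cx <- w / (2 * s) + oxs[i]; cy <- h / (2 * s) + oys[i]
    r <- rfr[i]
    d <- sqrt((xx - cx)^2 + (yy - cy)^2)
    disease <- exp(-(d / r)^4)
    ang <- atan2(yy - cy, xx - cx)
    subtype <- lapply(seq_len(n), function(si) {
      th <- (20 + (si - 1) * 360 / n) * pi / 180
      dth <- abs(((ang - th + pi) %% (2 * pi)) - pi)
      disease * exp(-(dth / (50 * pi / 180))^2)
    })
    list(disease = disease, subtype = subtype)
  })
}

#' Generate a synthetic multi-modal dataset
#'
#' Produces exactly `sum(class_counts)` cases, `class_counts[k]` of class
#' `k` (normal first).  Each modality image is iid Gaussian background
#' noise plus, for diseased cases, the disease-common disc template scaled
#' by the modality's disease signal strength and the subtype's disc-sector
#' template scaled by the modality's subtype signal strength, clipped to
#' `[0, 1]`.  Identical configuration (including seed) yields a
#' bit-identical dataset.
#'
#' @param config an [hs_sim_config()].
#' @return An object of class `"hs_dataset"`: a list with `cases` (each a
#'   list of `case_id`, `images` named by modality, `root`, `leaf`),
#'   `config`, `classes`, `modalities`.
#' @examples
#' d <- hs_simulate(hs_sim_config(class_counts = c(3, 2, 2, 2, 2),
#'                                image_size = c(16, 16)))
#' length(d$cases)
#' @export
hs_simulate <- function(config) {
  stopifnot(inherits(config, "hs_sim_config"))
  tpl <- hs_templates(config)
  h <- config$image_size[1L]; w <- config$image_size[2L]
  n_cases <- sum(config$class_counts)
  cls <- rep(config$classes, times = config$class_counts)
  ids <- sprintf("case%04d", seq_len(n_cases))
  cases <- with_seed(config$seed, {
    lapply(seq_len(n_cases), function(i) {
      leaf <- if (cls[i] == "normal") NA_character_ else cls[i]
      si <- if (is.na(leaf)) 0L else match(leaf, config$subtypes)
      imgs <- lapply(seq_len(config$n_modalities), function(m) {
        img <- config$background + stats::rnorm(h * w, 0, config$noise_sd)
        dim(img) <- c(h, w)
        if (si > 0L)
          img <- img + config$disease_signal_strength[m] * tpl[[m]]$disease +
            config$subtype_signal_strength[m] * tpl[[m]]$subtype[[si]]
        pmin(pmax(img, 0), 1)
      })
      names(imgs) <- config$modalities
      list(case_id = ids[i], images = imgs,
           root = if (is.na(leaf)) "normal" else "disease", leaf = leaf)
    })
  })
  structure(list(cases = cases, config = config, classes = config$classes,
                 modalities = config$modalities),
            class = "hs_dataset")
}

#' @export
print.hs_dataset <- function(x, ...) {
  tab <- table(hs_labels(x))
  cat(sprintf("Synthetic multi-modal dataset: %d cases, %d modalities (%s), %dx%d px\n",
              length(x$cases), length(x$modalities),
              paste(x$modalities, collapse = ", "),
              x$config$image_size[1], x$config$image_size[2]))
  print(tab)
  invisible(x)
}

#' Class labels of a dataset
#'
#' @param dataset an [hs_simulate()] dataset.
#' @return A factor (levels = the dataset's classes, normal first) named by
#'   case id; normal cases are labelled `"normal"`, diseased cases by their
#'   subtype.
#' @export
hs_labels <- function(dataset) {
  stopifnot(inherits(dataset, "hs_dataset"))
  v <- vapply(dataset$cases, function(cs)
    if (cs$root == "normal") "normal" else cs$leaf, character(1))
  names(v) <- vapply(dataset$cases, `[[`, character(1), "case_id")
  factor(v, levels = dataset$classes)
}

#' Root (normal/disease) labels of a dataset
#'
#' Every subtype collapses to `"disease"`; the mapping from the full label
#' set onto \{normal, disease\} is surjective.
#'
#' @inheritParams hs_labels
#' @return A factor with levels `c("normal", "disease")`, named by case id.
#' @export
hs_root_labels <- function(dataset) {
  labs <- hs_labels(dataset)
  factor(ifelse(labs == "normal", "normal", "disease"),
         levels = c("normal", "disease"))
}

# pixels x n matrix of one modality over the given case ids (default all)
dataset_matrix <- function(dataset, modality, ids = NULL) {
  all_ids <- names(hs_labels(dataset))
  idx <- if (is.null(ids)) seq_along(dataset$cases) else match(ids, all_ids)
  if (anyNA(idx)) hs_stop("unknown case id(s)", "hs_input_error")
  if (!modality %in% dataset$modalities)
    hs_stop(sprintf("unknown modality '%s'", modality), "hs_input_error")
  npix <- length(dataset$cases[[1L]]$images[[modality]])
  vapply(dataset$cases[idx], function(cs) as.vector(cs$images[[modality]]),
         numeric(npix))
}

#' Ground-truth matched-filter oracle classifier
#'
#' Brute-force reference classifier for generator sanity checks: scores
#' each class by the summed cross-correlation of the case's images with
#' the class's noiseless template stack (with the usual energy correction,
#' i.e. the Gaussian maximum-likelihood discriminant), and returns the
#' best-scoring class.  On noiseless data it is exact; no trained model
#' should beat it by more than sampling error.
#'
#' @param x an `"hs_dataset"` or one of its `cases` elements.
#' @param config the [hs_sim_config()] the data were generated under.
#' @return For a dataset, a factor of predicted class labels named by case
#'   id; for a single case, a list with `root`, `leaf`, and `class`.
#' @export
oracle_classify <- function(x, config) {
  stopifnot(inherits(config, "hs_sim_config"))
  tpl <- hs_templates(config)
  n <- config$n_subtypes
  # per-class per-modality signal (background excluded); normal = all-zero
  sig <- lapply(seq_len(n + 1L), function(k) {
    lapply(seq_len(config$n_modalities), function(m) {
      if (k == 1L) 0 * tpl[[m]]$disease
      else config$disease_signal_strength[m] * tpl[[m]]$disease +
        config$subtype_signal_strength[m] * tpl[[m]]$subtype[[k - 1L]]
    })
  })
  energy <- vapply(sig, function(s) sum(vapply(s, function(t) sum(t * t), 1)), 1)
  score_case <- function(cs) {
    if (!identical(dim(cs$images[[1L]]), config$image_size) ||
        length(cs$images) != config$n_modalities)
      hs_stop("case does not match config (image size or modality count)",
              "hs_input_error")
    sc <- vapply(seq_len(n + 1L), function(k) {
      s <- 0
      for (m in seq_len(config$n_modalities))
        s <- s + sum((cs$images[[m]] - config$background) * sig[[k]][[m]])
      s - 0.5 * energy[k]
    }, 1)
    which.max(sc)
  }
  if (inherits(x, "hs_dataset")) {
    k <- vapply(x$cases, score_case, 1L)
    out <- factor(config$classes[k], levels = config$classes)
    names(out) <- vapply(x$cases, `[[`, character(1), "case_id")
    out
  } else {
    k <- score_case(x)
    list(root = if (k == 1L) "normal" else "disease",
         leaf = if (k == 1L) NA_character_ else config$subtypes[k - 1L],
         class = config$classes[k])
  }
}

# --------------------------------------------------------------------------
# PNG + manifest I/O --------------------------------------------------------

#' Write a dataset as PNG files plus a CSV manifest
#'
#' One 8-bit grayscale PNG per case per modality under
#' `out_dir/<modality>/<case_id>.png`, plus `manifest.csv` with columns
#' `case_id`, one `modality_path_<tag>` per modality, `root_label`, and
#' `leaf_label` (empty string for normal cases).
#'
#' @param dataset an `"hs_dataset"`.
#' @param out_dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "hs_dataset"))
  for (m in dataset$modalities)
    dir.create(file.path(out_dir, m), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset$cases, function(cs) {
    paths <- vapply(dataset$modalities, function(m) {
      p <- file.path(out_dir, m, paste0(cs$case_id, ".png"))
      png::writePNG(cs$images[[m]], p)
      file.path(m, paste0(cs$case_id, ".png"))
    }, character(1))
    c(case_id = cs$case_id, stats::setNames(paths, paste0("modality_path_", dataset$modalities)),
      root_label = cs$root, leaf_label = if (is.na(cs$leaf)) "" else cs$leaf)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  manifest <- file.path(out_dir, "manifest.csv")
  utils::write.csv(df, manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset back from a manifest
#'
#' @param manifest path to a `manifest.csv` written by [write_dataset()].
#' @return An `"hs_dataset"` (pixel values carry 8-bit PNG quantisation;
#'   labels and the case-to-file mapping are exact).
#' @export
read_dataset <- function(manifest) {
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE,
                        colClasses = "character")
  base <- dirname(manifest)
  mods <- sub("^modality_path_", "", grep("^modality_path_", names(df), value = TRUE))
  cases <- lapply(seq_len(nrow(df)), function(i) {
    imgs <- lapply(mods, function(m) {
      img <- png::readPNG(file.path(base, df[[paste0("modality_path_", m)]][i]))
      if (length(dim(img)) == 3L) img <- img[, , 1L]
      img
    })
    names(imgs) <- mods
    leaf <- df$leaf_label[i]
    list(case_id = df$case_id[i], images = imgs, root = df$root_label[i],
         leaf = if (identical(leaf, "")) NA_character_ else leaf)
  })
  subtypes <- unique(df$leaf_label[df$leaf_label != ""])
  h <- nrow(cases[[1L]]$images[[1L]]); w <- ncol(cases[[1L]]$images[[1L]])
  structure(list(cases = cases, config = NULL,
                 classes = c("normal", sort(subtypes)), modalities = mods,
                 image_size = c(h, w)),
            class = "hs_dataset")
}

# subset of a dataset by case ids (keeps config/classes)
dataset_subset <- function(dataset, ids) {
  all_ids <- vapply(dataset$cases, `[[`, character(1), "case_id")
  idx <- match(ids, all_ids)
  if (anyNA(idx)) hs_stop("unknown case id(s)", "hs_input_error")
  dataset$cases <- dataset$cases[idx]
  dataset
}
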