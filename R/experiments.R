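# Orchestration of the two shipped experiments: strategy comparison on the
# full training data, and the learning-curve study over training fractions.

#' Experiment configuration
#'
#' @param sim an [hs_sim_config()] describing the synthetic dataset (its
#'   seed is re-derived from `seed` so that independent experiment seeds
#'   draw independent datasets).
#' @param arch an [hs_arch()] template for all networks.
#' @param control an [hs_control()] for network training.
#' @param pretext_control an [hs_control()] for pretext pretraining;
#'   `NULL` disables pretraining (random-initialisation source baseline).
#' @param strategies subset of `c("fc", "hc", "hc_htl")`.
#' @param modalities modality tags to train single-input bundles on.
#' @param fractions training fractions for the learning curve.
#' @param replicates number of shuffled stratified train/test splits.
#' @param test_fraction held-out test proportion.
#' @param include_stacked train the stacking ensemble over the modalities.
#' @param include_multiinput train the multiple-input network comparator.
#' @param meta,meta_folds metamodel confidence generation (see
#'   [hierstack()]).
#' @param seed master seed; everything else derives from it via
#'   [child_seed()].
#' @param out_dir optional directory: completed cells are persisted as
#'   they finish.
#' @return An object of class `"hs_experiment_config"`.
#' @export
hs_experiment_config <- function(sim = hs_sim_config(),
                                 arch = NULL,
                                 control = hs_control(),
                                 pretext_control = hs_control(epochs = 10L),
                                 strategies = c("fc", "hc", "hc_htl"),
                                 modalities = sim$modalities,
                                 fractions = c(0.25, 0.375, 0.5, 0.625, 0.75, 0.875, 1),
                                 replicates = 3L,
                                 test_fraction = 0.2,
                                 include_stacked = TRUE,
                                 include_multiinput = TRUE,
                                 meta = "oof", meta_folds = 5L,
                                 seed = 1L, out_dir = NULL) {
  if (any(fractions <= 0 | fractions > 1))
    hs_stop("fractions must lie in (0, 1]", "hs_config_error")
  if (replicates < 1L) hs_stop("replicates must be >= 1", "hs_config_error")
  stopifnot(all(strategies %in% c("fc", "hc", "hc_htl")))
  if (is.null(arch))
    arch <- hs_arch(n_classes = 2L, input_size = sim$image_size)
  sim$seed <- child_seed(seed, "sim")
  structure(list(sim = sim, arch = arch, control = control,
                 pretext_control = pretext_control,
                 strategies = strategies, modalities = modalities,
                 fractions = fractions, replicates = as.integer(replicates),
                 test_fraction = test_fraction,
                 include_stacked = isTRUE(include_stacked),
                 include_multiinput = isTRUE(include_multiinput),
                 meta = meta, meta_folds = as.integer(meta_folds),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "hs_experiment_config")
}

#' Desk-scale benchmark configuration
#'
#' The package's default study conditions: 225 cases with class counts
#' 40/30/60/70/25 (the clinical imbalance scaled down), 24x24-pixel
#' images over four modalities with a deliberately weak fourth modality,
#' a 2-block 6/12-channel network, short RMSprop training with on-the-fly
#' rotation/shift augmentation, 3-fold out-of-fold metamodels, and three
#' replicate splits.  Sized so the full learning curve runs in minutes on
#' one CPU; the clinical scale stays reachable through the arguments.
#'
#' @param seed master seed.
#' @param ... overrides passed on to [hs_experiment_config()].
#' @return An `"hs_experiment_config"`.
#' @export
hs_benchmark_config <- function(seed = 1L, ...) {
  sim <- hs_sim_config(class_counts = c(40L, 30L, 60L, 70L, 25L),
                       image_size = c(24L, 24L),
                       disease_signal_strength = c(0.30, 0.36, 0.30, 0.10),
                       subtype_signal_strength = c(0.22, 0.30, 0.24, 0.064),
                       noise_sd = 0.25)
  arch <- hs_arch(n_blocks = 2L, channels = c(6L, 12L), dense_units = 24L,
                  n_classes = 2L, input_size = c(24L, 24L))
  ctl <- hs_control(epochs = 12L, batch_size = 16L, learning_rate = 2e-3,
                    augment = hs_augment_policy(horizontal_flip = FALSE,
                                                rotation_deg_max = 10,
                                                shift_frac_max = 0.05))
  hs_experiment_config(sim = sim, arch = arch, control = ctl,
                       pretext_control = hs_control(epochs = 6L, batch_size = 16L,
                                                    learning_rate = 2e-3,
                                                    augment = hs_augment_policy(FALSE, 0, 0)),
                       meta = "naive", meta_folds = 2L, seed = seed, ...)
}

# shared setup: dataset, labels, source model, splits
experiment_setup <- function(config) {
  data <- hs_simulate(config$sim)
  labs <- hs_labels(data)
  source_model <- if (!is.null(config$pretext_control))
    hs_pretext(config$arch, control = config$pretext_control,
               seed = child_seed(config$seed, "pretext"))
  splits <- make_splits(labs, config$replicates, config$test_fraction,
                        seed = config$seed)
  list(data = data, labs = labs, source = source_model, splits = splits)
}

fit_one <- function(config, setup, strategy, modality, replicate, train_ids) {
  hierstack(setup$data, strategy = strategy, modality = modality,
            source = setup$source, arch = config$arch, control = config$control,
            meta = config$meta, meta_folds = config$meta_folds,
            seed = child_seed(config$seed,
                              sprintf("bundle_%s_%s_r%d", strategy,
                                      paste(modality, collapse = "+"), replicate)),
            subset = train_ids)
}

persist_cell <- function(config, row) {
  if (is.null(config$out_dir)) return(invisible())
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- file.path(config$out_dir, "cells.csv")
  utils::write.table(row, f, sep = ",", row.names = FALSE,
                     col.names = !file.exists(f), append = file.exists(f))
}

#' Compare the training strategies on full training data
#'
#' For each replicate split trains every requested strategy on every
#' modality, plus the stacking ensemble over the per-modality bundles and
#' the multiple-input network comparator, and evaluates all of them on the
#' untouched test set.  Reports per-cell Cohen's kappa, weighted accuracy
#' and macro AUC, their means and standard deviations, and all pairwise
#' paired t-tests between strategies (and stacking vs each single
#' modality).
#'
#' @param config an [hs_experiment_config()].
#' @return An object of class `"hs_comparison"` with fields `results`
#'   (one row per replicate x strategy x model), `summary`, `t_tests`,
#'   `rocs`, `splits`, `config`.
#' @export
run_strategy_comparison <- function(config) {
  stopifnot(inherits(config, "hs_experiment_config"))
  setup <- experiment_setup(config)
  rows <- list(); rocs <- list()
  for (r in seq_len(config$replicates)) {
    sp <- setup$splits[[r]]
    for (strat in config$strategies) {
      bundles <- list()
      for (mod in config$modalities) {
        b <- fit_one(config, setup, strat, mod, r, sp$train_ids)
        bundles[[mod]] <- b
        ev <- evaluate(b, setup$data, subset = sp$test_ids)
        row <- data.frame(replicate = r, strategy = strat, model = mod,
                          kappa = ev$kappa, weighted_accuracy = ev$weighted_accuracy,
                          macro_auc = ev$macro_auc)
        rows[[length(rows) + 1L]] <- row
        persist_cell(config, row)
      }
      if (config$include_stacked && length(config$modalities) > 1L) {
        st <- hs_stack(bundles, setup$data)
        ev <- evaluate(st, setup$data, subset = sp$test_ids)
        row <- data.frame(replicate = r, strategy = strat, model = "stacked",
                          kappa = ev$kappa, weighted_accuracy = ev$weighted_accuracy,
                          macro_auc = ev$macro_auc)
        rows[[length(rows) + 1L]] <- row
        persist_cell(config, row)
        if (r == 1L) {
          pr <- predict(st, setup$data, subset = sp$test_ids)
          rocs[[strat]] <- list(scores = pr$scores,
                                truth = as.character(setup$labs[sp$test_ids]))
        }
      }
      if (config$include_multiinput && length(config$modalities) > 1L) {
        mb <- fit_one(config, setup, strat, config$modalities, r, sp$train_ids)
        ev <- evaluate(mb, setup$data, subset = sp$test_ids)
        row <- data.frame(replicate = r, strategy = strat, model = "multiinput",
                          kappa = ev$kappa, weighted_accuracy = ev$weighted_accuracy,
                          macro_auc = ev$macro_auc)
        rows[[length(rows) + 1L]] <- row
        persist_cell(config, row)
      }
    }
  }
  results <- do.call(rbind, rows)
  structure(list(results = results,
                 summary = summarize_cells(results),
                 t_tests = comparison_t_tests(results),
                 rocs = rocs,
                 splits = setup$splits,
                 config = config),
            class = "hs_comparison")
}

summarize_cells <- function(results, by = c("strategy", "model")) {
  if (is.null(results) || nrow(results) == 0L)
    return(data.frame(strategy = character(), model = character(),
                      mean_kappa = numeric(), sd_kappa = numeric(),
                      mean_weighted_accuracy = numeric()))
  ag <- stats::aggregate(results[c("kappa", "weighted_accuracy")],
                         results[by], function(v) c(mean = mean(v), sd = stats::sd(v)))
  out <- ag[by]
  out$mean_kappa <- ag$kappa[, "mean"]
  out$sd_kappa <- ag$kappa[, "sd"]
  out$mean_weighted_accuracy <- ag$weighted_accuracy[, "mean"]
  out
}

comparison_t_tests <- function(results) {
  out <- list()
  for (mod in unique(results$model)) {
    sub <- results[results$model == mod, ]
    strats <- unique(sub$strategy)
    if (length(strats) < 2L) next
    for (i in seq_along(strats)) for (j in seq_along(strats)) {
      if (i >= j) next
      a <- sub$kappa[sub$strategy == strats[i]][order(sub$replicate[sub$strategy == strats[i]])]
      b <- sub$kappa[sub$strategy == strats[j]][order(sub$replicate[sub$strategy == strats[j]])]
      p <- tryCatch(paired_t_test(a, b)$p, error = function(e) NA_real_)
      out[[length(out) + 1L]] <- data.frame(model = mod, a = strats[i],
                                            b = strats[j], p = p)
    }
  }
  if ("stacked" %in% results$model) {
    for (strat in unique(results$strategy)) {
      sub <- results[results$strategy == strat, ]
      st <- sub$kappa[sub$model == "stacked"][order(sub$replicate[sub$model == "stacked"])]
      for (mod in setdiff(unique(sub$model), c("stacked"))) {
        sm <- sub$kappa[sub$model == mod][order(sub$replicate[sub$model == mod])]
        p <- tryCatch(paired_t_test(st, sm)$p, error = function(e) NA_real_)
        out[[length(out) + 1L]] <- data.frame(model = paste0("stacked_vs_", mod),
                                              a = strat, b = strat, p = p)
      }
    }
  }
  if (length(out) == 0L) return(data.frame(model = character(), a = character(),
                                           b = character(), p = numeric()))
  do.call(rbind, out)
}

#' @export
print.hs_comparison <- function(x, ...) {
  cat(sprintf("Strategy comparison: %d replicate(s), strategies [%s]\n",
              x$config$replicates, paste(x$config$strategies, collapse = ", ")))
  cat("Mean Cohen's kappa (sd) by strategy and model:\n")
  s <- x$summary
  s$mean_kappa <- sprintf("%.3f (%.3f)", s$mean_kappa,
                          ifelse(is.na(s$sd_kappa), 0, s$sd_kappa))
  print(s[c("strategy", "model", "mean_kappa", "mean_weighted_accuracy")],
        row.names = FALSE)
  invisible(x)
}

#' Learning-curve experiment over training fractions
#'
#' For each replicate split and each training fraction, keeps a stratified
#' fraction of the training cases, trains each strategy on it (a
#' single-input bundle when one modality is configured; per-modality
#' bundles plus the stacking ensemble when several are), and evaluates on
#' the untouched test set.  Summaries include, per strategy and fraction,
#' the mean and sd of Cohen's kappa, the relative kappa with respect to
#' the hierarchy-transfer strategy at the same fraction, and the
#' performance reduction.
#'
#' @param config an [hs_experiment_config()]; `fractions`, `strategies`
#'   and `modalities` drive the grid.
#' @return An object of class `"hs_learning_curve"` with `results`,
#'   `summary`, `table` (wide, one row per fraction), `splits`,
#'   `fraction_ids`, `config`.
#' @export
run_learning_curve <- function(config) {
  stopifnot(inherits(config, "hs_experiment_config"))
  setup <- experiment_setup(config)
  stacked_mode <- length(config$modalities) > 1L && config$include_stacked
  rows <- list(); frac_ids <- list(); rocs <- list()
  for (r in seq_len(config$replicates)) {
    sp <- setup$splits[[r]]
    for (fr in config$fractions) {
      plan <- subsample_fraction(sp, setup$labs, fr,
                                 seed = child_seed(config$seed, "fraction",
                                                   r * 1000L + round(fr * 1000)))
      frac_ids[[sprintf("r%d_f%g", r, fr)]] <-
        list(replicate = r, fraction = fr, kept_ids = plan$kept_ids)
      for (strat in config$strategies) {
        if (stacked_mode) {
          bundles <- lapply(config$modalities, function(mod)
            fit_one(config, setup, strat, mod, r, plan$kept_ids))
          names(bundles) <- config$modalities
          fit <- hs_stack(bundles, setup$data)
        } else {
          fit <- fit_one(config, setup, strat, config$modalities[1L], r,
                         plan$kept_ids)
        }
        ev <- evaluate(fit, setup$data, subset = sp$test_ids)
        row <- data.frame(replicate = r, fraction = fr, strategy = strat,
                          n_train = length(plan$kept_ids),
                          kappa = ev$kappa,
                          weighted_accuracy = ev$weighted_accuracy,
                          macro_auc = ev$macro_auc)
        rows[[length(rows) + 1L]] <- row
        persist_cell(config, row)
        if (r == 1L && fr == min(config$fractions) && strat == "hc_htl") {
          pr <- predict(fit, setup$data, subset = sp$test_ids)
          rocs[["hc_htl_smallest_fraction"]] <-
            list(scores = pr$scores, truth = as.character(setup$labs[sp$test_ids]))
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  summ <- summarize_cells(results, by = c("strategy", "fraction"))
  summ$n_train <- results$n_train[match(paste(summ$strategy, summ$fraction),
                                        paste(results$strategy, results$fraction))]
  ref <- if ("hc_htl" %in% summ$strategy)
    summ$mean_kappa[match(paste("hc_htl", summ$fraction),
                          paste(summ$strategy, summ$fraction))]
  else rep(NA_real_, nrow(summ))
  rel <- rep(NA_real_, nrow(summ))
  ok <- !is.na(ref) & ref > 0
  rel[ok] <- round(summ$mean_kappa[ok] / ref[ok], 3)
  summ$relative_kappa <- rel
  summ$performance_reduction <-
    ifelse(!is.na(rel) & rel >= 0 & rel <= 1, round((1 - rel) * 100, 1), NA_real_)
  structure(list(results = results, summary = summ,
                 table = curve_table(summ), rocs = rocs,
                 splits = setup$splits, fraction_ids = frac_ids,
                 config = config),
            class = "hs_learning_curve")
}

# wide, one row per fraction (the classic learning-curve table layout)
curve_table <- function(summ) {
  fracs <- sort(unique(summ$fraction))
  get <- function(strat, col) {
    v <- summ[[col]][match(paste(strat, fracs), paste(summ$strategy, summ$fraction))]
    if (is.null(v)) rep(NA_real_, length(fracs)) else v
  }
  data.frame(fraction = fracs,
             n_train = summ$n_train[match(fracs, summ$fraction)],
             FC = get("fc", "mean_kappa"),
             HC = get("hc", "mean_kappa"),
             HC_HTL = get("hc_htl", "mean_kappa"),
             rel_FC = get("fc", "relative_kappa"),
             rel_HC = get("hc", "relative_kappa"),
             rel_HC_HTL = get("hc_htl", "relative_kappa"))
}

#' @export
print.hs_learning_curve <- function(x, ...) {
  cat(sprintf("Learning curve: %d fraction(s) x %d strateg%s x %d replicate(s)\n",
              length(x$config$fractions), length(x$config$strategies),
              if (length(x$config$strategies) > 1) "ies" else "y",
              x$config$replicates))
  print(format(x$table, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
plot.hs_learning_curve <- function(x, ...) {
  s <- x$summary
  strats <- unique(s$strategy)
  cols <- stats::setNames(seq_along(strats) + 1L, strats)
  graphics::plot(NULL, xlim = range(s$fraction), ylim = range(c(0, s$mean_kappa), na.rm = TRUE),
                 xlab = "training fraction", ylab = "Cohen's kappa",
                 main = "Learning curve", ...)
  for (st in strats) {
    sub <- s[s$strategy == st, ]
    sub <- sub[order(sub$fraction), ]
    graphics::lines(sub$fraction, sub$mean_kappa, type = "b",
                    col = cols[[st]], pch = 16)
    if (any(!is.na(sub$sd_kappa)))
      graphics::arrows(sub$fraction, sub$mean_kappa - sub$sd_kappa,
                       sub$fraction, sub$mean_kappa + sub$sd_kappa,
                       angle = 90, code = 3, length = 0.02, col = cols[[st]])
  }
  graphics::legend("bottomright", legend = toupper(strats), col = cols,
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}

# --------------------------------------------------------------------------
# reporting -----------------------------------------------------------------

roc_curve_points <- function(score, pos) {
  ord <- order(score, decreasing = TRUE)
  data.frame(threshold = score[ord],
             fpr = cumsum(!pos[ord]) / max(1, sum(!pos)),
             tpr = cumsum(pos[ord]) / max(1, sum(pos)))
}

#' Render experiment reports to files
#'
#' Writes CSV tables (including the wide per-fraction learning-curve
#' table), JSON summaries, learning-curve plots and one-vs-rest ROC curve
#' CSVs/plots into a directory.  Missing cells are rendered as `NA`;
#' empty results give headers-only files with a warning.
#'
#' @param x an `"hs_comparison"` or `"hs_learning_curve"` result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
render_reports <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    f <- file.path(dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  if (is.null(x$results) || nrow(x$results) == 0L)
    warning("empty results; writing headers-only files")
  wr(x$results %||% data.frame(), "cells.csv")
  wr(x$summary, "summary.csv")
  if (inherits(x, "hs_learning_curve")) {
    wr(x$table, "learning_curve_table.csv")
    if (nrow(x$results) > 0L) {
      f <- file.path(dir, "learning_curve.png")
      grDevices::png(f, width = 700, height = 500)
      plot(x)
      grDevices::dev.off()
      files <- c(files, f)
    }
  }
  if (!is.null(x$t_tests)) wr(x$t_tests, "t_tests.csv")
  for (nm in names(x$rocs %||% list())) {
    sc <- x$rocs[[nm]]$scores; truth <- x$rocs[[nm]]$truth
    pts <- do.call(rbind, lapply(colnames(sc), function(cl)
      cbind(class = cl, roc_curve_points(sc[, cl], truth == cl))))
    wr(pts, sprintf("roc_%s.csv", nm))
    f <- file.path(dir, sprintf("roc_%s.png", nm))
    grDevices::png(f, width = 600, height = 600)
    graphics::plot(NULL, xlim = 0:1, ylim = 0:1, xlab = "False positive rate",
                   ylab = "True positive rate", main = sprintf("ROC (%s)", nm))
    graphics::abline(0, 1, lty = 3)
    for (i in seq_along(colnames(sc))) {
      cl <- colnames(sc)[i]
      p <- roc_curve_points(sc[, cl], truth == cl)
      graphics::lines(p$fpr, p$tpr, col = i + 1L)
    }
    graphics::legend("bottomright", legend = colnames(sc),
                     col = seq_along(colnames(sc)) + 1L, lty = 1, bty = "n")
    grDevices::dev.off()
    files <- c(files, f)
  }
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(x$summary, js, dataframe = "rows", digits = NA, na = "null")
  files <- c(files, js)
  invisible(files)
}

#' Audit an experiment for train/test leakage
#'
#' Checks, by case id, that no test case of any replicate ever entered the
#' corresponding training set or any of its fraction subsamples.
#'
#' @param x an `"hs_comparison"` or `"hs_learning_curve"` result.
#' @return `TRUE` invisibly; stops with an error on any leakage.
#' @export
leakage_audit <- function(x) {
  stopifnot(inherits(x, "hs_comparison") || inherits(x, "hs_learning_curve"))
  for (sp in x$splits) {
    if (length(intersect(sp$train_ids, sp$test_ids)) > 0L)
      hs_stop(sprintf("leakage in replicate %d: train and test overlap",
                      sp$replicate_index), "hs_leakage_error")
  }
  if (inherits(x, "hs_learning_curve")) {
    for (fi in x$fraction_ids) {
      sp <- x$splits[[fi$replicate]]
      if (!all(fi$kept_ids %in% sp$train_ids) ||
          length(intersect(fi$kept_ids, sp$test_ids)) > 0L)
        hs_stop(sprintf("leakage in replicate %d at fraction %g",
                        fi$replicate, fi$fraction), "hs_leakage_error")
    }
  }
  invisible(TRUE)
}
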