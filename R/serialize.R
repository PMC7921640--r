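# Bundle persistence: a directory of model checkpoints, metamodel
# coefficients, training logs, and a YAML descriptor.

#' Save a fitted bundle to a directory
#'
#' Writes each network as an RDS checkpoint (`flat.ckpt`, `low.ckpt`,
#' `high.ckpt` as applicable) with its training log as CSV, the metamodel
#' both as a checkpoint and as human-readable JSON coefficients (per-class
#' weights, intercepts, class order), and a `bundle.yaml` descriptor.
#'
#' @param bundle a [hierstack()] fit.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_hierstack <- function(bundle, dir) {
  stopifnot(inherits(bundle, "hierstack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(list(strategy = bundle$strategy,
                        modality = as.list(bundle$modality),
                        classes = as.list(bundle$classes),
                        meta = bundle$meta,
                        n_train = bundle$n_train,
                        seed = bundle$seed),
                   file.path(dir, "bundle.yaml"))
  for (nm in c("flat", "low", "high")) {
    if (is.null(bundle[[nm]])) next
    saveRDS(bundle[[nm]], file.path(dir, paste0(nm, ".ckpt")))
    utils::write.csv(bundle[[nm]]$training_log,
                     file.path(dir, paste0(nm, "_training_log.csv")),
                     row.names = FALSE)
  }
  if (!is.null(bundle$metamodel)) {
    saveRDS(bundle$metamodel, file.path(dir, "metamodel.ckpt"))
    cf <- coef(bundle$metamodel)
    jsonlite::write_json(list(classes = bundle$metamodel$classes,
                              weights = lapply(seq_len(nrow(cf)), function(i)
                                unname(cf[i, -ncol(cf)])),
                              intercepts = unname(cf[, ncol(cf)])),
                         file.path(dir, "metamodel.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  saveRDS(bundle[c("high_init_trunk", "n_high_train", "oof", "meta_folds",
                   "train_ids", "arch", "control", "subtypes")],
          file.path(dir, "state.ckpt"))
  invisible(dir)
}

#' Load a bundle saved by [save_hierstack()]
#'
#' @param dir the bundle directory.
#' @return The reconstructed `"hierstack"` fit.
#' @export
load_hierstack <- function(dir) {
  desc <- yaml::read_yaml(file.path(dir, "bundle.yaml"))
  state <- readRDS(file.path(dir, "state.ckpt"))
  rd <- function(nm) {
    f <- file.path(dir, paste0(nm, ".ckpt"))
    if (file.exists(f)) readRDS(f) else NULL
  }
  structure(c(list(strategy = desc$strategy,
                   modality = unlist(desc$modality),
                   classes = unlist(desc$classes),
                   flat = rd("flat"), low = rd("low"), high = rd("high"),
                   metamodel = rd("metamodel"),
                   meta = desc$meta, n_train = desc$n_train,
                   seed = desc$seed, call = NULL),
              state),
            class = "hierstack")
}
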