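# Shared fixtures: tiny configurations for fast unit tests, and a cache for
# objects reused across test files.

the <- new.env(parent = emptyenv())

tiny_sim <- function(seed = 1L, counts = c(6L, 4L, 4L, 4L, 4L), ...) {
  hs_sim_config(class_counts = counts, image_size = c(16L, 16L),
                noise_sd = 0.15, seed = seed, ...)
}

tiny_arch <- function(n_classes = 2L, n_trunks = 1L) {
  hs_arch(n_blocks = 1L, channels = 4L, dense_units = 8L,
          n_classes = n_classes, input_size = c(16L, 16L), n_trunks = n_trunks)
}

fast_ctl <- function(epochs = 4L, seed = 1L, ...) {
  hs_control(epochs = epochs, batch_size = 8L, learning_rate = 3e-3,
             seed = seed, augment = hs_augment_policy(FALSE, 0, 0), ...)
}

tiny_dataset <- function() {
  if (is.null(the$tiny_dataset)) the$tiny_dataset <- hs_simulate(tiny_sim())
  the$tiny_dataset
}

# per-seed benchmark setup (dataset + pretext source + splits), cached
benchmark_setup <- function(seed) {
  key <- paste0("bench", seed)
  if (is.null(the[[key]])) {
    cfg <- hs_benchmark_config(seed = seed)
    the[[key]] <- list(config = cfg, setup = hierstack:::experiment_setup(cfg))
  }
  the[[key]]
}

# independent brute-force oracles (deliberately naive implementations)
bf_kappa <- function(t, p) {
  t <- as.character(t); p <- as.character(p)
  lev <- sort(unique(c(t, p))); n <- length(t)
  po <- mean(t == p)
  pe <- 0
  for (l in lev) pe <- pe + (sum(t == l) / n) * (sum(p == l) / n)
  if (pe >= 1) 1 else (po - pe) / (1 - pe)
}

bf_weighted_accuracy <- function(t, p) {
  t <- as.character(t); p <- as.character(p)
  acc <- c()
  for (l in sort(unique(t))) acc <- c(acc, sum(p == l & t == l) / sum(t == l))
  mean(acc)
}

bf_auc_paircount <- function(score, pos) {
  P <- which(pos); N <- which(!pos)
  tot <- 0
  for (i in P) for (j in N)
    tot <- tot + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
  tot / (length(P) * length(N))
}
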