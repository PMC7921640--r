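# Backbone: architecture, initialisation, training, transfer, prediction.

test_that("architecture validation and pooled feature dimensions", {
  expect_error(hs_arch(n_blocks = 5L, channels = rep(4L, 5), n_classes = 2L,
                       input_size = c(16L, 16L)),
               class = "hs_arch_error")
  expect_error(hs_arch(channels = c(4L, 4L)), class = "hs_arch_error")
  # 64x64 through 3 poolings -> 8x8 spatial map
  a <- hs_arch(n_blocks = 3L, channels = c(4L, 4L, 4L), dense_units = 8L,
               n_classes = 2L, input_size = c(64L, 64L))
  m <- hs_cnn(a, seed = 1L)
  f <- hs_features(m, matrix(stats::runif(64 * 64), ncol = 1))
  expect_equal(nrow(f), 4L * 8L * 8L)
})

test_that("weight initialisation is seeded and exactly reproducible", {
  a <- tiny_arch()
  expect_identical(hs_cnn(a, seed = 5L)$params, hs_cnn(a, seed = 5L)$params)
  expect_false(identical(hs_cnn(a, seed = 5L)$params, hs_cnn(a, seed = 6L)$params))
})

test_that("softmax outputs are normalised and batching-invariant", {
  a <- tiny_arch(n_classes = 3L)
  m <- hs_cnn(a, seed = 2L)
  m$class_order <- c("a", "b", "c")
  set.seed(1); X <- matrix(stats::runif(256 * 7), 256, 7)
  p <- predict(m, X)
  expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-6)
  one_by_one <- t(vapply(1:7, function(i)
    predict(m, X[, i, drop = FALSE])[1, ], numeric(3)))
  expect_equal(unname(p), unname(one_by_one), tolerance = 1e-10)
})

# two trivially separable classes: bright-left vs bright-right patterns
separable_data <- function(n_per = 10L, seed = 3L, d = 16L) {
  set.seed(seed)
  X <- matrix(stats::runif(d * d * 2 * n_per, 0, 0.2), d * d, 2 * n_per)
  half <- as.vector(row(matrix(0, d, d)) <= d / 2)
  X[half, seq_len(n_per)] <- X[half, seq_len(n_per)] + 0.6
  X[!half, n_per + seq_len(n_per)] <- X[!half, n_per + seq_len(n_per)] + 0.6
  list(x = pmin(X, 1), y = factor(rep(c("L", "R"), each = n_per)))
}

test_that("training reaches 100% on separable data and is seed-deterministic", {
  d <- separable_data()
  m <- hs_train(hs_cnn(tiny_arch(), seed = 1L), d$x, d$y, fast_ctl(epochs = 30L))
  p <- predict(m, d$x)
  expect_equal(colnames(p)[max.col(p)], as.character(d$y))
  m2 <- hs_train(hs_cnn(tiny_arch(), seed = 1L), d$x, d$y, fast_ctl(epochs = 30L))
  expect_identical(m$params, m2$params)
  expect_equal(nrow(m$training_log), 30L)
})

test_that("transfer copies the trunk bit-exactly and re-initialises the head", {
  d <- separable_data()
  src <- hs_train(hs_cnn(tiny_arch(), seed = 1L), d$x, d$y, fast_ctl())
  tr <- hs_transfer(src, n_classes_new = 4L, seed = 9L)
  expect_equal(tr$arch$n_classes, 4L)
  for (nm in grep("^t1\\.", names(src$params), value = TRUE))
    expect_identical(tr$params[[nm]], src$params[[nm]])
  expect_false(identical(dim(tr$params[["head.W2"]]), dim(src$params[["head.W2"]])))
  # shared trunk: identical pre-head features, different outputs
  expect_identical(hs_features(tr, d$x[, 1:3]), hs_features(src, d$x[, 1:3]))
  # incompatible trunk is refused
  other <- hs_cnn(hs_arch(1L, 8L, 8L, 2L, c(16L, 16L)), seed = 1L)
  expect_error(hs_transfer(other, 2L, arch = tiny_arch()), class = "hs_transfer_error")
})

test_that("frozen blocks stay bit-identical through training", {
  a <- hs_arch(2L, c(4L, 4L), 8L, 2L, c(16L, 16L))
  d <- separable_data()
  m0 <- hs_cnn(a, seed = 4L)
  m <- hs_train(m0, d$x, d$y, fast_ctl(epochs = 3L, freeze_blocks = 1L))
  for (nm in grep("^t1\\.b1\\.", names(m0$params), value = TRUE))
    expect_identical(m$params[[nm]], m0$params[[nm]])
  expect_false(identical(m$params[["t1.b2.W1"]], m0$params[["t1.b2.W1"]]))
})

test_that("inverse-frequency loss weights raise minority-class recall", {
  d <- 8L
  gen <- function(seed, n_maj = 36L, n_min = 4L) {
    set.seed(seed)
    n <- n_maj + n_min
    X <- matrix(stats::runif(d * d * n, 0, 0.45), d * d, n)
    tgt <- n_maj + seq_len(n_min)
    X[as.vector(col(matrix(0, d, d)) <= d / 2), tgt] <-
      X[as.vector(col(matrix(0, d, d)) <= d / 2), tgt] + 0.25
    list(x = pmin(X, 1), y = factor(rep(c("maj", "min"), c(n_maj, n_min))))
  }
  arch <- hs_arch(1L, 4L, 8L, 2L, c(d, d))
  rec <- function(seed, weights) {
    tr <- gen(seed); te <- gen(seed + 100L, 20L, 20L)
    m <- hs_train(hs_cnn(arch, seed = seed), tr$x, tr$y,
                  fast_ctl(epochs = 8L, seed = seed, class_weights = weights))
    p <- predict(m, te$x)
    mean(colnames(p)[max.col(p)][te$y == "min"] == "min")
  }
  uni <- vapply(1:5, rec, 1, weights = c(maj = 1, min = 1))
  inv <- vapply(1:5, rec, 1, weights = NULL)  # default: total/(K * count)
  expect_gt(mean(inv), mean(uni))
})

test_that("a non-finite loss raises an error advising a lower learning rate", {
  d <- separable_data()
  m <- hs_cnn(tiny_arch(), seed = 1L)
  m <- hs_set_weights(m, list("head.W2" = m$params[["head.W2"]] * Inf))
  expect_error(hs_train(m, d$x, d$y, fast_ctl(epochs = 2L)),
               "learning_rate", class = "hs_divergence_error")
})

test_that("pretext pretraining learns above chance and feeds transfer exactly", {
  src <- hs_pretext(tiny_arch(), control = fast_ctl(epochs = 8L), seed = 2L)
  expect_gt(utils::tail(src$training_log$accuracy, 1), 1 / 6 + 0.1)
  tr <- hs_transfer(src, 5L, seed = 3L)
  for (nm in grep("^t1\\.", names(src$params), value = TRUE))
    expect_identical(tr$params[[nm]], src$params[[nm]])
  expect_error(hs_pretext(tiny_arch(),
                          data = list(x = matrix(0.5, 256, 4),
                                      y = factor(rep("a", 4))),
                          control = fast_ctl()),
               class = "hs_training_error")
})

test_that("external weights can be loaded through the hook", {
  m <- hs_cnn(tiny_arch(), seed = 1L)
  w <- list("t1.b1.W1" = m$params[["t1.b1.W1"]] * 0 + 0.5)
  m2 <- hs_set_weights(m, w)
  expect_identical(m2$params[["t1.b1.W1"]], w[["t1.b1.W1"]])
  expect_error(hs_set_weights(m, list(bogus = 1)), class = "hs_transfer_error")
  expect_error(hs_set_weights(m, list("t1.b1.W1" = matrix(0, 2, 2))),
               class = "hs_transfer_error")
})
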