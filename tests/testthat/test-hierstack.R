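# Strategy bundles: flat, hierarchical, hierarchy transfer, prediction.

tiny_bundle <- function(strategy, meta = "naive", seed = 1L, ...) {
  key <- paste0("bundle_", strategy, "_", meta, "_", seed)
  if (is.null(the[[key]]))
    the[[key]] <- hierstack(tiny_dataset(), strategy = strategy,
                            modality = "projection", source = NULL,
                            arch = tiny_arch(), control = fast_ctl(),
                            meta = meta, meta_folds = 2L, seed = seed, ...)
  the[[key]]
}

test_that("confidence vectors concatenate the normal and subtype confidences", {
  v <- build_confidence_vector(c(normal = 0.9, disease = 0.1), rep(0.25, 4))
  expect_equal(unname(v), c(0.9, 0.25, 0.25, 0.25, 0.25))
  expect_length(v, 5L)  # n + 1 for n = 4
  expect_error(build_confidence_vector(c(0.9, 0.05, 0.05), rep(0.25, 4)),
               class = "hs_input_error")
})

test_that("flat bundles hold one (n+1)-class model and softmax scores", {
  b <- tiny_bundle("fc")
  expect_equal(b$flat$arch$n_classes, 5L)
  expect_null(b$low); expect_null(b$high); expect_null(b$metamodel)
  pr <- predict(b, tiny_dataset())
  expect_equal(unname(rowSums(pr$scores)), rep(1, length(pr$class)),
               tolerance = 1e-6)
  expect_identical(levels(pr$class), tiny_dataset()$classes)
})

test_that("hierarchical bundles train the high model on diseased cases only", {
  b <- tiny_bundle("hc", meta = "oof")
  expect_null(b$flat)
  expect_false(is.null(b$low) || is.null(b$high) || is.null(b$metamodel))
  expect_equal(b$low$arch$n_classes, 2L)
  expect_equal(b$high$arch$n_classes, 4L)
  # all 16 diseased cases and zero normals reach the high-level model
  expect_equal(b$n_high_train, sum(hs_labels(tiny_dataset()) != "normal"))
  expect_lt(b$n_high_train, b$n_train)
  # subtype block of the confidence vector is a softmax
  pr <- predict(b, tiny_dataset())
  expect_equal(unname(rowSums(pr$confidence[, -1])), rep(1, nrow(pr$confidence)),
               tolerance = 1e-6)
  expect_equal(colnames(pr$confidence), c("normal", "FI", "GE", "MY", "SS"))
})

test_that("hierarchy transfer initialises the high trunk from the trained low trunk", {
  b <- tiny_bundle("hc_htl")
  tn <- hierstack:::trunk_param_names(b$high$arch)
  expect_identical(b$high_init_trunk, b$low$params[tn])
  # without HTL the high model starts from an unrelated initialisation
  b2 <- tiny_bundle("hc")
  expect_false(identical(b2$high_init_trunk, b2$low$params[tn]))
})

test_that("every subtype collapses onto the disease root label", {
  d <- tiny_dataset()
  roots <- hs_root_labels(d)
  labs <- hs_labels(d)
  expect_identical(levels(roots), c("normal", "disease"))
  expect_true(all(roots[labs != "normal"] == "disease"))
  expect_true(all(roots[labs == "normal"] == "normal"))
})

test_that("bundle predictions are deterministic and evaluation reports are complete", {
  b <- tiny_bundle("hc_htl")
  d <- tiny_dataset()
  p1 <- predict(b, d); p2 <- predict(b, d)
  expect_identical(p1, p2)
  ev <- evaluate(b, d)
  expect_s3_class(ev, "hs_eval")
  expect_equal(sum(ev$confusion), length(d$cases))
  expect_lte(ev$kappa, 1)
  expect_length(ev$per_class_auc, 5L)
})

test_that("a training subset missing a subtype is refused", {
  d <- tiny_dataset()
  labs <- hs_labels(d)
  ids <- names(labs)[labs != "SS"]
  expect_error(hierstack(d, strategy = "hc", arch = tiny_arch(),
                         control = fast_ctl(), subset = ids),
               class = "hs_stratification_error")
})

test_that("stacking one bundle reproduces that bundle's metamodel decisions", {
  b <- tiny_bundle("hc", meta = "naive")
  st <- hs_stack(list(projection = b), tiny_dataset())
  expect_equal(st$metamodel$d, 5L)
  pr_b <- predict(b, tiny_dataset())
  pr_s <- predict(st, tiny_dataset())
  expect_equal(as.character(pr_s$class), as.character(pr_b$class))
})

test_that("stacked vectors concatenate M blocks of n+1 confidences", {
  d <- tiny_dataset()
  bundles <- lapply(d$modalities, function(m) {
    hierstack(d, strategy = "hc", modality = m, arch = tiny_arch(),
              control = fast_ctl(epochs = 2L), meta = "naive", seed = 4L)
  })
  names(bundles) <- d$modalities
  st <- hs_stack(bundles, d)
  expect_equal(st$metamodel$d, 4L * 5L)  # M * (n + 1) = 20
  pr <- predict(st, d)
  expect_equal(ncol(pr$confidence), 20L)
  expect_identical(st$block_order, d$modalities)
  # mixing strategies is refused
  fcb <- tiny_bundle("fc")
  expect_error(hs_stack(list(bundles[[1]], fcb), d), class = "hs_input_error")
})

test_that("multiple-input bundles concatenate per-trunk features before the head", {
  d <- tiny_dataset()
  b <- hierstack(d, strategy = "fc", modality = d$modalities,
                 arch = tiny_arch(), control = fast_ctl(epochs = 2L),
                 meta = "naive", seed = 5L)
  expect_equal(b$flat$arch$n_trunks, 4L)
  # head input dimension = M x per-trunk feature dim
  expect_equal(ncol(b$flat$params[["head.W1"]]),
               4L * hierstack:::arch_feat_dim(b$flat$arch))
  pr <- predict(b, d)
  expect_equal(unname(rowSums(pr$scores)), rep(1, length(d$cases)), tolerance = 1e-6)
})

test_that("bundles round-trip through the directory format", {
  b <- tiny_bundle("hc_htl")
  dir <- withr::local_tempdir()
  save_hierstack(b, dir)
  expect_true(file.exists(file.path(dir, "bundle.yaml")))
  expect_true(file.exists(file.path(dir, "metamodel.json")))
  expect_true(file.exists(file.path(dir, "low_training_log.csv")))
  b2 <- load_hierstack(dir)
  d <- tiny_dataset()
  p1 <- predict(b, d); p2 <- predict(b2, d)
  expect_equal(as.character(p1$class), as.character(p2$class))
  expect_equal(p1$scores, p2$scores)
  js <- jsonlite::read_json(file.path(dir, "metamodel.json"),
                            simplifyVector = TRUE)
  expect_equal(js$classes, b$classes)
  expect_length(js$intercepts, 5L)
})
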