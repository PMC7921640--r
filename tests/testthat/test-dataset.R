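make_labels <- function(counts, classes = c("normal", "FI", "GE", "MY", "SS")) {
  v <- rep(classes[seq_along(counts)], times = counts)
  stats::setNames(factor(v, levels = classes[seq_along(counts)]),
                  sprintf("c%04d", seq_along(v)))
}

test_that("stratified split allocates round(count * fraction) per class", {
  labs <- make_labels(c(5L, 5L), classes = c("a", "b"))
  sp <- stratified_split(labs, 0.2, seed = 1L)
  expect_equal(as.vector(table(labs[sp$test_ids])), c(1L, 1L))
  expect_equal(as.vector(table(labs[sp$train_ids])), c(4L, 4L))

  # the clinical class counts: test 31/24/53/61/21, train 125/94/213/246/86
  labs <- make_labels(c(156L, 118L, 266L, 307L, 107L))
  sp <- stratified_split(labs, 0.2, seed = 5L)
  expect_equal(as.vector(table(labs[sp$train_ids])),
               c(125L, 94L, 213L, 246L, 86L))
  expect_length(sp$train_ids, 764L)
  # independent arithmetic oracle: round-half-up per class
  expect_equal(as.vector(table(labs[sp$test_ids])),
               as.vector(floor(c(156, 118, 266, 307, 107) * 0.2 + 0.5)))
})

test_that("splits are deterministic under seed and cover every class on both sides", {
  labs <- make_labels(c(7L, 3L, 9L, 2L, 5L))
  expect_identical(stratified_split(labs, 0.25, seed = 3L),
                   stratified_split(labs, 0.25, seed = 3L))
  for (seed in 1:3) for (tf in c(0.2, 0.3)) {
    sp <- stratified_split(labs, tf, seed = seed)
    expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
    expect_setequal(c(sp$train_ids, sp$test_ids), names(labs))
    for (cl in levels(labs)) {
      n_cl <- sum(labs == cl)
      n_te <- sum(labs[sp$test_ids] == cl)
      expect_gte(n_te, 1L); expect_gte(n_cl - n_te, 1L)
      expect_lte(abs(n_te / n_cl - tf), 1 / n_cl + 1e-9)
    }
  }
  expect_error(stratified_split(make_labels(c(1L, 5L), classes = c("a", "b")), 0.2),
               class = "hs_stratification_error")
})

test_that("fraction subsampling keeps per-class round(count * fraction), min 1", {
  labs <- make_labels(c(50L, 50L, 50L, 50L, 50L))
  sp <- stratified_split(labs, 0.2, seed = 2L)  # 40 per class in train
  expect_identical(subsample_fraction(sp, labs, 1, seed = 9L)$kept_ids, sp$train_ids)
  fr <- subsample_fraction(sp, labs, 0.25, seed = 9L)
  expect_equal(as.vector(table(labs[fr$kept_ids])), rep(10L, 5))
  expect_length(fr$kept_ids, 50L)
  expect_true(all(fr$kept_ids %in% sp$train_ids))
  expect_length(intersect(fr$kept_ids, sp$test_ids), 0L)
  expect_error(subsample_fraction(sp, labs, 0), class = "hs_config_error")
})

test_that("per-class rounding reproduces the printed 739-case schedule", {
  # brute-force-found witness: per-class training counts summing to 739 whose
  # per-class round-half-up fractions give exactly the printed totals
  witness <- c(128L, 96L, 208L, 231L, 76L)
  expect_equal(sum(witness), 739L)
  sched <- vapply(c(0.25, 0.375, 0.5, 0.625, 0.75, 0.875, 1),
                  function(f) sum(floor(witness * f + 0.5)), 1)
  expect_equal(sched, c(185, 278, 370, 462, 554, 647, 739))
  # and subsample_fraction realises those totals on such a training set
  labs <- make_labels(witness + 2L)  # 2 extra per class act as the test side
  tr <- unlist(lapply(levels(labs), function(cl)
    utils::head(names(labs)[labs == cl], witness[match(cl, levels(labs))])))
  sp <- structure(list(train_ids = tr, test_ids = setdiff(names(labs), tr),
                       replicate_index = 1L, seed = 1L), class = "hs_split")
  for (i in seq_along(sched)) {
    fr <- subsample_fraction(sp, labs, c(0.25, 0.375, 0.5, 0.625, 0.75, 0.875, 1)[i],
                             seed = 4L)
    expect_length(fr$kept_ids, sched[i])
  }
})

test_that("augmentation is identity at the zero policy and flips are involutions", {
  img <- tiny_dataset()$cases[[2]]$images$projection
  pol0 <- hs_augment_policy(FALSE, 0, 0)
  expect_identical(augment_image(img, pol0), img)
  flipped <- augment_image(img, pol0, force_flip = TRUE)
  expect_false(identical(flipped, img))
  expect_identical(augment_image(flipped, pol0, force_flip = TRUE), img)
})

test_that("default augmentation preserves mean intensity and pixel range", {
  img <- tiny_dataset()$cases[[5]]$images$enface
  pol <- hs_augment_policy(horizontal_flip = FALSE, rotation_deg_max = 10,
                           shift_frac_max = 0.05)
  set.seed(42)
  draws <- replicate(1000, mean(augment_image(img, pol)))
  expect_lt(abs(mean(draws) - mean(img)), 0.05)
  one <- augment_image(img, pol, seed = 1L)
  expect_gte(min(one), 0); expect_lte(max(one), 1)
  expect_identical(augment_image(img, pol, seed = 1L), one)  # seeded determinism
  expect_error(hs_augment_policy(rotation_deg_max = 45), class = "hs_config_error")
})

test_that("split JSON round trip and child-seed scheme are stable", {
  labs <- make_labels(c(6L, 4L, 4L, 4L, 4L))
  sp <- stratified_split(labs, 0.2, seed = 11L, replicate_index = 2L)
  f <- withr::local_tempfile(fileext = ".json")
  write_split(sp, f)
  sp2 <- read_split(f)
  expect_identical(sp2$train_ids, sp$train_ids)
  expect_identical(sp2$test_ids, sp$test_ids)
  expect_identical(sp2$replicate_index, 2L)

  expect_identical(child_seed(1, "split", 1), child_seed(1, "split", 1))
  seeds <- c(child_seed(1, "split", 1), child_seed(1, "split", 2),
             child_seed(1, "subsample", 1), child_seed(2, "split", 1))
  expect_length(unique(seeds), 4L)
  expect_true(all(seeds >= 0 & seeds < 2^31))
})

test_that("replicate splits differ from each other but are reproducible", {
  labs <- make_labels(c(8L, 5L, 5L, 5L, 5L))
  sps <- make_splits(labs, replicates = 3L, seed = 7L)
  expect_length(sps, 3L)
  expect_false(identical(sort(sps[[1]]$test_ids), sort(sps[[2]]$test_ids)))
  sps2 <- make_splits(labs, replicates = 3L, seed = 7L)
  expect_identical(sps, sps2)
})
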