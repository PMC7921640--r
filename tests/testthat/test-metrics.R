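# Evaluation statistics against hand-computed and independent oracles.

test_that("Cohen's kappa matches the marginal-product formula", {
  expect_equal(cohens_kappa(c("A", "A", "B", "B"), c("A", "B", "B", "B")), 0.5)
  expect_equal(cohens_kappa(rep(c("x", "y"), 5), rep(c("x", "y"), 5)), 1)
  expect_equal(cohens_kappa(c("a", "a"), c("a", "a")), 1)  # p_e = 1 edge case
  expect_error(cohens_kappa(c("a", "b"), "a"), class = "hs_input_error")
})

test_that("kappa is invariant under class relabelling and near 0 at chance", {
  set.seed(2)
  t <- sample(letters[1:4], 300, replace = TRUE)
  p <- sample(letters[1:4], 300, replace = TRUE)
  relab <- c(a = "q", b = "r", c = "s", d = "t")
  expect_equal(cohens_kappa(relab[t], relab[p]), cohens_kappa(t, p))
  set.seed(3)
  t2 <- sample(1:3, 10000, replace = TRUE); p2 <- sample(1:3, 10000, replace = TRUE)
  expect_lt(abs(cohens_kappa(t2, p2)), 0.05)
  # independent library implementation agrees
  expect_equal(cohens_kappa(t, p),
               e1071::classAgreement(table(t, p))$kappa, tolerance = 1e-12)
})

test_that("weighted accuracy is the unweighted mean of per-class recalls", {
  expect_equal(weighted_accuracy(c("a", "a", "b"), c("a", "a", "b")), 1)
  # recalls 1.0 and 0.0 -> 0.5 regardless of class sizes
  expect_equal(weighted_accuracy(c(rep("a", 9), "b"), rep("a", 10)), 0.5)
  set.seed(4)
  for (i in 1:100) {
    k <- sample(2:5, 1); n <- sample(10:60, 1)
    t <- sample(letters[1:k], n, replace = TRUE)
    while (length(unique(t)) < k) t <- sample(letters[1:k], n, replace = TRUE)
    p <- sample(letters[1:k], n, replace = TRUE)
    expect_equal(weighted_accuracy(t, p), bf_weighted_accuracy(t, p))
  }
})

test_that("relative kappa and performance reduction reproduce printed arithmetic", {
  expect_equal(relative_kappa(0.727, 0.809), 0.899)
  expect_equal(relative_kappa(0.556, 0.642), 0.866)
  expect_equal(relative_kappa(0.5, 0.5), 1)
  expect_error(relative_kappa(0.5, 0), class = "hs_domain_error")
  expect_equal(performance_reduction(0.903), 9.7)
  expect_equal(performance_reduction(1), 0)
  expect_equal(performance_reduction(0.984), 1.6)
  expect_error(performance_reduction(1.2), class = "hs_domain_error")
  # round trip: reduction(rel) + 100 * rel = 100 (at reporting precision)
  for (rel in c(0.851, 0.903, 0.975, 1)) {
    expect_equal(performance_reduction(rel) + 100 * rel, 100, tolerance = 0.051)
  }
})

test_that("one-vs-rest AUC uses midranks and averages over present classes", {
  sc <- cbind(a = c(0.9, 0.8, 0.2, 0.1), b = c(0.1, 0.2, 0.8, 0.9))
  out <- roc_auc_ovr(sc, c("a", "a", "b", "b"))
  expect_equal(unname(out$per_class), c(1, 1))
  expect_equal(out$macro, 1)
  # monotone transforms leave AUC unchanged
  out2 <- roc_auc_ovr(exp(3 * sc), c("a", "a", "b", "b"))
  expect_equal(out2$per_class, out$per_class)
  # absent class -> NA, excluded from macro with a warning
  sc3 <- cbind(sc, c = c(0.1, 0.1, 0.1, 0.1))
  expect_warning(out3 <- roc_auc_ovr(sc3, c("a", "a", "b", "b")), "absent")
  expect_true(is.na(out3$per_class[["c"]]))
  expect_equal(out3$macro, 1)
})

test_that("AUC is near 0.5 for label-independent scores", {
  set.seed(6)
  y <- sample(c("a", "b", "c"), 2000, replace = TRUE)
  sc <- matrix(stats::rnorm(2000 * 3), 2000, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_lt(abs(roc_auc_ovr(sc, y)$macro - 0.5), 0.05)
})

test_that("the paired t-test matches the closed form and its symmetries", {
  out <- paired_t_test(c(1, 2, 3), c(0, 0, 0))
  expect_equal(out$t, sqrt(3) * 2, tolerance = 1e-6)  # d.bar/(s_d/sqrt(n)) = 3.464
  expect_equal(out$df, 2)
  expect_equal(out$p, 0.0742, tolerance = 1e-3)
  swapped <- paired_t_test(c(0, 0, 0), c(1, 2, 3))
  expect_equal(swapped$t, -out$t, tolerance = 1e-10)
  expect_equal(swapped$p, out$p)
  expect_error(paired_t_test(c(1, 2), c(0, 1)), class = "hs_degenerate_error")
  expect_error(paired_t_test(1, 2), class = "hs_input_error")
})

test_that("evaluation reports serialise and their pieces agree", {
  set.seed(7)
  t <- factor(sample(c("normal", "FI", "GE"), 40, replace = TRUE))
  p <- factor(sample(c("normal", "FI", "GE"), 40, replace = TRUE),
              levels = levels(t))
  sc <- matrix(stats::runif(120), 40, 3, dimnames = list(NULL, levels(t)))
  ev <- eval_report(t, p, scores = sc)
  expect_equal(sum(ev$confusion), 40L)
  expect_equal(ev$kappa, cohens_kappa(t, p))
  expect_equal(ev$weighted_accuracy,
               mean(diag(ev$confusion) / rowSums(ev$confusion)))
  f <- withr::local_tempfile()
  write_eval(ev, f)
  js <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(js$kappa, ev$kappa, tolerance = 1e-12)
  expect_true(file.exists(paste0(f, "_confusion.csv")))
})
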