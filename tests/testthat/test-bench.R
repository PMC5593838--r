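# well-separated 4-cluster feature fixture
cluster_fixture <- function(n = 40, p = 4, gap = 8, sd = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(4 * n * p, sd = sd), ncol = p)
  X <- X + gap * matrix(rep(diag(4)[rep(1:4, each = n), 1:p]), ncol = p)
  list(X = X, y = factor(rep(beat_classes(), each = n),
                         levels = beat_classes()))
}

test_that("exactly nine configurations exist", {
  specs <- model_specs()
  expect_length(specs, 9)
  expect_setequal(vapply(specs, `[[`, "", "label"),
                  c("kNN_k1", "kNN_k5", "kNN_k10", "DFA_linear",
                    "DFA_quadratic", "NB_gaussian", "NB_kernel",
                    "SVM_rbf", "SVM_linear"))
})

test_that("per-fold standardization uses training statistics only", {
  set.seed(21)
  tr <- matrix(rnorm(200, mean = 5, sd = 2), ncol = 4)
  z <- standardize_fold(tr, tr)
  expect_equal(unname(colMeans(z$train)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(z$train, 2, sd)), rep(1, 4), tolerance = 1e-12)
  # shifted test set lands at shift/SD
  shift <- 3
  z2 <- standardize_fold(tr, tr + shift)
  expect_equal(unname(colMeans(z2$test)),
               unname(shift / apply(tr, 2, sd)), tolerance = 1e-9)
  # constant feature flagged and zeroed
  tr3 <- cbind(tr, const = 7)
  z3 <- standardize_fold(tr3, tr3)
  expect_true(z3$constant[5])
  expect_true(all(z3$train[, 5] == 0) && all(z3$test[, 5] == 0))
})

test_that("confusion matrices count as labelled", {
  y <- rep(beat_classes(), each = 3)
  cm <- confusion_matrix(y, y)
  expect_equal(unname(diag(cm)), rep(3L, 4), ignore_attr = TRUE)
  expect_equal(sum(cm), 12)
  cm2 <- confusion_matrix(y, rep("NOR", 12))
  expect_equal(unname(cm2[, "NOR"]), rep(3L, 4), ignore_attr = TRUE)
  expect_equal(sum(cm2[, -1]), 0)
  # hand-enumerated fixture
  cm3 <- confusion_matrix(c("NOR", "NOR", "ISM", "VPB"),
                          c("NOR", "ISM", "ISM", "ISE"))
  expect_equal(unname(cm3["NOR", "NOR"]), 1L, ignore_attr = TRUE)
  expect_equal(unname(cm3["NOR", "ISM"]), 1L, ignore_attr = TRUE)
  expect_equal(unname(cm3["VPB", "ISE"]), 1L, ignore_attr = TRUE)
  expect_error(confusion_matrix(c("NOR"), c("XX")), "unknown")
})

test_that("cross-validation is deterministic and consistent", {
  fx <- cluster_fixture(n = 30, seed = 2)
  spec <- model_specs()[[2]]                      # kNN k = 5
  r1 <- cross_validate(spec, fx$X, fx$y, folds = 10, seed = 7)
  r2 <- cross_validate(spec, fx$X, fx$y, folds = 10, seed = 7)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$fold_acc, r2$fold_acc)
  # report invariants
  expect_equal(unname(rowSums(r1$confusion)), rep(30L, 4),
               ignore_attr = TRUE)
  expect_equal(sum(diag(r1$confusion)) / sum(r1$confusion),
               mean(r1$predictions == fx$y))
  prev <- rowSums(r1$confusion) / sum(r1$confusion)
  expect_equal(unname(sum(prev * r1$sensitivity)),
               sum(diag(r1$confusion)) / sum(r1$confusion),
               tolerance = 1e-12)
})

test_that("all nine models master a well-separated fixture", {
  fx <- cluster_fixture(n = 30, gap = 10, seed = 3)
  for (spec in model_specs()) {
    r <- cross_validate(spec, fx$X, fx$y, folds = 5, seed = 11)
    expect_gte(r$mean_acc, 0.95)
  }
})

test_that("k-NN attains near-perfect accuracy on separated clusters", {
  fx <- cluster_fixture(n = 40, gap = 8, seed = 4)
  r5 <- cross_validate(model_specs()[[2]], fx$X, fx$y, folds = 10, seed = 5)
  expect_gte(r5$mean_acc, 0.99)
  r1 <- cross_validate(model_specs()[[1]], fx$X, fx$y, folds = 10, seed = 5)
  r10 <- cross_validate(model_specs()[[3]], fx$X, fx$y, folds = 10, seed = 5)
  expect_gte(r1$mean_acc, r10$mean_acc - 0.05)
})

test_that("randomly permuted labels drop accuracy to chance", {
  fx <- cluster_fixture(n = 40, gap = 8, seed = 6)
  set.seed(23)
  yperm <- sample(fx$y)
  r <- cross_validate(model_specs()[[2]], fx$X, yperm, folds = 10, seed = 8)
  expect_lt(abs(r$mean_acc - 0.25), 0.08)
})

test_that("the ridged Gaussian discriminant agrees with the reference LDA", {
  skip_if_not_installed("MASS")
  fx <- cluster_fixture(n = 50, gap = 3, sd = 1.5, seed = 7)
  fit <- ecgbeats:::dfa_fit(fx$X, fx$y, "linear")
  p1 <- ecgbeats:::dfa_predict(fit, fx$X)
  p2 <- stats::predict(MASS::lda(fx$X, fx$y))$class
  expect_gte(mean(as.character(p1) == as.character(p2)), 0.99)
})

test_that("test-fold labels cannot influence predictions", {
  fx <- cluster_fixture(n = 25, gap = 2, seed = 8)
  tr <- fx$X[1:60, ]; ytr <- droplevels(fx$y[1:60])
  te <- fx$X[61:100, ]
  z <- standardize_fold(tr, te)
  for (spec in model_specs()[c(1, 4, 6, 8)]) {
    p1 <- ecgbeats:::fit_predict(spec, z$train, ytr, z$test)
    p2 <- ecgbeats:::fit_predict(spec, z$train, ytr, z$test)
    expect_identical(p1, p2)
  }
})

test_that("benchmark grids cover every (group, model) pair", {
  fx <- cluster_fixture(n = 15, gap = 10, seed = 9)
  colnames(fx$X) <- paste0("f", 1:4)
  groups <- list(all = paste0("f", 1:4), pair = c("f1", "f2"))
  bench <- run_benchmark(groups, model_specs()[c(2, 4)], fx$X, fx$y,
                         folds = 5, seed = 3)
  expect_equal(dim(bench$grid), c(2L, 2L))
  expect_true(all(is.finite(bench$grid)))
  expect_named(bench$reports$all, c("kNN_k5", "DFA_linear"))
  expect_error(run_benchmark(list(bad = "nope"), model_specs()[2], fx$X,
                             fx$y, 5, 1), "unknown columns")
})
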