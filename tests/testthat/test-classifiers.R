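test_that("Minkowski distance reduces to Manhattan and Euclidean", {
  expect_equal(minkowski(c(0, 0), c(3, 4), 2), 5)
  expect_equal(minkowski(c(0, 0), c(3, 4), 1), 7)
  for (c_exp in c(0.5, 1, 2, 3))
    expect_equal(minkowski(c(1, 2, 3), c(1, 2, 3), c_exp), 0)
  expect_error(minkowski(1:3, 1:4), "mismatch")
  expect_error(minkowski(1:3, 4:6, 0), "positive")
})

test_that("k-NN memorizes with k = 1 and follows the global majority", {
  ds <- blob_dataset(10, 2, sep = 6, seed = 2)
  m1 <- knn_fit(ds, k = 1)
  expect_equal(predict(m1, ds$x), ds$label)
  maj <- toy_dataset(matrix(rnorm(10), ncol = 2),
                     c("A", "A", "A", "B", "B"))
  m5 <- knn_fit(maj, k = 5)
  expect_equal(predict(m5, matrix(rnorm(6), ncol = 2)), rep("A", 3))
  expect_error(knn_fit(maj, k = 6), "between 1 and")
})

test_that("k-NN agrees with the brute-force oracle on random data", {
  set.seed(10)
  for (trial in 1:5) {
    n <- sample(20:60, 1); d <- sample(1:6, 1)
    k <- sample(1:7, 1); c_exp <- sample(c(1, 2, 3), 1)
    x <- matrix(rnorm(n * d), ncol = d)
    y <- sample(c("GRASP", "FLEXION", "RELAX"), n, replace = TRUE)
    m <- knn_fit(toy_dataset(x, y), k = k, c = c_exp)
    q <- matrix(rnorm(40 * d), ncol = d)
    expect_equal(predict(m, q),
                 apply(q, 1, function(row) knn_oracle(x, y, row, k, c_exp)))
  }
})

test_that("Gaussian NB posteriors match a hand-computed evaluation", {
  # symmetric 1-D case: equidistant query splits the posterior
  x <- matrix(c(-1.2, -1, -0.8, 0.8, 1, 1.2), ncol = 1)
  y <- rep(c("A", "B"), each = 3)
  m <- gnb_fit(toy_dataset(x, y))
  p <- gnb_predict_proba(m, matrix(0))
  expect_equal(unname(p[1, ]), c(0.5, 0.5), tolerance = 1e-12)
  expect_gt(gnb_predict_proba(m, matrix(1))[1, "B"], 0.5)
  # randomized parity with the dnorm oracle
  set.seed(11)
  for (trial in 1:5) {
    n <- 60; d <- sample(2:5, 1)
    xs <- matrix(rnorm(n * d, sd = runif(1, 0.5, 3)), ncol = d)
    ys <- sample(c("GRASP", "EXTENSION", "RELAX"), n, replace = TRUE)
    mm <- gnb_fit(toy_dataset(xs, ys))
    qs <- matrix(rnorm(20 * d), ncol = d)
    probs <- gnb_predict_proba(mm, qs)
    expect_equal(rowSums(probs), rep(1, 20), tolerance = 1e-12)
    for (r in 1:20)
      expect_equal(unname(probs[r, ]),
                   unname(gnb_oracle_proba(xs, ys, qs[r, ])),
                   tolerance = 1e-9)
    expect_equal(predict(mm, qs),
                 colnames(probs)[max.col(probs, ties.method = "first")])
  }
  expect_error(gnb_fit(toy_dataset(matrix(1:3, ncol = 1), c("A", "A", "B"))),
               "B")
})

test_that("entropy matches its closed form", {
  expect_equal(entropy(rep("A", 7)), 0)
  expect_equal(entropy(rep(c("A", "B", "C", "D"), 5)), 2)
  expect_equal(entropy(c("A", "A", "A", "B")),
               -0.75 * log2(0.75) - 0.25 * log2(0.25))
  expect_error(entropy(character(0)), "empty")
})

test_that("decision tree finds the exhaustive best split", {
  ds <- toy_dataset(matrix(c(1, 2, 8, 9), ncol = 1), c("A", "A", "B", "B"))
  m <- dt_fit(ds)
  expect_equal(dt_depth(m), 1L)
  expect_gt(m$tree$threshold, 2)
  expect_lt(m$tree$threshold, 8)
  expect_equal(predict(m, ds$x), ds$label)
  # pure data: a single leaf
  pure <- dt_fit(toy_dataset(matrix(rnorm(8), ncol = 2), rep("A", 4)))
  expect_equal(dt_depth(pure), 0L)
  expect_true(pure$tree$leaf)
  # randomized root-split parity with a brute-force oracle
  set.seed(12)
  for (trial in 1:5) {
    x <- matrix(rnorm(60), ncol = 2)
    y <- sample(c("A", "B"), 30, replace = TRUE)
    m1 <- dt_fit(toy_dataset(x, y), max_depth = 1)
    best_gain <- -Inf
    h <- entropy(y)
    for (f in 1:2) for (thr in sort(unique(x[, f]))) {
      sel <- x[, f] <= thr
      if (!any(sel) || all(sel)) next
      g <- h - mean(sel) * entropy(y[sel]) - mean(!sel) * entropy(y[!sel])
      best_gain <- max(best_gain, g)
    }
    if (m1$tree$leaf) {
      expect_lte(best_gain, 1e-12)
    } else {
      expect_equal(m1$tree$gain, best_gain, tolerance = 1e-9)
    }
  }
})

test_that("depth-limited trees cannot solve XOR but respect the cap", {
  xor <- toy_dataset(matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2),
                     c("A", "B", "B", "A"))
  m1 <- dt_fit(xor, max_depth = 1)
  expect_lte(mean(predict(m1, xor$x) == xor$label), 0.75)
  m3 <- dt_fit(xor, max_depth = 3)
  expect_lte(dt_depth(m3), 3)
  expect_equal(predict(m3, xor$x), xor$label)  # depth 2 suffices for XOR
})

test_that("SVM separates a margin toy and satisfies its dual constraints", {
  ds <- blob_dataset(20, 2, sep = 5, seed = 13)
  m <- svm_fit(ds)
  expect_equal(mean(predict(m, ds$x) == ds$label), 1)
  for (sub in m$submodels) {
    expect_lt(abs(sub$alpha_y_sum), 1e-6)
    expect_true(all(sub$alpha >= 0 & sub$alpha <= m$cost + 1e-12))
    expect_true(sub$converged)
  }
  # duplicate of a training point classifies as its class
  expect_equal(predict(m, ds$x[1, , drop = FALSE]), ds$label[1])
  expect_error(svm_fit(toy_dataset(matrix(rnorm(10), ncol = 2),
                                   rep("A", 5))), "2 classes")
})

test_that("SVM predictions agree with a reference solver on separable data", {
  skip_if_not_installed("e1071")
  set.seed(14)
  for (trial in 1:3) {
    d <- sample(2:4, 1)
    ds <- blob_dataset(15, d, sep = 6, classes = c("A", "B", "C"),
                       seed = 14 + trial)
    gamma <- 1 / d
    mine <- svm_fit(ds, gamma = gamma, cost = 1)
    ref <- e1071::svm(ds$x, factor(ds$label), kernel = "radial",
                      gamma = gamma, cost = 1, scale = FALSE)
    q <- matrix(rnorm(50 * d, mean = 3), ncol = d)
    agree <- mean(predict(mine, q) == as.character(predict(ref, q)))
    expect_gte(agree, 0.98)
  }
})

test_that("training-row permutation leaves predictions unchanged", {
  set.seed(15)
  ds <- blob_dataset(15, 3, sep = 4, classes = c("GRASP", "RELAX"), seed = 15)
  perm <- sample(nrow(ds$x))
  dsp <- toy_dataset(ds$x[perm, ], ds$label[perm])
  q <- matrix(rnorm(30 * 3, 2), ncol = 3)
  for (meth in c("knn", "gnb", "dt", "svm")) {
    a <- predict(fit_classifier(ds, meth), q)
    b <- predict(fit_classifier(dsp, meth), q)
    expect_equal(a, b)
  }
})

test_that("models survive JSON round trips bit-for-bit", {
  ds <- blob_dataset(12, 2, sep = 5, classes = c("GRASP", "FLEXION", "RELAX"),
                     seed = 16)
  q <- matrix(rnorm(40), ncol = 2)
  for (meth in c("knn", "gnb", "dt", "svm")) {
    m <- fit_classifier(ds, meth)
    path <- tempfile(fileext = ".json")
    write_model_json(m, path)
    back <- read_model_json(path)
    expect_identical(predict(back, q), predict(m, q))
  }
})

test_that("classifier tie-breaks follow the canonical motion order", {
  expect_equal(canonical_classes(c("RELAX", "EXTENSION", "GRASP", "FLEXION")),
               c("GRASP", "FLEXION", "EXTENSION", "RELAX"))
  expect_equal(canonical_classes(c("B", "RELAX", "A")), c("RELAX", "A", "B"))
  # symmetric 2-point 1-NN with k=2: equal votes, equal distances
  ds <- toy_dataset(matrix(c(-1, 1), ncol = 1), c("RELAX", "GRASP"))
  m <- knn_fit(ds, k = 2)
  expect_equal(predict(m, matrix(0)), "GRASP")
})
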