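make_eval_dataset <- function(n = 1000, seed = 20, subjects = 5) {
  set.seed(seed)
  labels <- sample(motion_levels(), n, replace = TRUE)
  mu <- matrix(c(4, 2.5, 5, 1.2, 1.2, 5, 1, 1), ncol = 2, byrow = TRUE,
               dimnames = list(motion_levels(), NULL))
  x <- mu[labels, ] + matrix(rnorm(2 * n, sd = 0.4), ncol = 2)
  colnames(x) <- c("MAV_ch1", "MAV_ch2")
  toy_dataset(x, labels,
              subjects = sprintf("S%02d", rep_len(seq_len(subjects), n)))
}

test_that("pooled splits are exact, disjoint and seed-deterministic", {
  ds <- make_eval_dataset(1000)
  sp <- split_dataset(ds, "pooled", test_fraction = 0.2, seed = 3)
  expect_equal(nrow(sp$train$x), 800)
  expect_equal(nrow(sp$test$x), 200)
  expect_equal(sort(c(sp$train$start, sp$test$start)), sort(ds$start))
  sp2 <- split_dataset(ds, "pooled", test_fraction = 0.2, seed = 3)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_dataset(ds, "pooled", seed = 4)))
})

test_that("subject-wise splits exclude test subjects from training", {
  ds <- make_eval_dataset(500, subjects = 5)
  sp <- split_dataset(ds, "subject_wise", test_subjects = c("S04", "S05"))
  expect_false(any(sp$train$subject_id %in% c("S04", "S05")))
  expect_setequal(unique(sp$test$subject_id), c("S04", "S05"))
  expect_equal(nrow(sp$train$x) + nrow(sp$test$x), 500)
  expect_error(split_dataset(ds, "subject_wise",
                             test_subjects = sprintf("S%02d", 1:5)),
               "exhaust")
  expect_error(split_dataset(ds, "subject_wise", test_subjects = "S99"),
               "unknown")
})

test_that("evaluation reports satisfy their bookkeeping identities", {
  ds <- make_eval_dataset(800)
  sp <- split_dataset(ds, "pooled", seed = 5)
  rep <- evaluate_model(sp$train, sp$test, "MAV", "gnb", time_windows = 5)
  cm <- rep$confusion
  expect_equal(rep$accuracy, 100 * sum(diag(cm)) / sum(cm))
  expect_equal(unname(rowSums(cm)),
               unname(as.vector(table(factor(sp$test$label,
                                             levels = rownames(cm))))))
  expect_equal(unname(rep$per_class_accuracy),
               unname(100 * diag(cm) / rowSums(cm)))
  expect_true(rep$accuracy >= 0 && rep$accuracy <= 100)
  expect_gt(rep$timing_ms$mean_ms, 0)
})

test_that("memorization: k-NN with k = 1 is perfect on its own training set", {
  ds <- make_eval_dataset(300)
  rep <- evaluate_model(ds, ds, "MAV", "knn", k = 1, time_windows = 0)
  expect_equal(rep$accuracy, 100)
})

test_that("permuted labels drive accuracy to chance level", {
  ds <- make_eval_dataset(2500, seed = 21)
  set.seed(22)
  ds$label <- sample(ds$label)
  sp <- split_dataset(ds, "pooled", test_fraction = 0.2, seed = 6)
  rep <- evaluate_model(sp$train, sp$test, "MAV", "dt", time_windows = 0)
  expect_gt(rep$accuracy, 20)
  expect_lt(rep$accuracy, 30)
})

test_that("the sweep covers the full feature x classifier x scheme grid", {
  cohort <- generate_cohort(3, session_protocol(reps = 2, hold_s = 0.5),
                            0.3, seed = 30)
  ds <- build_dataset(lapply(cohort, preprocess_record))
  sw <- sweep_grid(ds, seed = 1, test_subjects = "S03", time_windows = 0)
  expect_equal(nrow(sw$grid), 15 * 4 * 2)
  expect_setequal(unique(sw$grid$scheme), c("pooled", "subject_wise"))
  # per-classifier mean accuracy across its 15 feature sets
  summ <- sweep_summary(sw)
  g1 <- sw$grid[sw$grid$scheme == "pooled" & sw$grid$method == "dt", ]
  expect_equal(summ$mean[summ$scheme == "pooled" & summ$method == "dt"],
               mean(g1$accuracy))
  # grid round-trips through CSV
  path <- tempfile(fileext = ".csv")
  write_sweep(sw, path)
  back <- read_sweep_grid(path)
  expect_equal(back$accuracy, sw$grid$accuracy, tolerance = 1e-12)
  expect_identical(back$features, sw$grid$features)
})

test_that("scheme comparison implements Welch's t-test with degenerate cases", {
  same <- compare_schemes(c(90, 91, 92), c(90, 91, 92))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # hand-computed: means 91 vs 81, s^2 = 1 each, n = 3
  # t = 10 / sqrt(2/3), df = 4
  res <- compare_schemes(c(90, 91, 92), c(80, 81, 82))
  expect_equal(res$statistic, 10 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4, tolerance = 1e-9)
  expect_lt(res$p_value, 0.01)
  # degenerate zero-variance pairs
  flat <- compare_schemes(c(5, 5), c(5, 5))
  expect_equal(flat$p_value, 1)
  apart <- compare_schemes(c(5, 5), c(7, 7))
  expect_equal(apart$p_value, 0)
  expect_error(compare_schemes(1, c(1, 2)), "at least 2")
})

test_that("k-NN prediction time grows with training-set size", {
  ds_sizes <- c(200, 2000, 20000)
  set.seed(23)
  q <- matrix(rnorm(2), ncol = 2)
  med <- vapply(ds_sizes, function(n) {
    x <- matrix(rnorm(2 * n), ncol = 2)
    m <- knn_fit(toy_dataset(x, rep(c("A", "B"), length.out = n)), k = 5)
    times <- vapply(1:20, function(i) {
      t0 <- proc.time()[["elapsed"]]
      predict(m, q)
      proc.time()[["elapsed"]] - t0
    }, 0.0)
    stats::median(times)
  }, 0.0)
  expect_gt(med[3], med[1])
})
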