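#' Train/test split specifications
#'
#' Two designs are supported, mirroring the two ways a myoelectric classifier
#' is validated:
#' * **pooled** (scheme 1): all subjects' windows pooled, an unstratified
#'   uniform random fraction held out for testing;
#' * **subject-wise** (scheme 2): whole subjects held out, so the test
#'   windows come from people the classifier never saw — the measure of
#'   inter-subject generalisation.
#'
#' @param dataset an `emg_dataset`.
#' @param scheme `"pooled"` or `"subject_wise"`.
#' @param test_fraction held-out fraction for the pooled scheme (0 < f < 1).
#' @param test_subjects character vector of held-out subject ids for the
#'   subject-wise scheme (default: the last 2 subjects by id order).
#' @param seed integer seed for the pooled shuffle.
#' @return list with `train` and `test` (`emg_dataset`s); disjoint, and their
#'   union is the input.
#' @export
split_dataset <- function(dataset, scheme = c("pooled", "subject_wise"),
                          test_fraction = 0.2, test_subjects = NULL,
                          seed = 1L) {
  scheme <- match.arg(scheme)
  n <- nrow(dataset$x)
  if (n == 0) stop("empty dataset")
  if (scheme == "pooled") {
    stopifnot(test_fraction > 0, test_fraction < 1)
    set.seed(as.integer(seed))
    n_test <- round(n * test_fraction)
    if (n_test == 0 || n_test == n) stop("degenerate split")
    test_idx <- sort(sample.int(n, n_test))
  } else {
    subjects <- sort(unique(dataset$subject_id))
    if (is.null(test_subjects))
      test_subjects <- utils::tail(subjects, 2)
    if (!all(test_subjects %in% subjects))
      stop("unknown test subject(s): ",
           paste(setdiff(test_subjects, subjects), collapse = ", "))
    if (length(setdiff(subjects, test_subjects)) == 0)
      stop("test subjects exhaust the cohort; nothing left to train on")
    test_idx <- which(dataset$subject_id %in% test_subjects)
  }
  list(train = dataset_subset(dataset, -test_idx),
       test = dataset_subset(dataset, test_idx))
}

#' Confusion matrix of true versus predicted labels
#'
#' @param truth,predicted character vectors of equal length.
#' @param classes class order (default: canonical order of the union).
#' @return square integer matrix, rows = truth, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (is.null(classes)) classes <- canonical_classes(c(truth, predicted))
  table(truth = factor(truth, levels = classes),
        predicted = factor(predicted, levels = classes))
}

#' Fit, test and report one evaluation cell
#'
#' Fits the classifier on the training windows, predicts the test windows,
#' and assembles overall accuracy, per-motion accuracy (row-normalised
#' confusion diagonal) and the confusion matrix. Per-window prediction time
#' is measured as wall clock over single-window predictions on a subsample
#' of the test set (timing is hardware-dependent and reported for context
#' only).
#'
#' @param train,test `emg_dataset`s.
#' @param features a [feature_spec()]: which feature columns to use.
#' @param method classifier name, see [fit_classifier()].
#' @param time_windows how many single-window predictions to time (0 skips
#'   timing).
#' @param standardize z-score the feature columns using training-set mean and
#'   standard deviation before fitting (off by default: the classifiers see
#'   raw feature units, which notably handicaps the scale-sensitive RBF SVM;
#'   the switch exists for experiments).
#' @param ... extra arguments for the classifier fit.
#' @return an `emg_report`: list with `features`, `method`, `accuracy` (%),
#'   `per_class_accuracy` (%), `confusion`, `timing_ms` (mean, sd),
#'   `n_train`, `n_test`, `model`.
#' @export
evaluate_model <- function(train, test, features = feature_names(),
                           method = "dt", time_windows = 50L,
                           standardize = FALSE, ...) {
  features <- feature_spec(features)
  tr <- dataset_select(train, features)
  te <- dataset_select(test, features)
  if (length(unique(tr$label)) < 2) stop("training set needs >= 2 classes")
  if (standardize) {
    mu <- colMeans(tr$x)
    sdev <- pmax(apply(tr$x, 2, stats::sd), 1e-12)
    tr$x <- sweep(sweep(tr$x, 2, mu), 2, sdev, "/")
    te$x <- sweep(sweep(te$x, 2, mu), 2, sdev, "/")
  }
  model <- fit_classifier(tr, method, ...)
  pred <- predict(model, te$x)
  cm <- confusion_matrix(te$label, pred, classes = model$classes)
  timing <- if (time_windows > 0)
    time_classifier(model, te$x[seq_len(min(time_windows, nrow(te$x))), ,
                                drop = FALSE])
  else list(mean_ms = NA_real_, sd_ms = NA_real_, n = 0L)
  structure(list(
    features = as.character(features), method = method,
    accuracy = 100 * sum(diag(cm)) / sum(cm),
    per_class_accuracy = 100 * diag(cm) / pmax(rowSums(cm), 1L),
    confusion = cm, timing_ms = timing,
    n_train = nrow(tr$x), n_test = nrow(te$x), model = model),
    class = "emg_report")
}

#' @export
print.emg_report <- function(x, ...) {
  cat(sprintf("<emg_report %s on %s: accuracy %.2f%% (train %d / test %d)>\n",
              x$method, paste(x$features, collapse = "+"),
              x$accuracy, x$n_train, x$n_test))
  invisible(x)
}

#' Time single-window predictions
#'
#' Wall-clock time of `predict()` on one window at a time, the quantity that
#' matters for a real-time controller. Hardware-dependent; reported, never
#' gated on.
#'
#' @param model an `emg_model`.
#' @param queries matrix of query windows (rows).
#' @param repeats how many passes over the queries.
#' @return list with `mean_ms`, `sd_ms`, `n`.
#' @export
time_classifier <- function(model, queries, repeats = 1L) {
  queries <- if (is.null(dim(queries))) matrix(queries, 1) else as.matrix(queries)
  if (nrow(queries) < 1) stop("need at least one query")
  times <- numeric(0)
  for (r in seq_len(repeats)) {
    for (i in seq_len(nrow(queries))) {
      t0 <- proc.time()[["elapsed"]]
      predict(model, queries[i, , drop = FALSE])
      times <- c(times, (proc.time()[["elapsed"]] - t0) * 1000)
    }
  }
  list(mean_ms = mean(times), sd_ms = stats::sd(times), n = length(times))
}

#' Full feature-by-classifier evaluation sweep
#'
#' Evaluates every feature combination against every classifier under the
#' requested schemes, returning one report per cell plus a tidy summary
#' table. With the four base features this is the 15 x 4 (x schemes) grid.
#'
#' @param dataset an `emg_dataset` (all four base feature columns).
#' @param schemes character subset of `c("pooled", "subject_wise")`.
#' @param base_features base features to enumerate combinations of.
#' @param methods classifier names.
#' @param seed seed for the pooled split.
#' @param test_fraction,test_subjects passed to [split_dataset()].
#' @param time_windows per-cell timing sample size.
#' @param ... extra classifier arguments.
#' @return an `emg_sweep`: list with `grid` (data.frame: scheme, features,
#'   method, accuracy, timing, sizes) and `reports` (the full reports).
#' @export
sweep_grid <- function(dataset, schemes = c("pooled", "subject_wise"),
                       base_features = feature_names(),
                       methods = c("knn", "gnb", "dt", "svm"),
                       seed = 1L, test_fraction = 0.2, test_subjects = NULL,
                       time_windows = 10L, ...) {
  specs <- enumerate_combinations(base_features)
  reports <- list()
  rows <- list()
  for (scheme in schemes) {
    sp <- split_dataset(dataset, scheme, test_fraction = test_fraction,
                        test_subjects = test_subjects, seed = seed)
    for (fs in specs) for (m in methods) {
      rep <- evaluate_model(sp$train, sp$test, fs, m,
                            time_windows = time_windows, ...)
      key <- paste(scheme, paste(fs, collapse = "+"), m, sep = "|")
      reports[[key]] <- rep
      rows[[key]] <- data.frame(
        scheme = scheme, features = paste(fs, collapse = "+"), method = m,
        accuracy = rep$accuracy, mean_time_ms = rep$timing_ms$mean_ms,
        n_train = rep$n_train, n_test = rep$n_test,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(grid = do.call(rbind, c(rows, make.row.names = FALSE)),
                 reports = reports),
            class = "emg_sweep")
}

#' @rdname sweep_grid
#' @param sweep an `emg_sweep`.
#' @return `sweep_summary()` returns per-(scheme, method) mean/min/max
#'   accuracy across feature sets, the boxplot-style summary.
#' @export
sweep_summary <- function(sweep) {
  g <- sweep$grid
  agg <- stats::aggregate(accuracy ~ scheme + method, data = g,
                          FUN = function(a) c(mean = mean(a), min = min(a),
                                              max = max(a)))
  cbind(agg[c("scheme", "method")], as.data.frame(agg$accuracy))
}

#' @rdname sweep_grid
#' @param path CSV path for the grid.
#' @export
write_sweep <- function(sweep, path) {
  data.table::fwrite(sweep$grid, path)
  invisible(path)
}

#' @rdname sweep_grid
#' @export
read_sweep_grid <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Compare accuracy samples from two evaluation schemes
#'
#' Welch's unequal-variance two-sample t-test (two-sided) on two groups of
#' accuracies, e.g. the per-feature-set accuracies of one classifier under
#' the pooled versus the subject-wise scheme. When both samples are constant
#' the statistic degenerates: equal means give `t = 0, p = 1`, unequal means
#' `t = Inf (signed), p = 0`. Student's pooled-variance test is selectable.
#'
#' @param acc1,acc2 numeric samples (length >= 2 each).
#' @param var_equal use the pooled-variance (Student) test.
#' @return list with `statistic`, `p_value`, `df`, `mean1`, `mean2`.
#' @export
compare_schemes <- function(acc1, acc2, var_equal = FALSE) {
  if (length(acc1) < 2 || length(acc2) < 2)
    stop("each sample needs at least 2 values")
  if (stats::sd(acc1) == 0 && stats::sd(acc2) == 0) {
    eq <- isTRUE(all.equal(mean(acc1), mean(acc2)))
    return(list(statistic = if (eq) 0 else sign(mean(acc1) - mean(acc2)) * Inf,
                p_value = if (eq) 1 else 0, df = NA_real_,
                mean1 = mean(acc1), mean2 = mean(acc2)))
  }
  tt <- stats::t.test(acc1, acc2, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean1 = mean(acc1), mean2 = mean(acc2))
}

#' Confusion matrices to JSON
#'
#' @param reports list of `emg_report` (or an `emg_sweep`'s `reports`).
#' @param path output path.
#' @export
write_confusions_json <- function(reports, path) {
  payload <- lapply(reports, function(r) list(
    features = r$features, method = r$method, accuracy = r$accuracy,
    classes = rownames(r$confusion),
    confusion = unclass(unname(r$confusion))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
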