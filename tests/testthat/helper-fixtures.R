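# in-code fixtures shared across test files

# tiny labeled dataset wrapper around a plain matrix
toy_dataset <- function(x, labels, subjects = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  structure(list(x = x, label = as.character(labels),
                 subject_id = if (is.null(subjects)) rep("S01", nrow(x))
                              else as.character(subjects),
                 start = seq_len(nrow(x)) - 1L),
            class = "emg_dataset")
}

# two well-separated gaussian blobs in d dimensions
blob_dataset <- function(n_per = 20, d = 2, sep = 4, classes = c("A", "B"),
                         seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_along(classes), function(k)
    matrix(stats::rnorm(n_per * d, mean = (k - 1) * sep), ncol = d)))
  toy_dataset(x, rep(classes, each = n_per))
}

# short synthetic session for fast end-to-end tests
short_record <- function(seed = 1, reps = 2, hold_s = 1, variability = 0.3) {
  generate_session(sample_subject(seed, variability),
                   session_protocol(reps = reps, hold_s = hold_s),
                   seed = seed + 500)
}

# independent brute-force k-NN oracle (per-query loop, no shared code path
# with the vectorised implementation beyond the distance definition)
knn_oracle <- function(train_x, train_y, query, k, c = 2) {
  d <- apply(train_x, 1, function(row) sum(abs(row - query)^c)^(1 / c))
  nb <- order(d)[seq_len(k)]
  classes <- canonical_classes(train_y)
  votes <- table(factor(train_y[nb], levels = classes))
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1) {
    sums <- vapply(top, function(cl) sum(d[nb][train_y[nb] == cl]), 0.0)
    top <- top[sums == min(sums)]
  }
  top[1]
}

# hand-computed Gaussian naive Bayes posterior via dnorm
gnb_oracle_proba <- function(train_x, train_y, query, var_smoothing = 1e-9) {
  classes <- canonical_classes(train_y)
  pooled <- colMeans(sweep(train_x, 2, colMeans(train_x))^2)
  eps <- var_smoothing * max(pooled)
  post <- vapply(classes, function(cl) {
    xc <- train_x[train_y == cl, , drop = FALSE]
    mu <- colMeans(xc)
    va <- colMeans(sweep(xc, 2, mu)^2) + eps
    prior <- nrow(xc) / nrow(train_x)
    prior * prod(stats::dnorm(query, mu, sqrt(va)))
  }, 0.0)
  post / sum(post)
}
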