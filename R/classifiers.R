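#' Deterministic class ordering
#'
#' All classifier tie-breaks (k-NN vote, tree leaf majority, SVM vote)
#' resolve by this fixed order: the four motions in canonical order first
#' (`GRASP < FLEXION < EXTENSION < RELAX`), then any other labels
#' alphabetically. This makes every fit and prediction deterministic.
#'
#' @param labels character vector of observed labels.
#' @return unique labels in canonical order.
#' @export
canonical_classes <- function(labels) {
  u <- unique(labels)
  rank <- match(u, motion_levels(), nomatch = length(motion_levels()) + 1L)
  u[order(rank, u)]
}

as_xy <- function(data) {
  if (inherits(data, "emg_dataset"))
    list(x = unname(data$x), y = data$label, colnames = colnames(data$x))
  else stop("expected an emg_dataset")
}

query_matrix <- function(model, newdata) {
  x <- if (inherits(newdata, "emg_dataset")) newdata$x else newdata
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- unname(as.matrix(x))
  if (ncol(x) != model$n_features)
    stop(sprintf("query has %d features, model expects %d",
                 ncol(x), model$n_features))
  x
}

#' Minkowski distance
#'
#' `d(x, y) = (sum |x_i - y_i|^c)^(1/c)`; `c = 1` is Manhattan, `c = 2`
#' Euclidean.
#'
#' @param x,y numeric vectors of equal length.
#' @param c positive exponent.
#' @return scalar distance.
#' @export
minkowski <- function(x, y, c = 2) {
  if (length(x) != length(y)) stop("length mismatch")
  if (c <= 0) stop("Minkowski exponent must be positive")
  sum(abs(x - y)^c)^(1 / c)
}

# ---- k-nearest neighbours -------------------------------------------------

#' k-nearest-neighbour classifier
#'
#' Instance-based classifier: a query is assigned the majority label among
#' its `k` nearest training windows under the Minkowski distance (Euclidean
#' by default, `k = 5` as in typical EMG pattern-recognition practice). Vote
#' ties are broken by the smallest summed distance among the tied classes,
#' then by [canonical_classes()] order.
#'
#' @param data an `emg_dataset` (training windows).
#' @param k neighbourhood size, `1 <= k <= n`.
#' @param c Minkowski exponent.
#' @return a model of class `c("emg_knn", "emg_model")`.
#' @export
knn_fit <- function(data, k = 5L, c = 2) {
  d <- as_xy(data)
  if (k < 1 || k > nrow(d$x))
    stop("k must be between 1 and the number of training rows")
  structure(list(method = "knn", x = d$x, y = d$y, k = as.integer(k), c = c,
                 classes = canonical_classes(d$y), n_features = ncol(d$x),
                 feature_names = d$colnames),
            class = c("emg_knn", "emg_model"))
}

#' @rdname knn_fit
#' @param object fitted model.
#' @param newdata query matrix (rows = windows) or `emg_dataset`.
#' @param ... unused.
#' @export
predict.emg_knn <- function(object, newdata, ...) {
  q <- query_matrix(object, newdata)
  n_tr <- nrow(object$x)
  out <- character(nrow(q))
  # chunk the query set so the distance block stays small
  chunk <- max(1L, floor(5e6 / n_tr))
  for (from in seq(1L, nrow(q), by = chunk)) {
    idx <- from:min(nrow(q), from + chunk - 1L)
    dist <- minkowski_cross(q[idx, , drop = FALSE], object$x, object$c)
    out[idx] <- apply(dist, 1, function(dr) {
      nb <- order(dr)[seq_len(object$k)]
      votes <- table(factor(object$y[nb], levels = object$classes))
      top <- names(votes)[votes == max(votes)]
      if (length(top) > 1) {
        sums <- vapply(top, function(cl)
          sum(dr[nb][object$y[nb] == cl]), 0.0)
        top <- top[sums == min(sums)]
      }
      top[1]
    })
  }
  out
}

# pairwise Minkowski distances between row sets (queries x training)
minkowski_cross <- function(a, b, c = 2) {
  if (c == 2) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
    sqrt(pmax(d2, 0))
  } else {
    acc <- matrix(0, nrow(a), nrow(b))
    for (j in seq_len(ncol(a)))
      acc <- acc + abs(outer(a[, j], b[, j], `-`))^c
    acc^(1 / c)
  }
}

# ---- Gaussian naive Bayes -------------------------------------------------

#' Gaussian naive Bayes classifier
#'
#' Class-conditional independent Gaussians per feature: the posterior is
#' proportional to the class prior (estimated from training class
#' frequencies) times the product of per-feature normal densities. Each
#' per-class feature variance receives additive smoothing
#' `var_smoothing * max(pooled feature variances)` for numerical stability
#' (default `1e-9`).
#'
#' @param data an `emg_dataset`.
#' @param var_smoothing smoothing fraction applied to the largest pooled
#'   feature variance.
#' @return a model of class `c("emg_gnb", "emg_model")`.
#' @export
gnb_fit <- function(data, var_smoothing = 1e-9) {
  d <- as_xy(data)
  classes <- canonical_classes(d$y)
  counts <- vapply(classes, function(cl) sum(d$y == cl), 0L)
  small <- classes[counts < 2]
  if (length(small))
    stop("class with fewer than 2 training samples: ",
         paste(small, collapse = ", "))
  p <- ncol(d$x)
  mu <- matrix(vapply(classes, function(cl)
    colMeans(d$x[d$y == cl, , drop = FALSE]), numeric(p)),
    ncol = p, byrow = TRUE)
  va <- matrix(vapply(classes, function(cl) {
    xc <- d$x[d$y == cl, , drop = FALSE]
    colMeans(sweep(xc, 2, colMeans(xc))^2)  # MLE (1/n) variance
  }, numeric(p)), ncol = p, byrow = TRUE)
  pooled <- colMeans(sweep(d$x, 2, colMeans(d$x))^2)
  eps <- var_smoothing * max(pooled)
  structure(list(method = "gnb", classes = classes,
                 prior = counts / sum(counts), mu = mu, var = va + eps,
                 epsilon = eps, n_features = ncol(d$x),
                 feature_names = d$colnames),
            class = c("emg_gnb", "emg_model"))
}

#' @rdname gnb_fit
#' @param object fitted model.
#' @param newdata query matrix or `emg_dataset`.
#' @param ... unused.
#' @return `gnb_predict_proba()` returns a queries x classes matrix of
#'   posterior probabilities (rows sum to 1).
#' @export
gnb_predict_proba <- function(object, newdata, ...) {
  q <- query_matrix(object, newdata)
  loglik <- vapply(seq_along(object$classes), function(ci) {
    mu <- object$mu[ci, ]; va <- object$var[ci, ]
    rowSums(-0.5 * log(2 * pi * matrix(va, nrow(q), ncol(q), byrow = TRUE)) -
              0.5 * sweep(q, 2, mu)^2 %*% diag(1 / va, ncol(q))) +
      log(object$prior[ci])
  }, numeric(nrow(q)))
  loglik <- matrix(loglik, nrow = nrow(q),
                   dimnames = list(NULL, object$classes))
  m <- apply(loglik, 1, max)
  p <- exp(loglik - m)
  p / rowSums(p)
}

#' @rdname gnb_fit
#' @export
predict.emg_gnb <- function(object, newdata, ...) {
  p <- gnb_predict_proba(object, newdata)
  object$classes[max.col(p, ties.method = "first")]
}

# ---- entropy decision tree ------------------------------------------------

#' Shannon entropy of a label multiset (bits)
#'
#' `E(s) = -sum p_i log2 p_i` over class proportions, with `0 log 0 = 0`.
#'
#' @param labels non-empty character vector.
#' @return entropy in bits.
#' @export
entropy <- function(labels) {
  if (length(labels) == 0) stop("entropy of an empty set is undefined")
  p <- as.numeric(table(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Entropy-based decision tree classifier
#'
#' Greedy binary recursive partitioning maximising information gain (entropy
#' reduction). Candidate thresholds are midpoints between consecutive
#' distinct sorted values of each feature; splitting stops at the maximum
#' depth (default 3, the shallow pre-pruned tree typical of embedded EMG
#' classifiers), at node purity, or when no split yields positive gain.
#' Leaves predict their majority label (ties by [canonical_classes()] order).
#'
#' @param data an `emg_dataset`.
#' @param max_depth maximum tree depth (root = depth 0).
#' @param min_leaf minimum samples per child.
#' @return a model of class `c("emg_dt", "emg_model")`.
#' @export
dt_fit <- function(data, max_depth = 3L, min_leaf = 1L) {
  d <- as_xy(data)
  classes <- canonical_classes(d$y)
  tree <- grow_node(d$x, d$y, classes, depth = 0L,
                    max_depth = as.integer(max_depth),
                    min_leaf = as.integer(min_leaf))
  structure(list(method = "dt", tree = tree, classes = classes,
                 max_depth = as.integer(max_depth),
                 n_features = ncol(d$x), feature_names = d$colnames),
            class = c("emg_dt", "emg_model"))
}

make_leaf <- function(y, classes, depth) {
  counts <- table(factor(y, levels = classes))
  top <- names(counts)[counts == max(counts)][1]  # canonical-order tie-break
  list(leaf = TRUE, label = top,
       counts = stats::setNames(as.integer(counts), classes), depth = depth)
}

grow_node <- function(x, y, classes, depth, max_depth, min_leaf) {
  h <- entropy(y)
  if (depth >= max_depth || h == 0 || nrow(x) < 2 * min_leaf)
    return(make_leaf(y, classes, depth))
  best <- best_split(x, y, classes, min_leaf)
  # split any impure node with a valid cut, even at zero immediate gain
  # (a positive-gain requirement makes XOR-like patterns unlearnable)
  if (is.null(best)) return(make_leaf(y, classes, depth))
  left <- x[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       gain = best$gain, depth = depth,
       left = grow_node(x[left, , drop = FALSE], y[left], classes,
                        depth + 1L, max_depth, min_leaf),
       right = grow_node(x[!left, , drop = FALSE], y[!left], classes,
                         depth + 1L, max_depth, min_leaf))
}

# exhaustive best information-gain split; vectorised by cumulative class
# counts over each feature's sort order
best_split <- function(x, y, classes, min_leaf) {
  n <- nrow(x)
  parent_h <- entropy(y)
  yf <- factor(y, levels = classes)
  best <- NULL
  for (f in seq_len(ncol(x))) {
    ord <- order(x[, f])
    xs <- x[ord, f]
    ind <- stats::model.matrix(~ yf - 1)[ord, , drop = FALSE]
    cum <- apply(ind, 2, cumsum)
    # split after position i is valid where the value changes
    cut <- which(diff(xs) > 0)
    cut <- cut[cut >= min_leaf & (n - cut) >= min_leaf]
    if (!length(cut)) next
    nl <- cut; nr <- n - cut
    hl <- row_entropy(cum[cut, , drop = FALSE], nl)
    hr <- row_entropy(sweep(cum[cut, , drop = FALSE], 2,
                            cum[n, ], `-`) * -1, nr)
    gain <- parent_h - (nl / n) * hl - (nr / n) * hr
    i <- which.max(gain)
    if (is.null(best) || gain[i] > best$gain + 1e-15) {
      best <- list(feature = f, gain = unname(gain[i]),
                   threshold = unname((xs[cut[i]] + xs[cut[i] + 1]) / 2))
    }
  }
  best
}

row_entropy <- function(counts, totals) {
  p <- counts / totals
  rowSums(ifelse(p > 0, -p * log2(p), 0))
}

#' @rdname dt_fit
#' @param object fitted model.
#' @param newdata query matrix or `emg_dataset`.
#' @param ... unused.
#' @export
predict.emg_dt <- function(object, newdata, ...) {
  q <- query_matrix(object, newdata)
  apply(q, 1, function(row) {
    node <- object$tree
    while (!node$leaf)
      node <- if (row[node$feature] <= node$threshold) node$left else node$right
    node$label
  })
}

#' @rdname dt_fit
#' @param model fitted `emg_dt`.
#' @export
dt_depth <- function(model) node_depth(model$tree)

node_depth <- function(node) {
  if (node$leaf) return(0L)
  1L + max(node_depth(node$left), node_depth(node$right))
}

# ---- RBF-kernel support vector machine ------------------------------------

#' RBF-kernel support vector machine (SMO)
#'
#' Soft-margin SVM trained by sequential minimal optimisation of the dual
#' problem (maximise `sum a_i - 1/2 sum a_i a_j y_i y_j K(x_i, x_j)` subject
#' to `0 <= a_i <= C`, `sum a_i y_i = 0`) with the Gaussian kernel
#' `K(u, v) = exp(-gamma |u - v|^2)`. Working pairs are chosen by the
#' deterministic maximal-violating-pair rule, so fits are reproducible.
#' Multiclass problems are decomposed one-vs-one with majority voting; vote
#' ties are broken by the largest aggregate signed decision value, then by
#' [canonical_classes()] order.
#'
#' @param data an `emg_dataset` with at least 2 classes.
#' @param gamma kernel width; `"auto"` (default) uses `1 / n_features`.
#' @param cost box constraint C on the dual coefficients.
#' @param tol KKT violation tolerance for SMO convergence.
#' @param max_iter iteration cap per pairwise sub-problem.
#' @return a model of class `c("emg_svm", "emg_model")`; each pairwise
#'   sub-model records its support vectors, dual coefficients `alpha`,
#'   labels and bias `rho` (decision value `sum alpha_i y_i K(x, sv_i) - rho`).
#' @export
svm_fit <- function(data, gamma = "auto", cost = 1, tol = 1e-3,
                    max_iter = 100000L) {
  d <- as_xy(data)
  classes <- canonical_classes(d$y)
  if (length(classes) < 2) stop("SVM requires at least 2 classes")
  if (identical(gamma, "auto")) gamma <- 1 / ncol(d$x)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  submodels <- lapply(pairs, function(pr) {
    sel <- d$y %in% pr
    xs <- d$x[sel, , drop = FALSE]
    ys <- ifelse(d$y[sel] == pr[1], 1, -1)
    fit <- smo_solve(xs, ys, gamma, cost, tol, max_iter)
    sv <- fit$alpha > 1e-12
    list(pos = pr[1], neg = pr[2], sv = xs[sv, , drop = FALSE],
         alpha = fit$alpha[sv], y = ys[sv], rho = fit$rho,
         alpha_y_sum = sum(fit$alpha * ys), iterations = fit$iterations,
         converged = fit$converged)
  })
  structure(list(method = "svm", classes = classes, gamma = gamma,
                 cost = cost, tol = tol, submodels = submodels,
                 n_features = ncol(d$x), feature_names = d$colnames),
            class = c("emg_svm", "emg_model"))
}

rbf_kernel <- function(a, b, gamma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

# SMO with maximal-violating-pair working-set selection
smo_solve <- function(x, y, gamma, cost, tol, max_iter) {
  n <- nrow(x)
  K <- rbf_kernel(x, x, gamma)
  alpha <- numeric(n)
  grad <- rep(-1, n)            # gradient of 1/2 a'Qa - e'a at a = 0
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    up <- (y > 0 & alpha < cost - 1e-12) | (y < 0 & alpha > 1e-12)
    lo <- (y < 0 & alpha < cost - 1e-12) | (y > 0 & alpha > 1e-12)
    v <- -y * grad
    i <- which(up)[which.max(v[up])]
    j <- which(lo)[which.min(v[lo])]
    if (length(i) == 0 || length(j) == 0 || v[i] - v[j] < tol) {
      converged <- TRUE
      break
    }
    # analytic two-variable update (box [L, H] preserves sum a_i y_i)
    if (y[i] != y[j]) {
      L <- max(0, alpha[j] - alpha[i]); H <- min(cost, cost + alpha[j] - alpha[i])
    } else {
      L <- max(0, alpha[i] + alpha[j] - cost); H <- min(cost, alpha[i] + alpha[j])
    }
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (eta <= 1e-12) eta <- 1e-12
    aj <- alpha[j] + y[j] * (y[i] * grad[i] - y[j] * grad[j]) / eta
    aj <- min(max(aj, L), H)
    ai <- alpha[i] + y[i] * y[j] * (alpha[j] - aj)
    dai <- ai - alpha[i]; daj <- aj - alpha[j]
    grad <- grad + (y * K[, i]) * (y[i] * dai) + (y * K[, j]) * (y[j] * daj)
    alpha[i] <- ai; alpha[j] <- aj
  }
  free <- alpha > 1e-12 & alpha < cost - 1e-12
  rho <- if (any(free)) mean(y[free] * grad[free]) else {
    up <- (y > 0 & alpha < cost - 1e-12) | (y < 0 & alpha > 1e-12)
    lo <- (y < 0 & alpha < cost - 1e-12) | (y > 0 & alpha > 1e-12)
    v <- -y * grad
    -(max(v[up]) + min(v[lo])) / 2
  }
  list(alpha = alpha, rho = rho, iterations = it, converged = converged)
}

svm_decision <- function(sub, q, gamma) {
  if (nrow(sub$sv) == 0) return(rep(-sub$rho, nrow(q)))
  drop(rbf_kernel(q, sub$sv, gamma) %*% (sub$alpha * sub$y)) - sub$rho
}

#' @rdname svm_fit
#' @param object fitted model.
#' @param newdata query matrix or `emg_dataset`.
#' @param ... unused.
#' @export
predict.emg_svm <- function(object, newdata, ...) {
  q <- query_matrix(object, newdata)
  classes <- object$classes
  votes <- matrix(0L, nrow(q), length(classes),
                  dimnames = list(NULL, classes))
  margin <- matrix(0, nrow(q), length(classes),
                   dimnames = list(NULL, classes))
  for (sub in object$submodels) {
    dv <- svm_decision(sub, q, object$gamma)
    win <- ifelse(dv > 0, sub$pos, sub$neg)
    for (cl in c(sub$pos, sub$neg)) {
      sel <- win == cl
      votes[sel, cl] <- votes[sel, cl] + 1L
    }
    margin[, sub$pos] <- margin[, sub$pos] + dv
    margin[, sub$neg] <- margin[, sub$neg] - dv
  }
  vapply(seq_len(nrow(q)), function(r) {
    top <- classes[votes[r, ] == max(votes[r, ])]
    if (length(top) > 1) top <- top[margin[r, top] == max(margin[r, top])]
    top[1]
  }, "")
}

# ---- common surface -------------------------------------------------------

#' Fit any of the four classifiers behind one contract
#'
#' @param data an `emg_dataset`.
#' @param method one of `"knn"`, `"gnb"`, `"dt"`, `"svm"`.
#' @param ... method-specific arguments (see [knn_fit()], [gnb_fit()],
#'   [dt_fit()], [svm_fit()]).
#' @return an `emg_model`; predictions via `predict(model, newdata)`.
#' @export
fit_classifier <- function(data, method = c("knn", "gnb", "dt", "svm"), ...) {
  method <- match.arg(method)
  switch(method, knn = knn_fit(data, ...), gnb = gnb_fit(data, ...),
         dt = dt_fit(data, ...), svm = svm_fit(data, ...))
}

#' @export
print.emg_model <- function(x, ...) {
  cat(sprintf("<emg_model %s: %d features, classes %s>\n", x$method,
              x$n_features, paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Serialize / restore a fitted model as JSON
#'
#' All learned parameters are written explicitly at full double precision
#' under a versioned schema, so `read_model_json()` followed by `predict()`
#' is bit-identical to predicting with the original fit.
#'
#' @param model an `emg_model`.
#' @param path file path.
#' @return `read_model_json()` returns the restored model.
#' @export
write_model_json <- function(model, path) {
  payload <- list(schema = "emgpr-model-1", class = class(model),
                  model = unclass(model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "emgpr-model-1"))
    stop("unrecognised model schema: ", obj$schema)
  m <- obj$model
  m$n_features <- as.integer(m$n_features)
  if (m$method == "knn") m$x <- as.matrix(m$x)
  if (m$method == "gnb") { m$mu <- as.matrix(m$mu); m$var <- as.matrix(m$var) }
  if (m$method == "dt") m$tree <- restore_tree(m$tree)
  if (m$method == "svm") {
    m$submodels <- lapply(seq_len(nrow(m$submodels)), function(i) {
      s <- lapply(m$submodels, function(col) if (is.data.frame(col)) col[i, ] else col[[i]])
      s$sv <- matrix(unlist(s$sv), ncol = m$n_features, byrow = FALSE)
      s$alpha <- as.numeric(unlist(s$alpha)); s$y <- as.numeric(unlist(s$y))
      s
    })
  }
  structure(m, class = obj$class)
}

restore_tree <- function(node) {
  node$leaf <- as.logical(node$leaf)
  if (node$leaf) {
    node$counts <- unlist(node$counts)
    return(node)
  }
  node$left <- restore_tree(node$left)
  node$right <- restore_tree(node$right)
  node
}
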