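#' Canonical time-domain feature names
#'
#' The four window features used for EMG pattern recognition, in the fixed
#' listing order used when enumerating feature combinations.
#' @return character vector `c("MAV", "RMS", "SSI", "VAR")`.
#' @export
feature_names <- function() c("MAV", "RMS", "SSI", "VAR")

#' Time-domain window features
#'
#' For a window `x` of `N` samples:
#' * `mav(x)`  — mean absolute value, `mean(|x|)`;
#' * `rms(x)`  — root mean square, `sqrt(mean(x^2))`;
#' * `ssi(x)`  — simple square integral, `sum(x^2)` (total window energy);
#' * `var_td(x)` — `sum(x^2) / (N - 1)`.
#'
#' Note `var_td` deliberately performs **no mean subtraction**: it is the sum
#' of squares over `N - 1`, the form conventionally printed in the EMG
#' time-domain feature literature, and is therefore `ssi / (N - 1)` exactly.
#' A textbook mean-subtracted variance is available via
#' `var_td(x, textbook = TRUE)`. All four features are nonnegative; for a
#' filtered (near zero-mean) signal MAV and RMS scale linearly with amplitude
#' and SSI/VAR quadratically.
#'
#' @param x numeric vector of window samples (non-empty; `var_td` needs
#'   `N >= 2`).
#' @param textbook use the mean-subtracted sample variance instead of the
#'   printed no-mean-subtraction form.
#' @return scalar feature value.
#' @export
mav <- function(x) { check_window(x); mean(abs(x)) }

#' @rdname mav
#' @export
rms <- function(x) { check_window(x); sqrt(mean(x^2)) }

#' @rdname mav
#' @export
ssi <- function(x) { check_window(x); sum(x^2) }

#' @rdname mav
#' @export
var_td <- function(x, textbook = FALSE) {
  check_window(x)
  if (length(x) < 2) stop("var_td requires at least 2 samples")
  if (textbook) stats::var(x) else sum(x^2) / (length(x) - 1)
}

check_window <- function(x) {
  if (length(x) == 0) stop("empty window")
  if (anyNA(x)) stop("window contains NA")
  invisible(TRUE)
}

#' Segment a recording into fixed-length analysis windows
#'
#' Slices the record into windows of `window_ms` milliseconds starting at
#' multiples of `step_ms` (disjoint windows by default); the trailing
#' incomplete window is dropped. Each window is labeled by the policy:
#' `"strict"` (default) assigns a motion label only when every sample in the
#' window carries that label, otherwise `TRANSITION`; `"majority"` assigns
#' the modal sample label.
#'
#' @param record an `emg_record`.
#' @param window_ms window length in milliseconds (> 0); 100 ms at 1000 Hz
#'   gives the standard 100-sample EMG analysis frame.
#' @param step_ms hop between window starts in milliseconds (> 0); defaults
#'   to the window length.
#' @param label_policy `"strict"` or `"majority"`.
#' @return list of `emg_window` objects, each with `samples` (N x 2 matrix),
#'   `n`, `label`, `subject_id` and `start` (0-based sample index). A record
#'   shorter than one window yields an empty list.
#' @export
segment_record <- function(record, window_ms = 100, step_ms = window_ms,
                           label_policy = c("strict", "majority")) {
  stopifnot(window_ms > 0, step_ms > 0)
  label_policy <- match.arg(label_policy)
  w <- as.integer(round(window_ms * record$fs / 1000))
  s <- as.integer(round(step_ms * record$fs / 1000))
  n <- nrow(record$samples)
  if (w > n) return(list())
  starts <- seq(1L, n - w + 1L, by = s)
  lapply(starts, function(from) {
    idx <- from:(from + w - 1L)
    labs <- record$labels[idx]
    label <- if (label_policy == "strict") {
      if (length(unique(labs)) == 1) labs[1] else "TRANSITION"
    } else {
      names(which.max(table(factor(labs, levels = label_levels()))))
    }
    structure(list(samples = record$samples[idx, , drop = FALSE],
                   n = w, label = label, subject_id = record$subject_id,
                   start = from - 1L),
              class = "emg_window")
  })
}

#' Feature subset specification
#'
#' An ordered subset of [feature_names()]; the resulting vector layout is
#' feature-major, channel-minor (e.g. `MAV_ch1, MAV_ch2, RMS_ch1, RMS_ch2`).
#'
#' @param features character vector, non-empty subset of [feature_names()].
#' @return validated character vector of class `feature_spec`.
#' @export
feature_spec <- function(features) {
  features <- toupper(as.character(features))
  if (length(features) == 0) stop("feature spec must be non-empty")
  if (anyDuplicated(features)) stop("duplicate features in spec")
  bad <- setdiff(features, feature_names())
  if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  structure(features, class = "feature_spec")
}

feature_colnames <- function(spec, n_channels = 2L) {
  as.vector(t(outer(spec, paste0("ch", seq_len(n_channels)), paste, sep = "_")))
}

#' Extract a feature vector from one window
#'
#' Applies each feature in the spec to each channel, feature-major
#' channel-minor ordering.
#'
#' @param window an `emg_window` from [segment_record()].
#' @param spec a [feature_spec()] (default: all four features).
#' @return named numeric vector of length `length(spec) * n_channels`.
#' @export
extract_features <- function(window, spec = feature_spec(feature_names())) {
  spec <- feature_spec(spec)
  fns <- list(MAV = mav, RMS = rms, SSI = ssi, VAR = var_td)
  vals <- unlist(lapply(spec, function(f)
    apply(window$samples, 2, fns[[f]])), use.names = FALSE)
  stats::setNames(vals, feature_colnames(spec, ncol(window$samples)))
}

#' Enumerate all feature combinations
#'
#' All non-empty subsets of the base features, ordered by subset size and
#' then by the canonical listing order (MAV, RMS, SSI, VAR). The four base
#' features yield the standard fifteen combinations.
#'
#' @param base character vector of base features (default all four).
#' @return list of `feature_spec`, length `2^length(base) - 1`.
#' @export
enumerate_combinations <- function(base = feature_names()) {
  base <- feature_spec(base)
  base <- base[order(match(base, feature_names()))]
  out <- list()
  for (size in seq_along(base)) {
    combos <- utils::combn(as.character(base), size, simplify = FALSE)
    out <- c(out, lapply(combos, feature_spec))
  }
  out
}

#' Build a labeled window-feature dataset from recordings
#'
#' Segments each (already preprocessed) record, computes **all four** base
#' features per window and channel, and stacks them into one feature matrix;
#' a subset of feature columns for a given combination is then selected with
#' [dataset_select()] without recomputation. Transition-labeled windows are
#' excluded by default since the protocol does not define a motion for them.
#'
#' @param records an `emg_record` or list of them.
#' @param window_ms,step_ms,label_policy see [segment_record()].
#' @param include_transition keep `TRANSITION` windows (default drop).
#' @return an `emg_dataset`: list with `x` (matrix, 8 columns), `label`
#'   (character), `subject_id` (character), `start` (integer).
#' @export
build_dataset <- function(records, window_ms = 100, step_ms = window_ms,
                          label_policy = "strict",
                          include_transition = FALSE) {
  if (inherits(records, "emg_record")) records <- list(records)
  windows <- unlist(lapply(records, segment_record, window_ms = window_ms,
                           step_ms = step_ms, label_policy = label_policy),
                    recursive = FALSE)
  if (!include_transition)
    windows <- Filter(function(w) w$label != "TRANSITION", windows)
  if (length(windows) == 0) stop("no usable windows")
  x <- do.call(rbind, lapply(windows, extract_features))
  structure(list(x = x,
                 label = vapply(windows, `[[`, "", "label"),
                 subject_id = vapply(windows, `[[`, "", "subject_id"),
                 start = vapply(windows, `[[`, 0L, "start")),
            class = "emg_dataset")
}

#' @rdname build_dataset
#' @param dataset an `emg_dataset`.
#' @param spec a [feature_spec()] selecting feature columns.
#' @export
dataset_select <- function(dataset, spec) {
  spec <- feature_spec(spec)
  cols <- feature_colnames(spec, 2L)
  out <- dataset
  out$x <- dataset$x[, cols, drop = FALSE]
  out
}

#' @rdname build_dataset
#' @param i integer/logical row index.
#' @export
dataset_subset <- function(dataset, i) {
  out <- dataset
  out$x <- dataset$x[i, , drop = FALSE]
  out$label <- dataset$label[i]
  out$subject_id <- dataset$subject_id[i]
  out$start <- dataset$start[i]
  out
}

#' @export
print.emg_dataset <- function(x, ...) {
  cat(sprintf("<emg_dataset: %d windows x %d features, %d subjects>\n",
              nrow(x$x), ncol(x$x), length(unique(x$subject_id))))
  invisible(x)
}

#' Persist a window-feature dataset as delimited text
#'
#' One row per window: feature columns, then `label`, `subject_id`,
#' `window_start`.
#'
#' @param dataset an `emg_dataset`.
#' @param path file path.
#' @return `read_dataset()` returns the restored `emg_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  dt <- data.table::as.data.table(dataset$x)
  dt$label <- dataset$label
  dt$subject_id <- dataset$subject_id
  dt$window_start <- dataset$start
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  dt <- data.table::fread(path)
  meta <- c("label", "subject_id", "window_start")
  stopifnot(all(meta %in% names(dt)))
  x <- as.matrix(dt[, setdiff(names(dt), meta), with = FALSE])
  structure(list(x = x, label = as.character(dt$label),
                 subject_id = as.character(dt$subject_id),
                 start = as.integer(dt$window_start)),
            class = "emg_dataset")
}
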