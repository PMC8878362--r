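#' Write / read an EMG recording as delimited text
#'
#' The on-disk schema is CSV with columns `time_s, ch1, ch2, label,
#' subject_id`; the time column is derived from the 0-based sample index and
#' the sampling rate (it is informational, the index is authoritative).
#' Samples survive a round trip to at least 15 significant digits and labels
#' and ids exactly.
#'
#' @param record an `emg_record`.
#' @param path file path.
#' @return `read_record()` returns a validated `emg_record`.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "emg_record"))
  n <- nrow(record$samples)
  dt <- data.table::data.table(
    time_s = (seq_len(n) - 1) / record$fs,
    ch1 = record$samples[, 1], ch2 = record$samples[, 2],
    label = record$labels, subject_id = record$subject_id)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- names(data.table::fread(path, nrows = 0L))
  required <- c("time_s", "ch1", "ch2", "label", "subject_id")
  missing <- setdiff(required, header)
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  dt <- data.table::fread(path, colClasses = list(
    numeric = c("time_s", "ch1", "ch2"), character = c("label", "subject_id")))
  if (nrow(dt) == 0) stop("no samples in ", path)
  bad <- which(!(dt$label %in% label_levels()))
  if (length(bad))
    stop(sprintf("unknown label %s at line %d of %s",
                 dt$label[bad[1]], bad[1] + 1L, path))
  if (is.unsorted(dt$time_s, strictly = FALSE))
    stop("non-monotone time column in ", path)
  sid <- unique(dt$subject_id)
  if (length(sid) != 1) stop("multiple subject_ids in one record file")
  # infer fs from the median time step; index remains authoritative
  fs <- if (nrow(dt) > 1) 1 / stats::median(diff(dt$time_s)) else 1000
  emg_record(sid, round(fs), cbind(dt$ch1, dt$ch2), dt$label)
}

#' Block of consecutive samples from a stream
#'
#' @param samples numeric matrix (samples x channels).
#' @param start 0-based index of the first sample in the stream.
#' @param fs sampling rate in Hz.
#' @return an object of class `sample_block`.
#' @export
sample_block <- function(samples, start, fs) {
  samples <- as.matrix(samples)
  stopifnot(start >= 0, fs > 0)
  structure(list(samples = samples, start = as.integer(start),
                 fs = as.numeric(fs)), class = "sample_block")
}

#' Bounded ring buffer over multi-channel samples
#'
#' Fixed-capacity FIFO storage for the acquisition stage: pushes append
#' samples, evicting the oldest once full; a snapshot returns the most recent
#' samples in arrival order. Never exposes more than `capacity` samples.
#'
#' @param capacity maximum number of samples retained.
#' @param n_channels channel count.
#' @return a `ring_buffer` object (updated copies are returned by
#'   [rb_push()]).
#' @export
ring_buffer <- function(capacity, n_channels = 2L) {
  stopifnot(capacity >= 1, n_channels >= 1)
  structure(list(capacity = as.integer(capacity),
                 data = matrix(NA_real_, capacity, n_channels),
                 cursor = 0L, total = 0L,
                 n_channels = as.integer(n_channels)),
            class = "ring_buffer")
}

#' @rdname ring_buffer
#' @param buf a `ring_buffer`.
#' @param block a `sample_block` or numeric matrix.
#' @export
rb_push <- function(buf, block) {
  x <- if (inherits(block, "sample_block")) block$samples else as.matrix(block)
  if (nrow(x) == 0) return(buf)
  if (ncol(x) != buf$n_channels)
    stop(sprintf("block has %d channels, buffer expects %d",
                 ncol(x), buf$n_channels))
  for (i in seq_len(nrow(x))) {
    buf$cursor <- (buf$cursor %% buf$capacity) + 1L
    buf$data[buf$cursor, ] <- x[i, ]
  }
  buf$total <- buf$total + nrow(x)
  buf
}

#' @rdname ring_buffer
#' @param n number of most-recent samples requested.
#' @export
rb_snapshot <- function(buf, n) {
  if (n > min(buf$total, buf$capacity))
    stop(sprintf("snapshot of %d samples requested but only %d available",
                 n, min(buf$total, buf$capacity)))
  if (n == 0) return(buf$data[0, , drop = FALSE])
  idx <- ((buf$cursor - n + seq_len(n) - 1L) %% buf$capacity) + 1L
  buf$data[idx, , drop = FALSE]
}

#' Replay a recording as a stream of sample blocks
#'
#' Simulates the data-acquisition front end by yielding consecutive
#' non-overlapping blocks covering the record (the trailing partial block is
#' emitted, not dropped, so streaming and offline paths see identical data).
#' Returns a closure-based iterator: each call to `$next_block()` yields a
#' `sample_block` or `NULL` when exhausted. With `realtime = TRUE`, emission
#' is paced at `block_size / fs` seconds per block.
#'
#' @param record an `emg_record`.
#' @param block_size samples per block (>= 1).
#' @param realtime pace emission at the nominal sampling rate.
#' @return list with `next_block()`, `reset()` and `n_blocks`.
#' @export
replay_source <- function(record, block_size = 100L, realtime = FALSE) {
  stopifnot(block_size >= 1)
  n <- nrow(record$samples)
  n_blocks <- ceiling(n / block_size)
  i <- 0L
  list(
    n_blocks = n_blocks,
    reset = function() i <<- 0L,
    next_block = function() {
      if (i >= n_blocks) return(NULL)
      from <- i * block_size + 1L
      to <- min(n, (i + 1L) * block_size)
      i <<- i + 1L
      if (realtime) Sys.sleep((to - from + 1L) / record$fs)
      sample_block(record$samples[from:to, , drop = FALSE], from - 1L, record$fs)
    })
}

#' Simulated ADC quantization
#'
#' Optional uniform quantization to `2^bits` levels over a symmetric
#' full-scale range, emulating a 10-bit acquisition ADC. Values outside the
#' range are clipped.
#'
#' @param x numeric vector or matrix of samples.
#' @param bits ADC resolution (default 10).
#' @param full_scale full-scale amplitude: the representable range is
#'   `[-full_scale, +full_scale]`.
#' @return quantized samples, same shape as `x`.
#' @export
quantize <- function(x, bits = 10L, full_scale = 1) {
  levels <- 2^bits - 1
  q <- round((pmin(pmax(x, -full_scale), full_scale) + full_scale) /
               (2 * full_scale) * levels)
  q / levels * 2 * full_scale - full_scale
}
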