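#' Design the EMG bandpass filter
#'
#' Designs a causal Butterworth IIR bandpass filter for surface EMG. The
#' order argument is the order of the final bandpass (the underlying low/high
#' prototype has `order/2` poles), so the conventional "order 6, 20--500 Hz"
#' EMG front end is `design_bandpass(1000, 20, 500, 6)`.
#'
#' At `fs = 1000` Hz an upper cutoff of 500 Hz sits exactly on Nyquist, which
#' no digital bandpass can realise; the upper edge is clamped to
#' `0.99 * fs / 2` and the clamp recorded in the returned spec (`$warnings`)
#' rather than raising an error.
#'
#' @param fs sampling rate in Hz.
#' @param low lower cutoff in Hz (must be > 0).
#' @param high upper cutoff in Hz; clamped below Nyquist if necessary.
#' @param order final bandpass order (even, >= 2). Default 6.
#' @return an object of class `emg_filter` holding the normalised
#'   coefficients `b` (numerator) and `a` (denominator, `a[1] == 1`), the
#'   design parameters, and any clamp warnings.
#' @export
design_bandpass <- function(fs, low, high, order = 6L) {
  stopifnot(fs > 0, low > 0, order >= 2)
  if (order %% 2 != 0) stop("bandpass order must be even")
  nyq <- fs / 2
  warnings <- character()
  if (high >= nyq) {
    clamped <- 0.99 * nyq
    warnings <- sprintf("upper cutoff %g Hz >= Nyquist (%g Hz); clamped to %g Hz",
                        high, nyq, clamped)
    high <- clamped
  }
  if (low >= high) stop("empty passband: low cutoff >= (clamped) high cutoff")
  bt <- signal::butter(order / 2, c(low, high) / nyq, type = "pass")
  spec <- new_filter_spec("bandpass", b = bt$b, a = bt$a, fs = fs,
                          params = list(low = low, high = high, order = order),
                          warnings = warnings)
  stopifnot(filter_is_stable(spec))
  spec
}

#' Design a power-line notch filter
#'
#' Second-order (biquad) notch with unit gain away from the stop band and a
#' zero exactly on the notch frequency, the standard constrained-pole-zero
#' design. Used to remove 50 Hz mains interference from EMG.
#'
#' @param fs sampling rate in Hz.
#' @param center notch frequency in Hz, inside (0, fs/2).
#' @param q quality factor; the -3 dB stop bandwidth is `center / q`.
#' @return an `emg_filter` spec.
#' @export
design_notch <- function(fs, center, q = 30) {
  stopifnot(fs > 0, q > 0)
  if (center <= 0 || center >= fs / 2)
    stop("notch center must lie strictly inside (0, fs/2)")
  w0 <- 2 * pi * center / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  spec <- new_filter_spec("notch", b = b, a = a, fs = fs,
                          params = list(center = center, q = q),
                          warnings = character())
  stopifnot(filter_is_stable(spec))
  spec
}

new_filter_spec <- function(kind, b, a, fs, params, warnings) {
  b <- as.numeric(b); a <- as.numeric(a)
  if (length(b) == 0 || length(a) == 0) stop("empty coefficient arrays")
  if (a[1] != 1) { b <- b / a[1]; a <- a / a[1] }
  structure(list(kind = kind, b = b, a = a, fs = fs, params = params,
                 warnings = warnings),
            class = "emg_filter")
}

#' @export
print.emg_filter <- function(x, ...) {
  cat(sprintf("<emg_filter %s fs=%g Hz, %d/%d coefficients>\n",
              x$kind, x$fs, length(x$b), length(x$a)))
  invisible(x)
}

#' Filter stability check
#'
#' A designed IIR filter is stable iff all poles (roots of the denominator
#' polynomial) lie strictly inside the unit circle.
#'
#' @param spec an `emg_filter`.
#' @return logical scalar.
#' @export
filter_is_stable <- function(spec) {
  a <- spec$a
  if (length(a) == 1) return(TRUE)
  all(Mod(polyroot(rev(a))) < 1)
}

#' Evaluate the filter's frequency response magnitude
#'
#' Computes |H(e^{i 2 pi f / fs})| from the designed coefficients.
#'
#' @param spec an `emg_filter`.
#' @param freq frequencies in Hz.
#' @return numeric vector of gain magnitudes (1 = unity).
#' @export
filter_gain <- function(spec, freq) {
  w <- 2 * pi * freq / spec$fs
  z <- exp(-1i * w)
  num <- vapply(z, function(zz) sum(spec$b * zz^(seq_along(spec$b) - 1)), complex(1))
  den <- vapply(z, function(zz) sum(spec$a * zz^(seq_along(spec$a) - 1)), complex(1))
  Mod(num / den)
}

#' Create a fresh (zero) streaming filter state
#'
#' Holds one delay line per channel, sized to the coefficient arrays. A zero
#' state corresponds to a cold start: the filter behaves as if all past
#' inputs and outputs were zero.
#'
#' @param spec an `emg_filter`.
#' @param n_channels number of independent channels.
#' @return an `emg_filter_state` object.
#' @export
filter_state <- function(spec, n_channels = 2L) {
  nz <- max(length(spec$b), length(spec$a)) - 1L
  structure(list(z = replicate(n_channels, numeric(nz), simplify = FALSE),
                 n_channels = as.integer(n_channels)),
            class = "emg_filter_state")
}

#' Apply an IIR filter to a block of samples, carrying state
#'
#' Runs the causal difference equation
#' `y[k] = b0 x[k] + ... + bM x[k-M] - a1 y[k-1] - ... - aN y[k-N]`
#' over a block, starting from (and updating) the per-channel delay lines, so
#' that a signal processed in arbitrary block partitions is identical to one
#' batch call.
#'
#' @param spec an `emg_filter`.
#' @param state an `emg_filter_state` from [filter_state()], or `NULL` for a
#'   cold start.
#' @param x numeric matrix (samples x channels) or vector (one channel).
#' @return list with `y` (filtered, same shape as `x`) and `state` (updated).
#' @export
apply_filter <- function(spec, state, x) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(as.numeric(x), ncol = 1) else as.matrix(x)
  nch <- ncol(xm)
  if (is.null(state)) state <- filter_state(spec, nch)
  if (state$n_channels != nch)
    stop(sprintf("state has %d channels but block has %d", state$n_channels, nch))
  ym <- xm
  for (ch in seq_len(nch)) {
    res <- .iir_df2t(spec$b, spec$a, xm[, ch], state$z[[ch]])
    ym[, ch] <- res$y
    state$z[[ch]] <- res$state
  }
  list(y = if (vec) drop(ym) else ym, state = state)
}

#' Batch-filter a whole signal from a cold start
#'
#' Convenience wrapper over [apply_filter()] with a zero initial state.
#'
#' @inheritParams apply_filter
#' @return filtered signal, same shape as `x`.
#' @export
filter_signal <- function(spec, x) apply_filter(spec, NULL, x)$y

#' Standard EMG preprocessing chain
#'
#' Applies the mains notch followed by the bandpass (order configurable) to
#' all channels of a record, from a cold start. The notch-first ordering
#' mirrors hardware front ends where line rejection precedes the acquisition
#' bandpass; swap `specs` to change it.
#'
#' @param record an `emg_record`.
#' @param specs list of `emg_filter` objects, applied in order. Default:
#'   50 Hz notch then 20--500 Hz order-6 bandpass at the record's rate.
#' @return the record with filtered samples.
#' @export
preprocess_record <- function(record, specs = default_filters(record$fs)) {
  x <- record$samples
  for (spec in specs) x <- filter_signal(spec, x)
  record$samples <- x
  record
}

#' @rdname preprocess_record
#' @param fs sampling rate in Hz.
#' @export
default_filters <- function(fs) {
  list(notch = design_notch(fs, 50, 30),
       bandpass = design_bandpass(fs, 20, 500, 6))
}

#' Serialize / restore a filter spec as JSON
#'
#' Coefficients are written at full double precision so a restored spec
#' filters bit-identically.
#'
#' @param spec an `emg_filter`.
#' @param path file path.
#' @return `read_filter_json()` returns the restored `emg_filter`.
#' @export
write_filter_json <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_filter_json
#' @export
read_filter_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_filter_spec(obj$kind, obj$b, obj$a, obj$fs, as.list(obj$params),
                  as.character(obj$warnings))
}
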