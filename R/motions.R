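#' Motion label vocabulary
#'
#' The four hand motions recognised by the pipeline plus the `TRANSITION`
#' label used for samples between movement repetitions. The motion order is
#' fixed (`GRASP < FLEXION < EXTENSION < RELAX`) and is used everywhere a
#' deterministic tie-break over classes is needed; the integer motion codes
#' exchanged with the motor-control stage follow the same order (0 to 3).
#'
#' @return `motion_levels()` returns the four motion labels in canonical
#'   order; `label_levels()` additionally includes `"TRANSITION"`.
#' @export
motion_levels <- function() c("GRASP", "FLEXION", "EXTENSION", "RELAX")

#' @rdname motion_levels
#' @export
label_levels <- function() c(motion_levels(), "TRANSITION")

#' Convert between motion labels and integer motion codes
#'
#' Codes are the fixed 0-based encoding used on the classifier-to-motor
#' mailbox: GRASP = 0, FLEXION = 1, EXTENSION = 2, RELAX = 3.
#'
#' @param label character vector of motion labels.
#' @param code integer vector of motion codes in 0..3.
#' @return `motion_code()` returns integer codes; `motion_label()` returns
#'   character labels.
#' @export
motion_code <- function(label) {
  i <- match(label, motion_levels())
  if (anyNA(i)) stop("unknown motion label: ", paste(label[is.na(i)], collapse = ", "))
  i - 1L
}

#' @rdname motion_code
#' @export
motion_label <- function(code) {
  code <- as.integer(code)
  if (any(code < 0L | code > 3L)) stop("motion code must be in 0..3")
  motion_levels()[code + 1L]
}

#' Derive a reproducible sub-seed
#'
#' Maps a master seed and an index to a deterministic sub-seed inside the
#' 32-bit range, so independent streams (one per subject, per replicate, ...)
#' can be seeded from a single experiment seed.
#'
#' @param seed master seed (integer-valued).
#' @param index stream index (integer-valued).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}
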