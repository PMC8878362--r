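#' Subject-specific EMG generation parameters
#'
#' Describes one simulated subject: per-channel resting (relax) noise
#' amplitude, a per-motion per-channel activation gain applied on top of that
#' baseline, the carrier noise band, the 50 Hz line-interference amplitude
#' and the contraction envelope rise/fall time. Channel 1 is the wrist
#' flexor, channel 2 the wrist extensor; grasp elevates both channels with
#' the flexor dominant, flexion is flexor-dominant, extension
#' extensor-dominant, and relax is baseline only.
#'
#' @param subject_id character id.
#' @param baseline length-2 positive numeric: relax-level RMS amplitude
#'   (signal units) for flexor and extensor.
#' @param gains 4 x 2 numeric matrix of activation gains, rows in
#'   [motion_levels()] order, columns (flexor, extensor); dimensionless
#'   multipliers, >= 1 on active channels, == 1 for RELAX.
#' @param carrier_band length-2 numeric (Hz), strictly inside (20, 500):
#'   band of the band-limited noise carrier.
#' @param line_amplitude nonnegative amplitude of the 50 Hz interference
#'   sinusoid (signal units).
#' @param ramp_ms envelope rise/fall time in milliseconds.
#' @return an object of class `subject_params`.
#' @export
subject_params <- function(subject_id = "S01",
                           baseline = c(flexor = 0.05, extensor = 0.05),
                           gains = default_gains(),
                           carrier_band = c(25, 445),
                           line_amplitude = 0.005,
                           ramp_ms = 200) {
  gains <- as.matrix(gains)
  stopifnot(length(baseline) == 2, all(baseline >= 0),
            all(dim(gains) == c(4, 2)), all(gains >= 1),
            length(carrier_band) == 2,
            carrier_band[1] > 20, carrier_band[2] < 500,
            carrier_band[1] < carrier_band[2],
            line_amplitude >= 0, ramp_ms >= 0)
  dimnames(gains) <- list(motion_levels(), c("flexor", "extensor"))
  # dominant channel of each non-relax motion must be genuinely active
  dominant <- c(GRASP = "flexor", FLEXION = "flexor", EXTENSION = "extensor")
  for (m in names(dominant)) {
    if (gains[m, dominant[[m]]] <= 1)
      stop("activation gain for the dominant channel of ", m, " must exceed 1")
  }
  structure(list(subject_id = as.character(subject_id),
                 baseline = stats::setNames(as.numeric(baseline), c("flexor", "extensor")),
                 gains = gains, carrier_band = as.numeric(carrier_band),
                 line_amplitude = as.numeric(line_amplitude),
                 ramp_ms = as.numeric(ramp_ms)),
            class = "subject_params")
}

#' @rdname subject_params
#' @export
default_gains <- function() {
  matrix(c(4.0, 2.5,   # GRASP: both elevated, flexor dominant
           5.0, 1.2,   # FLEXION: flexor strongly dominant
           1.2, 5.0,   # EXTENSION: extensor strongly dominant
           1.0, 1.0),  # RELAX: baseline only
         ncol = 2, byrow = TRUE,
         dimnames = list(motion_levels(), c("flexor", "extensor")))
}

#' Draw a random subject's generation parameters
#'
#' Inter-subject variability is modelled as independent log-normal
#' multiplicative jitter: baselines and line amplitude are scaled by
#' `exp(variability * z)`, and each activation gain `g` becomes
#' `1 + (g - 1) * exp(variability * z)` with `z ~ N(0, 1)`, which preserves
#' the gain-above-baseline invariant for any variability. With
#' `variability = 0` every subject equals the defaults.
#'
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param variability nonnegative dispersion of the log-normal jitter.
#' @param subject_id id to stamp on the parameters.
#' @return a `subject_params` object.
#' @export
sample_subject <- function(seed, variability = 0.3, subject_id = "S01") {
  if (variability < 0) stop("variability must be nonnegative")
  set.seed(as.integer(seed))
  base <- subject_params(subject_id = subject_id)
  jitter <- function(n) exp(variability * stats::rnorm(n))
  baseline <- base$baseline * jitter(2)
  gains <- base$gains
  gains[] <- 1 + (gains - 1) * jitter(length(gains))
  line_amp <- base$line_amplitude * jitter(1)
  subject_params(subject_id = subject_id, baseline = baseline, gains = gains,
                 carrier_band = base$carrier_band, line_amplitude = line_amp,
                 ramp_ms = base$ramp_ms)
}

#' Recording session protocol
#'
#' The measurement protocol: an ordered motion sequence, repeated a number of
#' times, each repetition held for a fixed duration and separated by a rest
#' transition whose duration is drawn uniformly from a range (2--3 s by
#' default, the usual anti-fatigue delay between repetitions).
#'
#' @param motions ordered character vector of motion labels for one cycle.
#' @param reps repetitions of the full motion sequence (>= 1).
#' @param hold_s hold duration of each repetition in seconds (> 0).
#' @param transition_s length-2 numeric: uniform range (seconds) of the rest
#'   transition inserted before every hold.
#' @param fs sampling rate in Hz.
#' @return an object of class `session_protocol`.
#' @export
session_protocol <- function(motions = motion_levels(), reps = 10,
                             hold_s = 2, transition_s = c(2, 3), fs = 1000) {
  stopifnot(length(motions) >= 1, all(motions %in% motion_levels()),
            reps >= 1, hold_s > 0, length(transition_s) == 2,
            transition_s[1] <= transition_s[2], transition_s[1] >= 0, fs > 0)
  structure(list(motions = as.character(motions), reps = as.integer(reps),
                 hold_s = as.numeric(hold_s),
                 transition_s = as.numeric(transition_s), fs = as.numeric(fs)),
            class = "session_protocol")
}

#' Labeled two-channel EMG recording
#'
#' Container for one session: a samples matrix (rows = samples, columns =
#' flexor, extensor channels), one label per sample (a motion or
#' `TRANSITION`), the sampling rate and the subject id.
#'
#' @param subject_id character id.
#' @param fs sampling rate (Hz).
#' @param samples numeric matrix, n x 2.
#' @param labels character vector of length n over [label_levels()].
#' @return an object of class `emg_record`.
#' @export
emg_record <- function(subject_id, fs, samples, labels) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 2) stop("emg_record requires exactly 2 channels")
  if (nrow(samples) != length(labels))
    stop("labels length must match sample count")
  if (nrow(samples) == 0) stop("no samples")
  bad <- !(labels %in% label_levels())
  if (any(bad))
    stop("unknown label(s): ", paste(unique(labels[bad]), collapse = ", "))
  if (fs <= 0) stop("sampling rate must be positive")
  colnames(samples) <- c("flexor", "extensor")
  structure(list(subject_id = as.character(subject_id), fs = as.numeric(fs),
                 samples = samples, labels = as.character(labels)),
            class = "emg_record")
}

#' @export
print.emg_record <- function(x, ...) {
  cat(sprintf("<emg_record %s: %d samples x 2 ch @ %g Hz>\n",
              x$subject_id, nrow(x$samples), x$fs))
  print(table(x$labels))
  invisible(x)
}

# segment plan: data.frame(label, n) of alternating TRANSITION / hold runs
plan_segments <- function(protocol) {
  holds <- rep(protocol$motions, times = protocol$reps)
  n_hold <- round(protocol$hold_s * protocol$fs)
  trans_s <- stats::runif(length(holds), protocol$transition_s[1],
                          protocol$transition_s[2])
  n_trans <- pmax(1L, round(trans_s * protocol$fs))
  data.frame(label = as.vector(rbind("TRANSITION", holds)),
             n = as.vector(rbind(n_trans, rep(n_hold, length(holds)))),
             stringsAsFactors = FALSE)
}

#' Generate one labeled synthetic EMG session
#'
#' The signal model per channel is amplitude-modulated band-limited noise
#' plus mains interference:
#' zero-mean Gaussian white noise is bandpass-filtered to the subject's
#' carrier band and scaled to unit RMS, then multiplied by a motion-dependent
#' amplitude envelope (baseline x activation gain during holds, decaying to
#' baseline across each rest transition with linear ramps of the subject's
#' rise/fall time), and a 50 Hz sinusoid of the configured amplitude is
#' added. Every sample is labeled with its motion or `TRANSITION`.
#'
#' @param params a `subject_params`.
#' @param protocol a `session_protocol`.
#' @param seed integer seed; output is deterministic given the seed.
#' @return an `emg_record`.
#' @export
generate_session <- function(params, protocol, seed = 1L) {
  stopifnot(inherits(params, "subject_params"),
            inherits(protocol, "session_protocol"))
  set.seed(as.integer(seed))
  fs <- protocol$fs
  segs <- plan_segments(protocol)
  n <- sum(segs$n)
  labels <- rep(segs$label, times = segs$n)

  carrier_spec <- design_bandpass(fs, params$carrier_band[1],
                                  params$carrier_band[2], 4L)
  ramp_n <- max(1L, round(params$ramp_ms * fs / 1000))
  t <- (seq_len(n) - 1) / fs

  samples <- matrix(0, n, 2)
  for (ch in 1:2) {
    carrier <- filter_signal(carrier_spec, stats::rnorm(n))
    carrier <- carrier / stats::sd(carrier)
    env <- envelope_from_segments(segs, params$baseline[ch],
                                  params$gains[, ch], ramp_n)
    phase <- stats::runif(1, 0, 2 * pi)
    samples[, ch] <- env * carrier +
      params$line_amplitude * sin(2 * pi * 50 * t + phase)
  }
  emg_record(params$subject_id, fs, samples, labels)
}

# Piecewise envelope: target amplitude during holds; transitions fall to
# baseline then rise to the next hold's amplitude with linear ramps.
envelope_from_segments <- function(segs, baseline, gains, ramp_n) {
  amp_of <- function(label) if (label == "TRANSITION") baseline else baseline * gains[[label]]
  env <- numeric(sum(segs$n))
  pos <- 0L
  prev_amp <- baseline
  for (i in seq_len(nrow(segs))) {
    L <- segs$n[i]
    idx <- pos + seq_len(L)
    if (segs$label[i] != "TRANSITION") {
      amp <- amp_of(segs$label[i])
      env[idx] <- amp
      prev_amp <- amp
    } else {
      next_amp <- if (i < nrow(segs)) amp_of(segs$label[i + 1]) else baseline
      seg <- rep(baseline, L)
      f <- min(ramp_n, L)
      seg[seq_len(f)] <- seq(prev_amp, baseline, length.out = f)
      r <- min(ramp_n, L)
      seg[L - r + seq_len(r)] <- seq(seg[L - r + 1], next_amp, length.out = r)
      env[idx] <- seg
      prev_amp <- baseline
    }
    pos <- pos + L
  }
  env
}

#' Generate a cohort of synthetic subjects
#'
#' One session per subject under a shared protocol. Subject parameter draws
#' and session noise use seeds derived deterministically from the master
#' seed, so a cohort is reproducible and subjects are mutually independent.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param protocol a `session_protocol` shared by all subjects.
#' @param variability inter-subject parameter dispersion; see
#'   [sample_subject()].
#' @param seed master integer seed.
#' @return list of `emg_record`, one per subject, ids `S01`, `S02`, ...
#' @export
generate_cohort <- function(n_subjects = 10, protocol = session_protocol(),
                            variability = 0.3, seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  lapply(seq_len(n_subjects), function(i) {
    id <- sprintf("S%02d", i)
    params <- sample_subject(derive_seed(seed, i), variability, subject_id = id)
    generate_session(params, protocol, seed = derive_seed(seed, 100000 + i))
  })
}
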