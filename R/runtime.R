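#' Latest-value mailbox
#'
#' Single-slot, non-blocking exchange between pipeline stages: writers
#' overwrite the slot and bump a monotonically increasing version counter;
#' readers always get a value — the pre-defined initial value before any
#' write — and can detect staleness by comparing versions. This formalises
#' the shared-global-variable handoff of an embedded multi-thread controller
#' in a testable way.
#'
#' @param initial the pre-defined value returned before any write.
#' @return a `mailbox` (environment-backed; `mb_post()`/`mb_read()` operate
#'   in place).
#' @export
mailbox <- function(initial = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- initial
  e$version <- 0L
  class(e) <- "mailbox"
  e
}

#' @rdname mailbox
#' @param mb a `mailbox`.
#' @param value value to publish.
#' @return `mb_post()` returns the new version (invisibly); `mb_read()`
#'   returns `list(value, version)`.
#' @export
mb_post <- function(mb, value) {
  mb$value <- value
  mb$version <- mb$version + 1L
  invisible(mb$version)
}

#' @rdname mailbox
#' @export
mb_read <- function(mb) list(value = mb$value, version = mb$version)

#' Simulated prosthetic actuator state
#'
#' Five finger linear-actuator strokes (clamped to 0--20 mm) and one wrist
#' servo angle (clamped to its configured range).
#'
#' @param strokes_mm length-5 numeric, finger strokes in mm.
#' @param wrist_deg wrist angle in degrees.
#' @param wrist_range length-2 allowed wrist angle range.
#' @return an `actuator_state`.
#' @export
actuator_state <- function(strokes_mm = rep(0, 5), wrist_deg = 0,
                           wrist_range = c(-60, 60)) {
  stopifnot(length(strokes_mm) == 5, length(wrist_range) == 2)
  structure(list(
    strokes_mm = pmin(pmax(as.numeric(strokes_mm), 0), 20),
    wrist_deg = min(max(wrist_deg, wrist_range[1]), wrist_range[2]),
    wrist_range = as.numeric(wrist_range)),
    class = "actuator_state")
}

#' Map a motion code to an actuator command
#'
#' GRASP drives all five finger actuators to full 20 mm stroke, RELAX opens
#' them to 0 mm; FLEXION/EXTENSION move the wrist servo to its configured
#' flexed/extended setpoint and leave the fingers unchanged. The mapping is
#' idempotent: repeating a code leaves the state fixed.
#'
#' @param code motion code (0--3 integer) or motion label.
#' @param current current `actuator_state`.
#' @param flexed_deg,extended_deg wrist setpoints for FLEXION / EXTENSION.
#' @return the new `actuator_state`.
#' @export
motion_to_actuation <- function(code, current = actuator_state(),
                                flexed_deg = -45, extended_deg = 45) {
  label <- if (is.character(code)) code else motion_label(code)
  switch(label,
    GRASP = actuator_state(rep(20, 5), current$wrist_deg, current$wrist_range),
    RELAX = actuator_state(rep(0, 5), current$wrist_deg, current$wrist_range),
    FLEXION = actuator_state(current$strokes_mm, flexed_deg, current$wrist_range),
    EXTENSION = actuator_state(current$strokes_mm, extended_deg,
                               current$wrist_range),
    stop("unknown motion: ", label))
}

#' Offline (sequential) classification of a whole record
#'
#' The reference path the staged pipeline must reproduce: batch-filter the
#' record from a cold start, segment into disjoint windows, extract features
#' and predict one motion code per window.
#'
#' @param record an `emg_record` (raw).
#' @param specs list of filter specs, applied in order (see
#'   [preprocess_record()]).
#' @param features a [feature_spec()] matching the model.
#' @param model a fitted `emg_model`.
#' @param window_ms analysis window length.
#' @return integer vector of motion codes, one per complete window.
#' @export
classify_record <- function(record, specs, features, model,
                            window_ms = 100) {
  filtered <- preprocess_record(record, specs)
  windows <- segment_record(filtered, window_ms = window_ms)
  if (length(windows) == 0) return(integer(0))
  x <- do.call(rbind, lapply(windows, extract_features,
                             spec = feature_spec(features)))
  motion_code(predict(model, x))
}

#' Run the four-stage online pipeline
#'
#' Emulates the embedded controller's four concurrent stages — data
#' acquisition (read + causal filtering), feature extraction (one feature
#' vector per completed window), classification (one motion code per new
#' vector), motor control (actuate the latest code) — communicating through
#' latest-value [mailbox()]es, with every publish recorded in an event log.
#'
#' In `"replay"` mode the stages are lock-step scheduled per acquired block,
#' so the emitted code sequence is deterministic and identical to the
#' sequential [classify_record()] path. In `"realtime"` mode the source
#' paces emission at the nominal sampling rate and the classifier consumes
#' only the freshest window at each wake-up; skipped windows are counted,
#' not hidden.
#'
#' @param source a [replay_source()] (or any object with `next_block()`).
#' @param specs list of filter specs applied by the acquisition stage.
#' @param features a [feature_spec()] matching the model.
#' @param model fitted `emg_model`.
#' @param window_ms analysis window length (ms).
#' @param mode `"replay"` (lock-step, deterministic) or `"realtime"`.
#' @return list with `codes` (integer motion codes in emission order),
#'   `events` (data.frame: stage, mailbox, version, time_s, info),
#'   `actuator` (final `actuator_state`), `n_windows`, `dropped`.
#' @export
run_pipeline <- function(source, specs, features, model, window_ms = 100,
                         mode = c("replay", "realtime")) {
  mode <- match.arg(mode)
  features <- feature_spec(features)
  t0 <- proc.time()[["elapsed"]]
  now <- function() proc.time()[["elapsed"]] - t0

  events <- new.env(parent = emptyenv())
  events$rows <- vector("list", 256L)
  events$n <- 0L
  log_event <- function(stage, box, version, info = "") {
    events$n <- events$n + 1L
    if (events$n > length(events$rows))
      events$rows <- c(events$rows, vector("list", length(events$rows)))
    events$rows[[events$n]] <- data.frame(
      stage = stage, mailbox = box, version = version, time_s = now(),
      info = info, stringsAsFactors = FALSE)
  }

  mb_feature <- mailbox()
  mb_code <- mailbox(motion_code("RELAX"))  # pre-defined safe initial code
  log_event("classifier", "code", 0L, "pre-defined RELAX")

  first <- source$next_block()
  if (is.null(first)) stop("source produced no data")
  fs <- first$fs
  w <- round(window_ms * fs / 1000)
  block_n <- nrow(first$samples)
  buf <- ring_buffer(max(4L * max(w, block_n), w + block_n), 2L)
  states <- lapply(specs, function(s) NULL)
  next_start <- 0L       # 0-based start of the next analysis window
  codes <- integer(0)
  actuator <- motion_to_actuation(mb_read(mb_code)$value)
  seen_code_version <- -1L
  seen_feat_version <- 0L
  dropped <- 0L
  failing <- NULL

  acquire <- function(block) {
    x <- block$samples
    for (k in seq_along(specs)) {
      res <- apply_filter(specs[[k]], states[[k]], x)
      x <- res$y
      states[[k]] <<- res$state
    }
    buf <<- rb_push(buf, x)
    log_event("acquisition", "samples", as.integer(buf$total),
              sprintf("block@%d", block$start))
  }

  extract_ready <- function() {
    while (buf$total >= next_start + w) {
      avail <- buf$total - next_start
      win <- rb_snapshot(buf, avail)[seq_len(w), , drop = FALSE]
      fv <- extract_features(list(samples = win, n = w), spec = features)
      v <- mb_post(mb_feature, list(x = fv, start = next_start))
      log_event("features", "feature", v, sprintf("window@%d", next_start))
      next_start <<- next_start + w
      if (mode == "replay") classify()   # consume every window
    }
    if (mode == "realtime") classify()   # consume only the freshest
  }

  classify <- function() {
    f <- mb_read(mb_feature)
    if (f$version == 0L || f$version == seen_feat_version) return(invisible())
    if (f$version > seen_feat_version + 1L)
      dropped <<- dropped + (f$version - seen_feat_version - 1L)
    seen_feat_version <<- f$version
    code <- motion_code(predict(model, matrix(f$value$x, nrow = 1)))
    v <- mb_post(mb_code, code)
    codes <<- c(codes, code)
    log_event("classifier", "code", v, motion_label(code))
    actuate()
  }

  actuate <- function() {
    c0 <- mb_read(mb_code)
    if (c0$version <= seen_code_version) return(invisible())
    seen_code_version <<- c0$version
    actuator <<- motion_to_actuation(c0$value, actuator)
    log_event("motor", "actuator", c0$version,
              sprintf("strokes=%gmm wrist=%gdeg",
                      actuator$strokes_mm[1], actuator$wrist_deg))
  }

  block <- first
  repeat {
    res <- tryCatch({
      acquire(block)
      extract_ready()
      NULL
    }, error = function(e) e)
    if (!is.null(res)) {
      failing <- res
      break
    }
    block <- source$next_block()
    if (is.null(block)) break            # orderly stop on source exhaustion
  }
  if (!is.null(failing))
    stop("pipeline stage failed: ", conditionMessage(failing))

  list(codes = codes,
       events = do.call(rbind, events$rows[seq_len(events$n)]),
       actuator = actuator, n_windows = seen_feat_version, dropped = dropped)
}

#' Per-window end-to-end latency from an event log
#'
#' Measures, for each analysis window, the time from the feature publish
#' (window completion) to the corresponding actuation command, and flags the
#' run against the real-time budget: one window period (100 ms by default),
#' the ceiling beyond which a prosthesis user perceives delay. Values are
#' hardware-dependent and reported for context.
#'
#' @param events the event log data.frame from [run_pipeline()].
#' @param budget_ms real-time budget per window.
#' @return list with `latency_ms` (per window), `mean_ms`, `max_ms`,
#'   `within_budget` (logical).
#' @export
measure_latency <- function(events, budget_ms = 100) {
  if (is.null(events) || nrow(events) == 0) stop("empty event log")
  feat <- events[events$stage == "features", ]
  act <- events[events$stage == "motor", ]
  if (nrow(feat) == 0 || nrow(act) == 0) stop("log lacks feature/motor events")
  k <- min(nrow(feat), nrow(act))
  lat <- (act$time_s[seq_len(k)] - feat$time_s[seq_len(k)]) * 1000
  list(latency_ms = lat, mean_ms = mean(lat), max_ms = max(lat),
       within_budget = all(lat < budget_ms))
}

#' Write an event log as JSON lines
#'
#' One event per line: stage, mailbox, version, timestamp, payload summary.
#'
#' @param events event log data.frame.
#' @param path output path.
#' @export
write_event_log <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events)))
    writeLines(jsonlite::toJSON(as.list(events[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  invisible(path)
}
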