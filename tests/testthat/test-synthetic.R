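test_that("subject sampling is deterministic and respects zero variability", {
  expect_equal(sample_subject(1, 0), sample_subject(2, 0))
  expect_identical(sample_subject(1, 0.3), sample_subject(1, 0.3))
  expect_false(identical(sample_subject(1, 0.3), sample_subject(2, 0.3)))
  p <- sample_subject(1, 0.3)
  expect_gt(p$gains["GRASP", "flexor"], 1)
  expect_gt(p$gains["FLEXION", "flexor"], 1)
  expect_gt(p$gains["EXTENSION", "extensor"], 1)
  expect_error(sample_subject(1, -0.1), "nonnegative")
})

test_that("invalid subject parameters are rejected", {
  bad_gain <- default_gains(); bad_gain["GRASP", "flexor"] <- 1
  expect_error(subject_params(gains = bad_gain), "dominant")
  expect_error(subject_params(carrier_band = c(10, 450)))
  expect_error(subject_params(line_amplitude = -1))
})

test_that("a session realises the protocol's hold/transition structure", {
  proto <- session_protocol(reps = 10, hold_s = 2, fs = 1000)
  rec <- generate_session(sample_subject(1, 0.2), proto, seed = 7)
  runs <- rle(rec$labels)
  holds <- runs$lengths[runs$values != "TRANSITION"]
  expect_length(holds, 40)              # 4 motions x 10 reps
  expect_true(all(holds == 2000))       # 2 s at 1000 Hz
  expect_equal(sum(runs$lengths), nrow(rec$samples))
  trans <- runs$lengths[runs$values == "TRANSITION"]
  expect_true(all(trans >= 2000 & trans <= 3000))
})

test_that("sessions are deterministic under a fixed seed", {
  proto <- session_protocol(reps = 2, hold_s = 0.5)
  p <- sample_subject(3, 0.3)
  a <- generate_session(p, proto, seed = 11)
  b <- generate_session(p, proto, seed = 11)
  expect_identical(a, b)
  # byte-for-byte after serialization
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  write_record(a, fa); write_record(b, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("active motions elevate the dominant channel over relax", {
  rec <- short_record(seed = 2)
  flex <- abs(rec$samples[, "flexor"])
  ext <- abs(rec$samples[, "extensor"])
  expect_gt(mean(flex[rec$labels == "GRASP"]), mean(flex[rec$labels == "RELAX"]))
  expect_gt(mean(flex[rec$labels == "FLEXION"]), mean(flex[rec$labels == "RELAX"]))
  expect_gt(mean(ext[rec$labels == "EXTENSION"]), mean(ext[rec$labels == "RELAX"]))
})

test_that("zero line interference leaves no 50 Hz spike", {
  p0 <- subject_params(line_amplitude = 0)
  rec <- generate_session(p0, session_protocol(reps = 2, hold_s = 2), seed = 5)
  hold <- rec$samples[rec$labels == "RELAX", 1][1:2000]
  spec <- stats::spec.pgram(stats::ts(hold, frequency = 1000), plot = FALSE,
                            taper = 0)
  at50 <- mean(spec$spec[abs(spec$freq - 50) < 1])
  nearby <- mean(spec$spec[abs(spec$freq - 50) > 3 & abs(spec$freq - 50) < 10])
  expect_lt(at50, 5 * nearby)
})

test_that("hold-segment power is concentrated in the 20-450 Hz band", {
  rec <- generate_session(subject_params(),
                          session_protocol(reps = 1, hold_s = 5), seed = 9)
  hold <- rec$samples[rec$labels == "GRASP", 1]
  spec <- stats::spec.pgram(stats::ts(hold, frequency = 1000), plot = FALSE,
                            taper = 0)
  inband <- sum(spec$spec[spec$freq >= 20 & spec$freq <= 450])
  expect_gt(inband / sum(spec$spec), 0.9)
})

test_that("window MAV separation from relax grows with activation gain", {
  margins <- vapply(c(1.5, 3, 6), function(g) {
    gains <- default_gains(); gains["GRASP", ] <- c(g, 1 + (g - 1) / 2)
    rec <- generate_session(subject_params(gains = gains),
                            session_protocol(motions = c("GRASP", "RELAX"),
                                             reps = 3, hold_s = 1), seed = 21)
    ds <- build_dataset(rec)
    mean(ds$x[ds$label == "GRASP", "MAV_ch1"]) -
      mean(ds$x[ds$label == "RELAX", "MAV_ch1"])
  }, 0.0)
  expect_true(all(diff(margins) > 0))
})

test_that("cohorts have unique subjects and reproduce under the seed", {
  proto <- session_protocol(reps = 1, hold_s = 0.5)
  cohort <- generate_cohort(10, proto, 0.3, seed = 4)
  expect_length(cohort, 10)
  ids <- vapply(cohort, `[[`, "", "subject_id")
  expect_length(unique(ids), 10)
  expect_identical(cohort, generate_cohort(10, proto, 0.3, seed = 4))
  expect_error(generate_cohort(0, proto), ">= 1")
})

test_that("zero cohort variability yields identical subject parameters", {
  p1 <- sample_subject(101, 0, "A")
  p2 <- sample_subject(202, 0, "A")
  expect_equal(p1, p2)
})
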