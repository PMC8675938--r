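test_that("R peaks are recovered on clean synthetic ECG", {
  rec <- generate_subject(quiet_spec(30), "nonCAD", 7)
  clean <- preprocess_recording(rec)
  truth <- attr(rec, "truth")
  r_det <- (detect_r_peaks(clean$channels$ecg, clean$fs) - 1) / clean$fs
  expect_length(r_det, length(truth$r_times))
  err <- vapply(truth$r_times, function(rt) min(abs(r_det - rt)), numeric(1))
  expect_lt(max(err), 0.010)
})

test_that("beat recall stays >= 95% at 10 dB ECG SNR", {
  rec <- generate_subject(quiet_spec(60), "nonCAD", 5)
  truth <- attr(rec, "truth")
  snr_rms <- sqrt(mean(rec$channels$ecg^2)) / sqrt(10)
  set.seed(15)
  rec$channels$ecg <- rec$channels$ecg + rnorm(length(rec), 0, snr_rms)
  clean <- preprocess_recording(rec)
  r_det <- (detect_r_peaks(clean$channels$ecg, clean$fs) - 1) / clean$fs
  hits <- vapply(truth$r_times,
                 function(rt) min(abs(r_det - rt)) < 0.025, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("flat or too-short signals raise insufficient-beats errors", {
  expect_error(detect_r_peaks(rep(0, 5000), 250), "insufficient beats")
  expect_error(detect_r_peaks(rnorm(100), 250), "insufficient beats")
})

test_that("Q points sit at the waveform minimum just before each R", {
  rec <- generate_subject(quiet_spec(30), "CAD", 9)
  clean <- preprocess_recording(rec)
  truth <- attr(rec, "truth")
  r <- detect_r_peaks(clean$channels$ecg, clean$fs)
  q <- locate_q_points(clean$channels$ecg, r, clean$fs)
  offs <- (r[seq_along(q) + (length(r) - length(q))] - q) / clean$fs
  ## generator Q-R offset is 30 ms
  expect_true(all(abs(offs - 0.030) <= 0.004))
  ## a monotone rise into R puts Q at the window start
  ramp <- seq(0, 1, length.out = 200)
  expect_equal(locate_q_points(ramp, 100L, 250), 100L - 15L)
  ## R too close to the signal start drops that beat
  expect_length(locate_q_points(ramp, c(5L, 100L), 250), 1)
})

test_that("cycle segmentation is half-open and reconstructs the signal", {
  x <- rnorm(300)
  cycles <- segment_cycles(x, c(1L, 101L, 251L))
  expect_equal(lengths(cycles), c(100, 150))
  expect_equal(unlist(cycles), x[1:250])
  expect_equal(segment_cycles(x, 42L), list())
})

test_that("cycle interpolation preserves endpoints, identity, and linearity", {
  x <- rnorm(250)
  expect_equal(interpolate_cycle(x, 250), x)
  ramp <- seq(2, 9, length.out = 313)
  out <- interpolate_cycle(ramp, 250)
  expect_equal(out, seq(2, 9, length.out = 250), tolerance = 1e-12)
  ## analytic oracle: a sinusoid resampled on the same span
  u <- seq(0, 1, length.out = 313)
  s <- sin(2 * pi * 3 * u)
  out <- interpolate_cycle(s, 250)
  ref <- sin(2 * pi * 3 * seq(0, 1, length.out = 250))
  expect_lt(sqrt(mean((out - ref)^2)) / sqrt(mean(ref^2)), 0.005)
  expect_error(interpolate_cycle(1), "at least 2")
})

test_that("series grouping takes consecutive non-overlapping runs of 10", {
  cycles <- lapply(1:25, function(i) rep(i, 250))
  series <- build_series(cycles)
  expect_length(series, 2)
  expect_length(series[[1]], 2500)
  expect_equal(unique(series[[2]][1:250]), 11)   # second run starts at cycle 11
  expect_length(build_series(lapply(1:10, function(i) rep(0, 250))), 1)
  expect_error(build_series(cycles[1:9]), "insufficient cycles")
})

test_that("detected series count is bounded by the beat count", {
  rec <- generate_subject(synth_spec(duration = 45, seed = 3), "CAD", 19)
  clean <- preprocess_recording(rec)
  ann <- annotate_beats(clean)
  cycles <- segment_cycles(clean$channels$scg_x, ann$q_indices)
  n_series <- length(build_series(lapply(cycles, interpolate_cycle)))
  expect_lte(n_series * 10, length(ann$q_indices) - 1)
})
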