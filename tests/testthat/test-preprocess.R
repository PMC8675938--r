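test_that("high-pass rejects DC exactly and passes the signal band", {
  expect_lt(max(abs(highpass_zerophase(rep(3, 5000), 1000))), 3e-6)
  t <- (0:29999) / 1000
  y <- highpass_zerophase(sin(2 * pi * 10 * t), 1000)
  mid <- 10000:25000
  expect_lt(abs(max(abs(y[mid])) - 1), 0.01)
  ## zero phase: cross-correlation peak at lag 0
  cc <- ccf(y[mid], sin(2 * pi * 10 * t)[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("high-pass attenuates sub-cutoff oscillations", {
  t <- (0:59999) / 1000
  y <- highpass_zerophase(sin(2 * pi * 0.05 * t), 1000)
  expect_lt(max(abs(y[20000:40000])), 0.05)
  ## filter magnitude response at 0.05 Hz (squared by the two passes)
  sos <- scgrisk:::butter_hp_sos(5, 0.5, 1000)
  H <- 1
  z <- exp(1i * 2 * pi * 0.05 / 1000)
  for (s in sos)
    H <- H * sum(s$b * z^(0:(length(s$b) - 1))) /
      sum(s$a * z^(0:(length(s$a) - 1)))
  expect_lt(Mod(H)^2, 0.05)          # analytic response agrees with the test
})

test_that("filtering a symmetric pulse gives a symmetric output", {
  n <- 20001                          # odd length: exact mirror center
  t <- (seq_len(n) - 1) / 1000
  p <- exp(-(t - t[(n + 1) / 2])^2 / (2 * 0.05^2))
  y <- highpass_zerophase(p, 1000)
  ## symmetry is assessed away from the ends: the 0.5 Hz filter settles
  ## over a few seconds and its edge transients are not reversal-equivariant
  ## (reference zero-phase implementations show the same edge behaviour)
  interior <- 4000:(n - 4000)
  d <- abs(y - rev(y))
  expect_lt(max(d[interior]), 1e-6)
})

test_that("normalization demeans then scales to the unit interval", {
  expect_equal(normalize_signal(c(1, 3)), c(-1, 1))
  expect_equal(normalize_signal(c(0, 0, 0)), c(0, 0, 0))
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(100, mean = runif(1, -5, 5), sd = runif(1, 0.1, 3))
    out <- normalize_signal(x)
    expect_lt(abs(mean(out)), 1e-12)
    expect_equal(max(abs(out)), 1)
  }
  expect_error(normalize_signal(numeric(0)), "empty")
})

test_that("decimation keeps passband content and suppresses aliasing", {
  t <- (0:9999) / 1000
  d <- downsample_signal(sin(2 * pi * 5 * t), 1000, 250)
  expect_length(d, 2500)
  ref <- sin(2 * pi * 5 * (seq_along(d) - 1) / 250)
  expect_lt(sqrt(mean((d - ref)^2)) / sqrt(mean(ref^2)), 0.02)
  ## near the new Nyquist the anti-aliasing filter must bite
  d120 <- downsample_signal(sin(2 * pi * 120 * t), 1000, 250)
  expect_lt(sqrt(mean(d120^2)) / sqrt(0.5), 0.5)
  expect_error(downsample_signal(rnorm(100), 1000, 300), "integer multiple")
  expect_length(downsample_signal(rnorm(4000), 1000, 250), 1000)
})

test_that("recording preprocessing removes wander and meets the output contract", {
  sp <- synth_spec(duration = 60, noise_sd = 0.02, wander_amp = 0.5,
                   wander_freq = 0.2, seed = 6)
  rec <- generate_subject(sp, "nonCAD", 13)
  band_power <- function(x, fs, f0, hw = 0.05) {
    s <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) / length(x) * fs
    sum(s[f >= f0 - hw & f <= f0 + hw])
  }
  pre <- band_power(rec$channels$scg_x, 1000, 0.2)
  clean <- preprocess_recording(rec)
  expect_equal(clean$fs, 250)
  expect_length(clean$channels$scg_x, 15000)
  ## wander band reduced by far more than the overall rescaling could explain
  post <- band_power(clean$channels$scg_x, 250, 0.2)
  scale2 <- max(abs(clean$channels$scg_x))^2 / max(abs(rec$channels$scg_x))^2
  expect_lt(post / (pre * scale2), 0.01)
  for (ch in scgrisk:::CHANNELS) {
    x <- clean$channels[[ch]]
    expect_lt(abs(mean(x)), 1e-9)
    expect_equal(max(abs(x)), 1)
  }
})

test_that("preprocessing an already-clean recording is near idempotent", {
  rec <- generate_subject(synth_spec(duration = 40, seed = 9), "CAD", 17)
  c1 <- preprocess_recording(rec)
  c2 <- preprocess_recording(c1)
  for (ch in c("scg_x", "gcg_y")) {
    a <- c1$channels[[ch]]; b <- c2$channels[[ch]]
    interior <- 1000:(length(a) - 1000)   # exclude filter settling regions
    d <- sqrt(mean((b - a)[interior]^2))
    expect_lt(d / sqrt(mean(a[interior]^2)), 0.02)
  }
})

test_that("too-short sequences are rejected by the zero-phase filter", {
  expect_error(highpass_zerophase(rnorm(5), 1000), "too short")
})
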