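test_that("SST of a pure tone concentrates magnitude at its frequency", {
  s <- sin(2 * pi * 10 * (0:2499) / 250)
  pl <- sst_transform(s, 250, return_cwt = TRUE)
  expect_equal(dim(pl$values), c(178L, 2500L))
  inband <- pl$freq_axis >= 8 & pl$freq_axis <= 12
  expect_gte(sum(pl$values[inband, ]) / sum(pl$values), 0.7)
  ## synchrosqueezing is strictly sharper than the raw scalogram
  expect_gt(sum(pl$values[inband, ]) / sum(pl$values),
            sum(pl$cwt_mag[inband, ]) / sum(pl$cwt_mag))
})

test_that("SST separates two tones into disjoint frequency bands", {
  s <- sin(2 * pi * 5 * (0:2499) / 250) + sin(2 * pi * 20 * (0:2499) / 250)
  pl <- sst_transform(s, 250)
  b5 <- pl$freq_axis >= 4 & pl$freq_axis <= 6
  b20 <- pl$freq_axis >= 18 & pl$freq_axis <= 22
  mid <- pl$freq_axis > 8 & pl$freq_axis < 15
  tot <- sum(pl$values)
  expect_gt(sum(pl$values[b5, ]) / tot, 0.3)
  expect_gt(sum(pl$values[b20, ]) / tot, 0.3)
  expect_lt(sum(pl$values[mid, ]) / tot, 0.05)
})

test_that("degenerate SST inputs are handled", {
  z <- sst_transform(rep(0, 2500), 250)
  expect_true(all(z$values == 0))
  expect_error(sst_transform(c(rep(0, 2499), NA), 250), "non-finite")
})

test_that("splitting truncates above 40 Hz and standardizes to 150 rows", {
  s <- sin(2 * pi * 10 * (0:2499) / 250)
  per_cycle <- split_and_truncate(sst_transform(s, 250))
  expect_length(per_cycle, 10)
  for (m in per_cycle) expect_equal(dim(m), c(150L, 250L))
  fa <- attr(per_cycle[[1]], "freq_axis")
  expect_true(all(fa <= 40) && length(fa) == 150)
  ## a 45 Hz tone leaves almost nothing below the cut
  s45 <- sin(2 * pi * 45 * (0:2499) / 250)
  pl45 <- sst_transform(s45, 250)
  kept <- sum(vapply(split_and_truncate(pl45), sum, numeric(1)))
  expect_lt(kept / sum(pl45$values), 0.02)
  bad <- sst_transform(s, 250)
  bad$values <- bad$values[, 1:2400]
  expect_error(split_and_truncate(bad), "columns")
})

test_that("an impulse's energy stays in its own cycle matrix", {
  x <- rep(0, 2500); x[701] <- 1            # cycle index 3 (samples 501-750)
  per_cycle <- split_and_truncate(sst_transform(x, 250))
  e <- vapply(per_cycle, sum, numeric(1))
  expect_equal(which.max(e), 3L)
  expect_gt(e[3] / sum(e), 0.6)
})

test_that("image reduction equals brute-force block means with rescaling", {
  set.seed(11)
  m <- matrix(runif(150 * 250), 150)
  img <- reduce_to_image(m)
  expect_equal(dim(img), c(30L, 25L))
  brute <- matrix(0, 30, 25)
  for (i in 1:30) for (j in 1:25)
    brute[i, j] <- mean(m[((i - 1) * 5 + 1):(i * 5),
                          ((j - 1) * 10 + 1):(j * 10)])
  brute <- (brute - min(brute)) / (max(brute) - min(brute))
  expect_equal(img, brute, tolerance = 1e-12)
  expect_equal(range(img), c(0, 1))
  ## degenerate all-constant plane maps to zeros
  expect_true(all(reduce_to_image(matrix(1, 150, 250)) == 0))
  expect_error(reduce_to_image(matrix(0, 149, 250)), "multiples")
})

test_that("reduction commutes with positive rescaling of the plane", {
  set.seed(12)
  m <- matrix(rexp(150 * 250), 150)
  expect_equal(reduce_to_image(m), reduce_to_image(7.3 * m), tolerance = 1e-12)
})

test_that("flattening is row-major and invertible", {
  img <- matrix(0, 30, 25)
  img[3, 4] <- 1                            # zero-based (2, 3)
  v <- flatten_image(img)
  expect_length(v, 750)
  expect_equal(which(v == 1), 2 * 25 + 3 + 1)
  set.seed(13)
  img2 <- matrix(runif(750), 30, 25)
  expect_equal(matrix(flatten_image(img2), 30, 25, byrow = TRUE), img2)
})

test_that("the feature shape chain is exact from series to vector", {
  rec <- generate_subject(quiet_spec(15), "CAD", 3)
  clean <- preprocess_recording(rec)
  ann <- annotate_beats(clean)
  cycles <- segment_cycles(clean$channels$scg_y, ann$q_indices)
  interp <- lapply(cycles, interpolate_cycle)
  expect_true(all(lengths(interp) == 250))
  series <- build_series(interp)
  expect_length(series[[1]], 2500)
  per_cycle <- split_and_truncate(sst_transform(series[[1]], 250))
  expect_equal(dim(per_cycle[[1]]), c(150L, 250L))
  img <- reduce_to_image(per_cycle[[1]])
  expect_equal(dim(img), c(30L, 25L))
  expect_length(flatten_image(img), 750)
})

test_that("feature extraction yields ten vectors per series for six channels", {
  rec <- generate_subject(quiet_spec(32), "nonCAD", 5)   # 31 beats -> 3 series
  feats <- extract_features(preprocess_recording(rec))
  expect_setequal(names(feats$channels),
                  c("scg_x", "scg_y", "scg_z", "gcg_x", "gcg_y", "gcg_z"))
  for (ch in names(feats$channels)) {
    m <- feats$channels[[ch]]
    expect_equal(dim(m), c(30L, 750L))
    expect_true(all(m >= 0 & m <= 1))
    expect_true(all(apply(m, 1, max) == 1))
  }
})

test_that("spectral class separation lands in the expected frequency rows", {
  sp <- synth_spec(duration = 30, separation = 1, noise_sd = 0.02,
                   wander_amp = 0.1, seed = 21)
  f_cad <- extract_features(preprocess_recording(
    generate_subject(sp, "CAD", 31)))
  f_non <- extract_features(preprocess_recording(
    generate_subject(sp, "nonCAD", 32)))
  d <- abs(colMeans(f_cad$channels$scg_x) - colMeans(f_non$channels$scg_x))
  rows <- matrix(d, 30, 25, byrow = TRUE)
  top <- order(rowSums(rows), decreasing = TRUE)[1:6]
  ## discriminative atom frequencies: nonCAD 26 Hz -> rows ~18-20,
  ## CAD 16 Hz -> rows ~11-13 (row r covers ((r-1)*4/3, r*4/3] Hz)
  expect_true(any(top %in% 10:14))
  expect_true(any(top %in% 16:21))
})

test_that("feature export writes one labeled table per channel", {
  rec <- generate_subject(quiet_spec(15), "CAD", 8)
  feats <- extract_features(preprocess_recording(rec))
  dir <- file.path(tempdir(), "feat_export")
  unlink(dir, recursive = TRUE)
  paths <- write_features(feats, dir)
  expect_length(paths, 6)
  df <- read.csv(paths[1])
  expect_equal(ncol(df), 753)
  expect_equal(unique(df$label), "CAD")
  expect_equal(nrow(df), nrow(feats$channels[[1]]))
})
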