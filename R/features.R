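#' Synchrosqueezing transform of a cycle series
#'
#' Computes an analytic-Morlet continuous wavelet transform on a
#' logarithmic scale grid, estimates each coefficient's instantaneous
#' frequency from the phase transform (time derivative of the CWT divided
#' by the CWT), and reallocates coefficient magnitudes to the scale-grid
#' row nearest that frequency. The reallocation is what sharpens the
#' representation: a pure tone that the plain scalogram smears across
#' neighbouring scales collapses onto a narrow frequency band.
#'
#' @param series Numeric series (one concatenation of interpolated cycles).
#' @param fs Sampling rate in Hz.
#' @param nscales Number of scales / frequency rows.
#' @param fmin Lowest analysis frequency in Hz.
#' @param omega0 Morlet center frequency (rad), conventionally 6.
#' @param return_cwt Also return the plain CWT scalogram magnitude
#'   (used by diagnostics comparing concentration).
#' @return A list of class `tf_plane`: `values` (non-negative matrix,
#'   `nscales` rows x `length(series)` columns), `freq_axis` (Hz,
#'   increasing), `fs`; optionally `cwt_mag`.
#' @export
sst_transform <- function(series, fs = 250, nscales = 178L, fmin = 0.5,
                          omega0 = 6, return_cwt = FALSE) {
  x <- as.numeric(series)
  if (any(!is.finite(x))) stop("series contains non-finite samples")
  n <- length(x)
  fmax <- fs / 2
  freqs <- exp(seq(log(fmin), log(fmax), length.out = nscales))
  scales <- fs * omega0 / (2 * pi * freqs)   # samples

  xh <- stats::fft(x)
  xi <- 2 * pi * (seq_len(n) - 1) / n        # rad/sample
  xi[xi > pi] <- xi[xi > pi] - 2 * pi        # signed grid; analytic wavelet
                                             # keeps positive half only
  ## wavelet filter bank: rows = scales, evaluated on the FFT grid
  W <- matrix(0 + 0i, nscales, n)
  dW <- matrix(0 + 0i, nscales, n)
  pos <- xi > 0
  for (j in seq_len(nscales)) {
    psi <- numeric(n)
    psi[pos] <- exp(-0.5 * (scales[j] * xi[pos] - omega0)^2)
    W[j, ] <- stats::fft(xh * psi, inverse = TRUE) / n
    dW[j, ] <- stats::fft(xh * psi * (1i * xi * fs), inverse = TRUE) / n
  }
  absW <- Mod(W)
  mx <- max(absW)
  Ts <- matrix(0, nscales, n)
  if (mx > 0) {
    gamma <- 1e-8 * mx
    ## instantaneous frequency in Hz from the phase transform
    omega <- matrix(NA_real_, nscales, n)
    ok <- absW > gamma
    omega[ok] <- Im(dW[ok] / W[ok]) / (2 * pi)
    ## nearest log-grid row for each coefficient
    dlf <- (log(fmax) - log(fmin)) / (nscales - 1)
    bin <- matrix(NA_integer_, nscales, n)
    good <- ok & is.finite(omega) & omega > 0
    bin[good] <- as.integer(round((log(omega[good]) - log(fmin)) / dlf)) + 1L
    bin[bin < 1L | bin > nscales] <- NA_integer_
    for (j in seq_len(nscales)) {
      bj <- bin[j, ]
      sel <- which(!is.na(bj))
      if (!length(sel)) next
      pos2 <- cbind(bj[sel], sel)
      Ts[pos2] <- Ts[pos2] + absW[j, sel]
    }
  }
  out <- list(values = Ts, freq_axis = freqs, fs = fs)
  if (return_cwt) out$cwt_mag <- absW
  class(out) <- "tf_plane"
  out
}

#' @export
print.tf_plane <- function(x, ...) {
  cat(sprintf("tf_plane: %d freq rows (%.2f-%.1f Hz) x %d time samples\n",
              nrow(x$values), min(x$freq_axis), max(x$freq_axis),
              ncol(x$values)))
  invisible(x)
}

## Linear re-gridding matrix mapping magnitudes sampled at src_f (any
## monotone grid) onto dst_f; zero outside the source support.
regrid_matrix <- function(src_f, dst_f) {
  R <- matrix(0, length(dst_f), length(src_f))
  for (i in seq_along(dst_f)) {
    f <- dst_f[i]
    if (f < src_f[1] || f > src_f[length(src_f)]) next
    j <- findInterval(f, src_f, all.inside = TRUE)
    w <- (f - src_f[j]) / (src_f[j + 1] - src_f[j])
    R[i, j] <- 1 - w
    R[i, j + 1] <- w
  }
  R
}

#' Split a time-frequency plane into per-cycle matrices and truncate
#'
#' Splits the plane at multiples of `cycle_len` columns into one matrix per
#' cycle, discards rows above `freq_max`, and standardizes the retained
#' band to exactly `n_rows` uniformly spaced frequency rows by linear
#' re-gridding (the raw row count depends on the wavelet scale grid; the
#' downstream feature shape must not).
#'
#' @param plane A `tf_plane` from [sst_transform()].
#' @param cycle_len Columns per cycle.
#' @param freq_max Truncation frequency in Hz.
#' @param n_rows Output rows for the truncated band.
#' @return List of per-cycle matrices (`n_rows` x `cycle_len`), each with a
#'   `freq_axis` attribute.
#' @export
split_and_truncate <- function(plane, cycle_len = 250L, freq_max = 40,
                               n_rows = 150L) {
  stopifnot(inherits(plane, "tf_plane"))
  n <- ncol(plane$values)
  if (n %% cycle_len != 0)
    stop("plane has ", n, " columns; must be a multiple of ", cycle_len)
  dst_f <- (seq_len(n_rows) - 0.5) * freq_max / n_rows
  R <- regrid_matrix(plane$freq_axis, dst_f)
  reg <- R %*% plane$values
  n_cyc <- n %/% cycle_len
  lapply(seq_len(n_cyc), function(kk) {
    m <- reg[, ((kk - 1L) * cycle_len + 1L):(kk * cycle_len), drop = FALSE]
    attr(m, "freq_axis") <- dst_f
    m
  })
}

#' Reduce a per-cycle plane to an intensity image
#'
#' Non-overlapping block means over `f_win` frequency rows by `t_win` time
#' columns, then min-max rescaling of the reduced matrix to `[0, 1]`
#' (0 black, 1 white). An all-constant matrix maps to all zeros.
#'
#' @param cycle_plane Numeric matrix whose dimensions are multiples of the
#'   window sizes (150 x 250 by default).
#' @param f_win,t_win Block sizes over rows and columns.
#' @return Matrix of dimension `nrow/f_win` x `ncol/t_win` with values in
#'   `[0, 1]`.
#' @export
reduce_to_image <- function(cycle_plane, f_win = 5L, t_win = 10L) {
  nr <- nrow(cycle_plane); nc <- ncol(cycle_plane)
  if (nr %% f_win != 0 || nc %% t_win != 0)
    stop("plane dimensions (", nr, " x ", nc,
         ") are not multiples of the windows (", f_win, " x ", t_win, ")")
  rg <- rep(seq_len(nr %/% f_win), each = f_win)
  cg <- rep(seq_len(nc %/% t_win), each = t_win)
  bm <- rowsum(t(rowsum(cycle_plane, rg)), cg)   # (nc/t_win) x (nr/f_win)
  bm <- t(bm) / (f_win * t_win)
  dimnames(bm) <- NULL
  rng <- range(bm)
  if (rng[2] - rng[1] < .Machine$double.eps * max(abs(rng), 1))
    return(matrix(0, nrow(bm), ncol(bm)))
  (bm - rng[1]) / (rng[2] - rng[1])
}

#' Flatten an intensity image to a feature vector
#'
#' Row-major flattening: row 1 left to right, then row 2, and so on.
#'
#' @param image Numeric matrix (30 x 25 by default shapes).
#' @return Numeric vector of length `nrow * ncol`.
#' @export
flatten_image <- function(image) {
  if (!is.matrix(image)) stop("`image` must be a matrix")
  as.vector(t(image))
}

#' Extract per-cycle feature vectors from a preprocessed recording
#'
#' Full feature chain for all six SCG/GCG channels: beat annotation on the
#' ECG, Q-to-Q segmentation, linear interpolation of each cycle to
#' `cycle_len` samples, concatenation into series of `cycles_per_series`,
#' synchrosqueezing of each series, per-cycle splitting with truncation at
#' `freq_max`, block-mean reduction, intensity rescaling, and flattening.
#' Every series yields exactly `cycles_per_series` feature vectors per
#' channel; the ECG itself is excluded from the output.
#'
#' @param rec A preprocessed recording (`scg_clean` from
#'   [preprocess_recording()]).
#' @param cfg An [scg_config()].
#' @return An object of class `scg_features`: list with `subject_id`,
#'   `label`, and `channels`, a named list of numeric matrices (rows =
#'   cycles, `cycle_len * ... = 750` feature columns) with a `cycle_index`
#'   attribute.
#' @export
extract_features <- function(rec, cfg = scg_config()) {
  stopifnot(inherits(rec, "scg_recording"))
  ann <- annotate_beats(rec)
  if (length(ann$q_indices) < cfg$cycles_per_series + 1L)
    stop("insufficient cycles: ", length(ann$q_indices) - 1L, " detected, need ",
         cfg$cycles_per_series)
  nvec_len <- (cfg$n_freq_rows %/% cfg$f_win) * (cfg$cycle_len %/% cfg$t_win)
  channels <- list()
  for (ch in setdiff(CHANNELS, "ecg")) {
    cycles <- segment_cycles(rec$channels[[ch]], ann$q_indices)
    interp <- lapply(cycles, interpolate_cycle, n_out = cfg$cycle_len)
    series <- build_series(interp, cfg$cycles_per_series)
    feats <- matrix(NA_real_, length(series) * cfg$cycles_per_series, nvec_len)
    ci <- 0L
    for (s in series) {
      plane <- sst_transform(s, fs = cfg$fs_target, nscales = cfg$sst_nscales,
                             fmin = cfg$sst_fmin)
      per_cycle <- split_and_truncate(plane, cfg$cycle_len, cfg$freq_max,
                                      cfg$n_freq_rows)
      for (cp in per_cycle) {
        ci <- ci + 1L
        feats[ci, ] <- flatten_image(reduce_to_image(cp, cfg$f_win, cfg$t_win))
      }
    }
    attr(feats, "cycle_index") <- seq_len(nrow(feats))
    channels[[ch]] <- feats
  }
  structure(list(subject_id = rec$subject_id, label = rec$label,
                 channels = channels),
            class = "scg_features")
}

#' @export
print.scg_features <- function(x, ...) {
  n <- nrow(x$channels[[1]])
  cat(sprintf("scg_features '%s' (%s): %d cycles x %d features x %d channels\n",
              x$subject_id, x$label, n, ncol(x$channels[[1]]),
              length(x$channels)))
  invisible(x)
}

#' Export feature vectors to CSV tables
#'
#' Writes one CSV per channel: `subject_id`, `label`, `cycle_index`, then
#' the 750 feature columns (`f001`...`f750`).
#'
#' @param feats An `scg_features` object or a list of them.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_features <- function(feats, dir) {
  if (inherits(feats, "scg_features")) feats <- list(feats)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  channels <- names(feats[[1]]$channels)
  paths <- character(0)
  for (ch in channels) {
    df <- do.call(rbind, lapply(feats, function(f) {
      m <- f$channels[[ch]]
      cbind(data.frame(subject_id = f$subject_id, label = f$label,
                       cycle_index = seq_len(nrow(m)),
                       stringsAsFactors = FALSE),
            as.data.frame(m))
    }))
    names(df)[-(1:3)] <- sprintf("f%03d", seq_len(ncol(df) - 3L))
    p <- file.path(dir, paste0("features_", ch, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
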