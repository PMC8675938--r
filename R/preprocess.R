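## Zero-phase IIR filtering with reflect padding of length 3*(order+1) on
## each end: forward pass, reverse pass, padding stripped. This doubles the
## filter order's magnitude response and cancels phase, so passband signals
## come out amplitude-preserved and unshifted.
filt_zerophase <- function(b, a, x) {
  npad <- 3L * max(length(a), length(b))
  if (length(x) <= npad)
    stop("sequence too short for zero-phase filtering (need > ",
         npad, " samples)")
  ## odd (point-symmetric) reflection, as is standard for filtfilt
  pre <- 2 * x[1] - x[(npad + 1):2]
  post <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - npad)]
  xp <- c(pre, x, post)
  ## start each pass in steady state for the first padded sample: all past
  ## inputs equal to it, past outputs at DC gain — kills step transients
  dc <- sum(b) / sum(a)
  run <- function(z) as.numeric(signal::filter(b, a, z,
                                               init.x = rep(z[1], length(b) - 1),
                                               init.y = rep(z[1] * dc, length(a) - 1)))
  y <- run(xp)
  y <- rev(run(rev(y)))
  y[(npad + 1):(npad + length(x))]
}

## Butterworth high-pass as second-order sections via the bilinear
## transform. At cutoffs far below Nyquist (0.5 Hz at 1 kHz) the single
## transfer-function form loses its DC zero to coefficient roundoff —
## the denominator's DC sum is ~(1-p)^order ~ 1e-13 and amplifies it —
## so the filter must be applied as a cascade of biquads.
butter_hp_sos <- function(order, cutoff, fs) {
  wc <- tan(pi * cutoff / fs)             # prewarped analog cutoff
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # unit-cutoff LP poles
  p_hp <- wc / p_lp                        # lowpass -> highpass transform
  zd <- (1 + p_hp) / (1 - p_hp)            # bilinear: analog pole -> digital
  secs <- list()
  ## pair complex-conjugate poles into biquads; a real pole (odd order)
  ## becomes a first-order section
  used <- rep(FALSE, order)
  for (i in seq_len(order)) {
    if (used[i]) next
    if (abs(Im(zd[i])) < 1e-12) {
      z1 <- Re(zd[i])
      g <- (1 + z1) / 2                    # unit gain at Nyquist
      secs[[length(secs) + 1]] <- list(b = g * c(1, -1), a = c(1, -z1))
      used[i] <- TRUE
    } else {
      j <- which(!used & abs(zd - Conj(zd[i])) < 1e-9 & seq_len(order) != i)[1]
      s1 <- zd[i] + zd[j]; s2 <- zd[i] * zd[j]
      g <- Re((1 + s1 + s2)) / 4
      secs[[length(secs) + 1]] <- list(b = g * c(1, -2, 1),
                                       a = c(1, -Re(s1), Re(s2)))
      used[c(i, j)] <- TRUE
    }
  }
  secs
}

#' Zero-phase high-pass Butterworth filter
#'
#' Removes baseline wander with a forward-backward (zero-phase) Butterworth
#' high-pass, applied as a cascade of second-order sections for numerical
#' robustness at low cutoffs. Defaults: order 5, 0.5 Hz cutoff.
#'
#' @param x Numeric sample sequence.
#' @param fs Sampling rate in Hz.
#' @param order Filter order.
#' @param cutoff Cutoff frequency in Hz.
#' @return Filtered sequence, same length as `x`.
#' @export
highpass_zerophase <- function(x, fs, order = 5L, cutoff = 0.5) {
  stopifnot(fs > 0, cutoff > 0, cutoff < fs / 2)
  for (s in butter_hp_sos(order, cutoff, fs))
    x <- filt_zerophase(s$b, s$a, x)
  x
}

#' Demean and scale to \[-1, 1\]
#'
#' Removes the mean, then divides by the maximum absolute value of the
#' demeaned sequence. An (almost) constant sequence is returned as zeros.
#'
#' @param x Numeric sample sequence.
#' @return Normalized sequence with zero mean and max absolute value 1.
#' @export
normalize_signal <- function(x) {
  if (length(x) == 0) stop("empty sequence")
  x <- x - mean(x)
  m <- max(abs(x))
  if (m < .Machine$double.eps) return(rep(0, length(x)))
  x / m
}

#' Decimate with a Chebyshev type-I anti-aliasing filter
#'
#' Applies an order-8 Chebyshev type-I low-pass (0.05 dB ripple, cutoff
#' 0.8 x the output Nyquist) zero-phase, then keeps every
#' `fs_in/fs_out`-th sample starting from the first.
#'
#' @param x Numeric sample sequence.
#' @param fs_in Input sampling rate in Hz.
#' @param fs_out Output sampling rate in Hz; must divide `fs_in`.
#' @param order Anti-aliasing filter order.
#' @param ripple Passband ripple in dB.
#' @return Decimated sequence of length `ceiling(length(x) / factor)`.
#' @export
downsample_signal <- function(x, fs_in, fs_out = 250, order = 8L,
                              ripple = 0.05) {
  stopifnot(fs_in > 0, fs_out > 0)
  factor <- fs_in / fs_out
  if (abs(factor - round(factor)) > 1e-9)
    stop("`fs_in` must be an integer multiple of `fs_out`")
  factor <- as.integer(round(factor))
  if (factor == 1L) return(as.numeric(x))
  cf <- signal::cheby1(order, ripple, 0.8 / factor, type = "low")
  y <- filt_zerophase(cf$b, cf$a, x)
  y[seq(1, length(y), by = factor)]
}

#' Preprocess a recording
#'
#' Applies, per channel and in this order: zero-phase high-pass filtering,
#' demeaning with \[-1, 1\] normalization, and Chebyshev-I decimation to the
#' target rate. After decimation each channel is re-demeaned and rescaled so
#' the output contract (zero mean, max absolute value 1) holds exactly at
#' the output rate. The ECG passes through the identical chain so its
#' Q-point timing stays aligned with the motion channels.
#'
#' @param rec An [scg_recording()].
#' @param cfg An [scg_config()].
#' @return An `scg_recording` at `cfg$fs_target` Hz with class attribute
#'   `"scg_clean"` prepended.
#' @export
preprocess_recording <- function(rec, cfg = scg_config()) {
  stopifnot(inherits(rec, "scg_recording"))
  clean <- lapply(rec$channels, function(x) {
    y <- highpass_zerophase(x, rec$fs, cfg$filter_order, cfg$filter_cutoff)
    y <- normalize_signal(y)
    y <- downsample_signal(y, rec$fs, cfg$fs_target,
                           cfg$cheby_order, cfg$cheby_ripple)
    normalize_signal(y)
  })
  out <- scg_recording(clean, fs = cfg$fs_target, subject_id = rec$subject_id,
                       label = rec$label, site = rec$site)
  attr(out, "truth") <- attr(rec, "truth")
  class(out) <- c("scg_clean", class(out))
  out
}
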