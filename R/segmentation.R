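#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Classic QRS detector: 5-15 Hz band-pass, five-point derivative, squaring,
#' 150 ms moving-window integration, then dual adaptive thresholds on the
#' integrated signal with a 200 ms refractory period and RR-interval
#' search-back at half threshold when an expected beat is missed. Each
#' detection is refined to the local ECG maximum within +/- 50 ms.
#'
#' @param ecg Numeric ECG sequence.
#' @param fs Sampling rate in Hz (200-1000).
#' @return Integer vector of R-peak sample indices (1-based), strictly
#'   increasing.
#' @export
detect_r_peaks <- function(ecg, fs) {
  stopifnot(fs >= 200, fs <= 1000)
  n <- length(ecg)
  if (n < fs) stop("insufficient beats: signal shorter than 1 s")

  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  bp <- filt_zerophase(bf$b, bf$a, ecg)
  ## five-point derivative (Pan-Tompkins kernel), then squaring
  der <- stats::filter(bp, c(2, 1, 0, -1, -2) / 8, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  w <- max(1L, round(0.15 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0

  ## candidate peaks: local maxima of the integrated signal that dominate
  ## their +/- 100 ms neighbourhood (suppresses noise riblets on the apex)
  refractory <- round(0.2 * fs)
  is_peak <- c(FALSE, diff(sign(diff(mwi))) < 0, FALSE)
  w2 <- round(0.1 * fs)
  cand <- which(is_peak)
  cand <- cand[vapply(cand, function(p)
    mwi[p] >= max(mwi[max(1, p - w2):min(n, p + w2)]), logical(1))]
  if (length(cand) == 0) stop("insufficient beats: no peaks found")

  ## adaptive dual thresholds (running estimates of signal and noise peaks)
  spki <- max(mwi[seq_len(min(n, 2 * fs))]) * 0.5
  npki <- mean(mwi[seq_len(min(n, 2 * fs))]) * 0.5
  thr1 <- function() npki + 0.25 * (spki - npki)
  beats <- integer(0)
  noise_cand <- integer(0)
  rr_avg <- fs  # running RR estimate, init 1 s
  last <- -refractory
  for (p in cand) {
    if (p - last < refractory) next
    if (mwi[p] > thr1()) {
      spki <- 0.125 * mwi[p] + 0.875 * spki
      if (length(beats)) rr_avg <- 0.875 * rr_avg + 0.125 * (p - last)
      beats <- c(beats, p)
      last <- p
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
      noise_cand <- c(noise_cand, p)
      ## search-back: no beat within 1.66 x the running RR estimate
      if (length(beats) && p - last > 1.66 * rr_avg) {
        sb <- noise_cand[noise_cand > last + refractory &
                           mwi[noise_cand] > 0.5 * thr1()]
        if (length(sb)) {
          pk <- sb[which.max(mwi[sb])]
          spki <- 0.25 * mwi[pk] + 0.75 * spki
          beats <- sort(c(beats, pk))
          rr_avg <- 0.875 * rr_avg + 0.125 * (pk - last)
          last <- max(beats)
          noise_cand <- integer(0)
        }
      }
    }
  }
  if (length(beats) < 2) stop("insufficient beats: fewer than 2 detections")

  ## refine to the local raw-ECG maximum within +/- 50 ms
  hw <- as.integer(round(0.05 * fs))
  r <- vapply(as.integer(beats), function(p) {
    lo <- max(1L, p - hw); hi <- min(n, p + hw)
    lo + which.max(ecg[lo:hi]) - 1L
  }, integer(1))
  r <- sort(unique(r))
  r[c(TRUE, diff(r) > refractory)]
}

#' Locate ECG Q points
#'
#' The Q point of each beat is the minimum of the ECG in the 60 ms window
#' ending at the R peak. Beats whose window would leave the start of the
#' signal are dropped.
#'
#' @param ecg Numeric ECG sequence.
#' @param r_indices R-peak sample indices from [detect_r_peaks()].
#' @param fs Sampling rate in Hz.
#' @return Integer vector of Q sample indices, one per surviving beat.
#' @export
locate_q_points <- function(ecg, r_indices, fs) {
  w <- as.integer(round(0.06 * fs))
  q <- vapply(as.integer(r_indices), function(r) {
    lo <- r - w
    if (lo < 1) return(NA_integer_)
    win <- ecg[lo:(r - 1L)]
    lo + which.min(win) - 1L
  }, integer(1))
  q[!is.na(q)]
}

#' Annotate beats on a preprocessed recording
#'
#' Runs [detect_r_peaks()] and [locate_q_points()] on the ECG channel and
#' applies physiologic gating: beats implying an inter-beat interval outside
#' 0.3-2.0 s are rejected, guarding the interpolator against missed or
#' false detections.
#'
#' @param rec A preprocessed recording (`scg_clean`).
#' @return A list of class `beat_annotations` with integer `q_indices` and
#'   `r_indices` at the recording's sampling rate.
#' @export
annotate_beats <- function(rec) {
  fs <- rec$fs
  r <- detect_r_peaks(rec$channels$ecg, fs)
  q <- locate_q_points(rec$channels$ecg, r, fs)
  ## physiologic gating on Q-to-Q intervals
  if (length(q) >= 2) {
    keep <- c(TRUE, diff(q) >= 0.3 * fs)
    q <- q[keep]
    long <- which(diff(q) > 2.0 * fs)
    if (length(long)) q <- q[seq_len(min(long))]  # stop at first dropout
  }
  r <- r[vapply(r, function(ri) any(q < ri & q >= ri - round(0.06 * fs)),
                logical(1))]
  structure(list(q_indices = q, r_indices = r, fs = fs),
            class = "beat_annotations")
}

#' @export
print.beat_annotations <- function(x, ...) {
  cat(sprintf("beat_annotations: %d Q points at %g Hz (median RR %.3f s)\n",
              length(x$q_indices), x$fs,
              stats::median(diff(x$q_indices)) / x$fs))
  invisible(x)
}

#' Cut a channel into cardiac cycles
#'
#' Cycle `k` spans the half-open index range `[q_k, q_{k+1})`, so the
#' concatenation of all cycles reconstructs the signal between the first
#' and last Q point exactly.
#'
#' @param x Numeric sample sequence.
#' @param q_indices Q-point sample indices (1-based).
#' @return A list of numeric cycles (possibly empty).
#' @export
segment_cycles <- function(x, q_indices) {
  if (length(q_indices) < 2) return(list())
  lapply(seq_len(length(q_indices) - 1L), function(k)
    x[q_indices[k]:(q_indices[k + 1L] - 1L)])
}

#' Interpolate a cycle to a fixed length
#'
#' Linear interpolation onto `n_out` equally spaced points spanning the
#' cycle's first to last sample position inclusive; endpoints are preserved
#' exactly.
#'
#' @param cycle Numeric cycle of length >= 2.
#' @param n_out Output length.
#' @return Numeric vector of length `n_out`.
#' @export
interpolate_cycle <- function(cycle, n_out = 250L) {
  if (length(cycle) < 2) stop("cycle must have at least 2 samples")
  if (length(cycle) == n_out) return(as.numeric(cycle))
  stats::approx(x = seq(0, 1, length.out = length(cycle)), y = cycle,
                xout = seq(0, 1, length.out = n_out))$y
}

#' Concatenate interpolated cycles into fixed-length series
#'
#' Groups consecutive interpolated cycles into non-overlapping runs of
#' `per_series` and concatenates each run; a trailing remainder shorter
#' than one run is discarded.
#'
#' @param cycles List of equal-length interpolated cycles.
#' @param per_series Cycles per series.
#' @return A list of numeric series, each of length
#'   `per_series * length(cycles[[1]])`.
#' @export
build_series <- function(cycles, per_series = 10L) {
  n <- length(cycles)
  if (n < per_series)
    stop("insufficient cycles: need at least ", per_series, ", got ", n)
  n_series <- n %/% per_series
  lapply(seq_len(n_series), function(s) {
    unlist(cycles[((s - 1L) * per_series + 1L):(s * per_series)],
           use.names = FALSE)
  })
}
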