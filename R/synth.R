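#' Synthetic cohort specification
#'
#' Describes a two-class synthetic cohort with the statistical structure the
#' pipeline assumes: quasi-periodic cardiac cycles with heart-rate
#' variability, a sharp QRS-like ECG complex per cycle at a known Q-R
#' offset, and SCG/GCG channels built from Gabor atoms (Gaussian-windowed
#' sinusoids) repeated every cycle, plus low-frequency baseline wander and
#' white sensor noise.
#'
#' Class separation is spectral and confined to the analysis band: in the
#' CAD class one atom per channel moves down in center frequency by
#' `10 * separation` Hz and gains `40 * separation` percent amplitude. All
#' atom frequencies stay below 40 Hz, so the class difference lives entirely
#' inside the band the time-frequency features retain, and baseline wander
#' stays strictly below the 0.5 Hz high-pass cutoff so preprocessing can
#' remove it.
#'
#' Inter-beat intervals are i.i.d. Gaussian (mean `60/hr_bpm` s, standard
#' deviation `hr_sd_bpm/hr_bpm` of the mean) truncated at three standard
#' deviations — the simplest heart-rate-variability model that exercises the
#' cycle-length interpolation stage.
#'
#' @param n_per_class Subjects per class.
#' @param duration Recording length in seconds.
#' @param fs Sampling rate in Hz.
#' @param hr_bpm,hr_sd_bpm Heart-rate mean and standard deviation in beats
#'   per minute.
#' @param separation Spectral class-separation strength in `[0, 1]`;
#'   0 makes the classes identically distributed.
#' @param noise_sd White-noise standard deviation as a fraction of template
#'   amplitude.
#' @param wander_amp,wander_freq Baseline-wander amplitude (same units as
#'   the signal) and frequency in Hz; the frequency must stay below 0.5 Hz.
#' @param amp_jitter_sd Per-cycle multiplicative amplitude jitter SD.
#' @param seed Integer seed; together with the spec it fully determines the
#'   cohort.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_per_class = 10L,
                       duration = 60,
                       fs = 1000,
                       hr_bpm = 70,
                       hr_sd_bpm = 5,
                       separation = 1,
                       noise_sd = 0.05,
                       wander_amp = 0.3,
                       wander_freq = 0.2,
                       amp_jitter_sd = 0.1,
                       seed = 1L) {
  stopifnot(n_per_class >= 1, duration > 0, fs > 0, hr_bpm > 0,
            hr_sd_bpm >= 0, separation >= 0, separation <= 1,
            noise_sd >= 0, wander_amp >= 0, amp_jitter_sd >= 0)
  if (wander_freq >= 0.5)
    stop("`wander_freq` must stay below the 0.5 Hz high-pass cutoff")
  structure(list(n_per_class = as.integer(n_per_class), duration = duration,
                 fs = fs, hr_bpm = hr_bpm, hr_sd_bpm = hr_sd_bpm,
                 separation = separation, noise_sd = noise_sd,
                 wander_amp = wander_amp, wander_freq = wander_freq,
                 amp_jitter_sd = amp_jitter_sd, seed = as.integer(seed)),
            class = "synth_spec")
}

## Per-channel Gabor atom banks: u = position within the cycle (fraction of
## the inter-beat interval), f in Hz, sigma in seconds, a = amplitude.
## The second atom of every channel is the class-discriminative one.
synth_atoms <- function(channel, separation, cad) {
  base <- switch(channel,
    scg_x = list(u = c(0.10, 0.32, 0.62), f = c(14, 26, 9),  a = c(1.0, 0.6, 0.4)),
    scg_y = list(u = c(0.12, 0.35, 0.60), f = c(12, 28, 8),  a = c(1.0, 0.6, 0.4)),
    scg_z = list(u = c(0.09, 0.30, 0.58), f = c(16, 24, 10), a = c(1.0, 0.6, 0.4)),
    gcg_x = list(u = c(0.11, 0.34, 0.64), f = c(10, 22, 7),  a = c(1.0, 0.6, 0.4)),
    gcg_y = list(u = c(0.13, 0.36, 0.61), f = c(11, 25, 6),  a = c(1.0, 0.6, 0.4)),
    gcg_z = list(u = c(0.10, 0.33, 0.63), f = c(13, 27, 8),  a = c(1.0, 0.6, 0.4)),
    stop("unknown channel: ", channel))
  base$sigma <- c(0.040, 0.040, 0.060)
  if (cad) {
    base$f[2] <- base$f[2] - 10 * separation
    base$a[2] <- base$a[2] * (1 + 0.4 * separation)
  }
  base
}

## ECG cycle template evaluated at absolute time t (seconds) relative to the
## cycle's Q onset. Gaussian Q dip, dominant R peak 30 ms after Q, S dip and
## a broad T wave. The template minimum sits at the Q dip, giving known
## ground-truth Q times for segmentation tests.
Q_R_OFFSET <- 0.030

ecg_cycle <- function(t, ibi) {
  g <- function(t0, sigma) exp(-(t - t0)^2 / (2 * sigma^2))
  -0.25 * g(0, 0.005) +
    1.00 * g(Q_R_OFFSET, 0.008) -
    0.20 * g(Q_R_OFFSET + 0.025, 0.006) +
    0.25 * g(Q_R_OFFSET + 0.30 * ibi, 0.05 * ibi)
}

scg_cycle <- function(t, ibi, atoms, amp) {
  y <- 0
  for (j in seq_along(atoms$u)) {
    t0 <- atoms$u[j] * ibi
    y <- y + atoms$a[j] * exp(-(t - t0)^2 / (2 * atoms$sigma[j]^2)) *
      cos(2 * pi * atoms$f[j] * (t - t0))
  }
  amp * y
}

#' Generate one synthetic subject
#'
#' Builds a seven-channel recording from a [synth_spec()]. Beat onset (Q)
#' times are drawn once and shared across channels; each SCG/GCG channel is
#' its class template repeated per cycle with multiplicative amplitude
#' jitter, plus sinusoidal baseline wander and white noise. Ground-truth
#' beat times are attached as `attr(rec, "truth")` (a list with `q_times`
#' and `r_times` in seconds) for validation against detectors.
#'
#' @param spec A [synth_spec()].
#' @param class_label `"CAD"` or `"nonCAD"`.
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Identifier stored in the recording.
#' @return An [scg_recording()] with a `truth` attribute.
#' @export
generate_subject <- function(spec, class_label = c("nonCAD", "CAD"),
                             subject_seed = 1L, subject_id = NULL) {
  class_label <- match.arg(class_label)
  stopifnot(inherits(spec, "synth_spec"))
  cad <- class_label == "CAD"
  if (is.null(subject_id))
    subject_id <- sprintf("synth_%s_%d", class_label, subject_seed)
  set.seed(subject_seed)

  mean_ibi <- 60 / spec$hr_bpm
  sd_ibi <- mean_ibi * spec$hr_sd_bpm / spec$hr_bpm
  if (floor((spec$duration - 0.5) / mean_ibi) + 1 < 12)
    stop("`duration` too short for at least 12 cardiac cycles")

  n_beats <- ceiling(spec$duration / max(mean_ibi - 3 * sd_ibi, 0.3)) + 2
  ibis <- stats::rnorm(n_beats, mean_ibi, sd_ibi)
  if (sd_ibi > 0)
    ibis <- pmin(pmax(ibis, mean_ibi - 3 * sd_ibi), mean_ibi + 3 * sd_ibi)
  q_times <- 0.2 + cumsum(c(0, ibis))
  keep <- q_times <= spec$duration - 0.3
  q_times <- q_times[keep]
  ibis <- diff(c(q_times, q_times[length(q_times)] + mean_ibi))

  n <- round(spec$duration * spec$fs)
  tt <- (seq_len(n) - 1) / spec$fs
  jitter <- 1 + stats::rnorm(length(q_times), 0, spec$amp_jitter_sd)
  jitter <- pmin(pmax(jitter, 0.5), 1.5)

  per_cycle <- function(fun) {
    y <- numeric(n)
    for (k in seq_along(q_times)) {
      ## evaluate the template on a window spanning this cycle (plus margin)
      lo <- max(1L, floor(q_times[k] * spec$fs) - round(0.05 * spec$fs))
      hi <- min(n, ceiling((q_times[k] + ibis[k]) * spec$fs) + round(0.05 * spec$fs))
      idx <- lo:hi
      y[idx] <- y[idx] + fun(tt[idx] - q_times[k], ibis[k], k)
    }
    y
  }

  channels <- list(ecg = per_cycle(function(t, ibi, k) ecg_cycle(t, ibi)))
  for (ch in CHANNELS[-1]) {
    atoms <- synth_atoms(ch, spec$separation, cad)
    y <- per_cycle(function(t, ibi, k) scg_cycle(t, ibi, atoms, jitter[k]))
    phase <- stats::runif(1, 0, 2 * pi)
    y <- y + spec$wander_amp * sin(2 * pi * spec$wander_freq * tt + phase)
    y <- y + stats::rnorm(n, 0, spec$noise_sd)
    channels[[ch]] <- y
  }
  channels$ecg <- channels$ecg +
    spec$wander_amp * 0.3 * sin(2 * pi * spec$wander_freq * tt) +
    stats::rnorm(n, 0, spec$noise_sd * 0.3)

  rec <- scg_recording(channels, fs = spec$fs, subject_id = subject_id,
                       label = class_label)
  attr(rec, "truth") <- list(q_times = q_times, r_times = q_times + Q_R_OFFSET)
  rec
}

#' Generate a balanced labeled cohort
#'
#' Produces `2 * n_per_class` recordings with per-subject seeds derived
#' deterministically from `spec$seed`, so the same spec always yields the
#' same cohort and no two subjects are identical.
#'
#' @param spec A [synth_spec()].
#' @return A list of [scg_recording()] objects (CAD and nonCAD interleaved).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (spec$n_per_class < 2)
    stop("need at least 2 subjects per class")
  set.seed(spec$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2 * spec$n_per_class)
  labels <- rep(c("CAD", "nonCAD"), each = spec$n_per_class)
  ids <- sprintf("S%02d_%s", seq_along(labels), labels)
  lapply(seq_along(labels), function(i)
    generate_subject(spec, labels[i], subject_seed = seeds[i],
                     subject_id = ids[i]))
}
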