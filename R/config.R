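#' Pipeline run configuration
#'
#' Collects every tunable constant of the pipeline in one flat object.
#' Defaults are the reference protocol: order-5 zero-phase Butterworth
#' high-pass at 0.5 Hz, decimation to 250 Hz through an order-8 Chebyshev-I
#' anti-aliasing filter, 250-sample interpolated cycles, series of 10
#' concatenated cycles, synchrosqueezing analysis truncated at 40 Hz with the
#' sub-40 Hz band standardized to 150 rows, block averaging with a 5-row
#' frequency window and a 10-column time window, 100 training epochs with an
#' 80/20 train/validation split, and a 0.5 decision threshold on the fused
#' predicted risk.
#'
#' @param filter_order High-pass Butterworth order.
#' @param filter_cutoff High-pass cutoff in Hz.
#' @param fs_target Sampling rate in Hz after decimation.
#' @param cheby_order Order of the Chebyshev type-I anti-aliasing filter.
#' @param cheby_ripple Passband ripple of the anti-aliasing filter in dB.
#' @param cycle_len Samples per interpolated cardiac cycle.
#' @param cycles_per_series Cycles concatenated into one analysis series.
#' @param freq_max Upper frequency bound in Hz kept after truncation.
#' @param n_freq_rows Rows the truncated (<= `freq_max`) band is re-gridded to.
#' @param sst_nscales Number of wavelet scales (rows of the raw SST plane).
#' @param sst_fmin Lowest analysis frequency in Hz of the wavelet scale grid.
#' @param f_win,t_win Block-averaging window sizes over frequency rows and
#'   time columns respectively.
#' @param cnn A [cnn_spec()] describing the per-channel classifier.
#' @param epochs Training epochs per channel model.
#' @param val_frac Fraction of training subjects assigned to the inner
#'   validation split.
#' @param threshold Decision threshold on predicted risk.
#' @param seed Integer seed controlling all randomized stages.
#' @return An object of class `scg_config` (a named list).
#' @export
scg_config <- function(filter_order = 5L,
                       filter_cutoff = 0.5,
                       fs_target = 250,
                       cheby_order = 8L,
                       cheby_ripple = 0.05,
                       cycle_len = 250L,
                       cycles_per_series = 10L,
                       freq_max = 40,
                       n_freq_rows = 150L,
                       sst_nscales = 178L,
                       sst_fmin = 0.5,
                       f_win = 5L,
                       t_win = 10L,
                       cnn = cnn_spec(),
                       epochs = 100L,
                       val_frac = 0.2,
                       threshold = 0.5,
                       seed = 1L) {
  stopifnot(filter_order >= 1, filter_cutoff > 0, fs_target > 0,
            cycle_len >= 2, cycles_per_series >= 1, freq_max > 0,
            n_freq_rows >= 1, sst_nscales >= 2, sst_fmin > 0,
            f_win >= 1, t_win >= 1, epochs >= 1,
            val_frac > 0, val_frac < 1, threshold > 0, threshold < 1)
  cfg <- list(filter_order = as.integer(filter_order),
              filter_cutoff = filter_cutoff,
              fs_target = fs_target,
              cheby_order = as.integer(cheby_order),
              cheby_ripple = cheby_ripple,
              cycle_len = as.integer(cycle_len),
              cycles_per_series = as.integer(cycles_per_series),
              freq_max = freq_max,
              n_freq_rows = as.integer(n_freq_rows),
              sst_nscales = as.integer(sst_nscales),
              sst_fmin = sst_fmin,
              f_win = as.integer(f_win),
              t_win = as.integer(t_win),
              cnn = cnn,
              epochs = as.integer(epochs),
              val_frac = val_frac,
              threshold = threshold,
              seed = as.integer(seed))
  class(cfg) <- "scg_config"
  cfg
}

#' @export
print.scg_config <- function(x, ...) {
  cat("scgrisk run configuration\n")
  cat(sprintf("  high-pass: Butterworth order %d, %.2f Hz (zero-phase)\n",
              x$filter_order, x$filter_cutoff))
  cat(sprintf("  decimation: Chebyshev-I order %d -> %g Hz\n",
              x$cheby_order, x$fs_target))
  cat(sprintf("  cycles: %d samples x %d per series; SST %d scales, <= %g Hz -> %d rows\n",
              x$cycle_len, x$cycles_per_series, x$sst_nscales,
              x$freq_max, x$n_freq_rows))
  cat(sprintf("  reduction windows: %d (freq) x %d (time)\n", x$f_win, x$t_win))
  cat(sprintf("  training: %d epochs, %.0f%% validation, threshold %.2f, seed %d\n",
              x$epochs, 100 * x$val_frac, x$threshold, x$seed))
  invisible(x)
}

#' Write / read a run configuration
#'
#' Serialized as a flat JSON object; the CNN sub-spec is stored under the
#' `cnn` key. `read_config` restores defaults for any field absent from the
#' file, so old config files stay readable.
#'
#' @param cfg An `scg_config`.
#' @param path File path.
#' @return `read_config` returns an `scg_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "scg_config"))
  flat <- unclass(cfg)
  flat$cnn <- unclass(flat$cnn)
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cnn_args <- raw$cnn
  raw$cnn <- NULL
  args <- raw[intersect(names(raw), names(formals(scg_config)))]
  if (!is.null(cnn_args)) {
    args$cnn <- do.call(cnn_spec,
                        cnn_args[intersect(names(cnn_args), names(formals(cnn_spec)))])
  }
  do.call(scg_config, args)
}
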