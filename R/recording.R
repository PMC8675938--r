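#' @keywords internal
CHANNELS <- c("ecg", "scg_x", "scg_y", "scg_z", "gcg_x", "gcg_y", "gcg_z")

#' Multi-channel cardiomechanical recording
#'
#' Container for one subject's time-synchronized recording: one ECG channel,
#' three seismocardiogram (SCG, linear acceleration) axes and three
#' gyrocardiogram (GCG, angular velocity) axes, all at a single sampling
#' rate. Channels are stored in the canonical order
#' `ecg, scg_x, scg_y, scg_z, gcg_x, gcg_y, gcg_z` regardless of input order.
#'
#' @param channels Named list of equal-length numeric vectors; names must
#'   cover all seven canonical channels.
#' @param fs Sampling rate in Hz.
#' @param subject_id Subject identifier.
#' @param label One of `"CAD"`, `"nonCAD"`, `"unknown"`.
#' @param site Optional acquisition-site string.
#' @return An object of class `scg_recording`.
#' @export
scg_recording <- function(channels, fs, subject_id = "anon",
                          label = c("unknown", "CAD", "nonCAD"),
                          site = NULL) {
  label <- match.arg(label)
  if (!is.list(channels) || is.null(names(channels)))
    stop("`channels` must be a named list of numeric vectors")
  missing <- setdiff(CHANNELS, names(channels))
  if (length(missing))
    stop("missing channel(s): ", paste(missing, collapse = ", "))
  channels <- channels[CHANNELS]
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("all channels must have the same length")
  if (lens[1] == 0L)
    stop("channels must be non-empty")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar")
  channels <- lapply(channels, as.numeric)
  structure(list(subject_id = as.character(subject_id),
                 fs = as.numeric(fs),
                 channels = channels,
                 label = label,
                 site = site),
            class = "scg_recording")
}

#' @export
print.scg_recording <- function(x, ...) {
  n <- length(x$channels$ecg)
  cat(sprintf("scg_recording '%s': 7 channels x %d samples (%.1f s at %g Hz), label %s\n",
              x$subject_id, n, n / x$fs, x$fs, x$label))
  invisible(x)
}

#' @export
length.scg_recording <- function(x) length(x$channels$ecg)

#' Duration of a recording in seconds
#' @param rec An `scg_recording`.
#' @return Seconds of signal.
#' @export
rec_duration <- function(rec) length(rec$channels$ecg) / rec$fs

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

write_sidecar <- function(rec, path) {
  meta <- list(subject_id = rec$subject_id, fs = rec$fs, label = rec$label)
  if (!is.null(rec$site)) meta$site <- rec$site
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write a recording to disk
#'
#' Three interchange formats are supported. `csv`: one header row with the
#' canonical channel names and one sample per row, full double precision.
#' `wfdb`: a PhysioBank-style record — text `.hea` header plus 16-bit
#' little-endian interleaved `.dat`, per-channel gain chosen to span the
#' 16-bit range. `edf`: European Data Format, 16-bit samples with per-channel
#' physical/digital scaling. The 16-bit formats quantize: round-tripped
#' samples agree to within one least-significant bit of the per-channel
#' scale. Subject metadata (`subject_id`, `fs`, `label`, `site`) is written
#' to a JSON sidecar next to the file for every format.
#'
#' @param rec An [scg_recording()].
#' @param path Output path (extension does not need to match `format`).
#' @param format `"csv"`, `"edf"`, or `"wfdb"`.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path, format = c("csv", "edf", "wfdb")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "scg_recording"))
  switch(format,
         csv = write_rec_csv(rec, path),
         edf = write_rec_edf(rec, path),
         wfdb = write_rec_wfdb(rec, path))
  write_sidecar(rec, path)
  invisible(path)
}

#' Read a recording from disk
#'
#' Counterpart to [write_recording()]. Channel columns/signals may appear in
#' any order in the file; they are mapped to canonical order by name. The
#' label is taken from the JSON sidecar when present, else `"unknown"`.
#'
#' @param path Input path.
#' @param format `"csv"`, `"edf"`, or `"wfdb"`.
#' @return An [scg_recording()].
#' @export
read_recording <- function(path, format = c("csv", "edf", "wfdb")) {
  format <- match.arg(format)
  if (!file.exists(path) && format != "wfdb")
    stop("file not found: ", path)
  parsed <- switch(format,
                   csv = read_rec_csv(path),
                   edf = read_rec_edf(path),
                   wfdb = read_rec_wfdb(path))
  meta <- read_sidecar(path)
  scg_recording(parsed$channels, fs = parsed$fs %||% meta$fs %||% 1000,
                subject_id = meta$subject_id %||% tools::file_path_sans_ext(basename(path)),
                label = meta$label %||% "unknown",
                site = meta$site)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- CSV ----

write_rec_csv <- function(rec, path) {
  df <- as.data.frame(rec$channels)
  utils::write.csv(df, path, row.names = FALSE)
}

read_rec_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(CHANNELS, names(df))
  if (length(missing))
    stop("missing channel(s): ", paste(missing, collapse = ", "))
  list(channels = as.list(df[CHANNELS]), fs = NULL)
}

## ---- WFDB (format 16) ----
## Minimal signal-16 record: <name>.hea text header and <name>.dat with
## int16 little-endian samples interleaved by frame.

write_rec_wfdb <- function(rec, path) {
  base <- tools::file_path_sans_ext(path)
  recname <- basename(base)
  n <- length(rec$channels$ecg)
  gains <- vapply(rec$channels, function(x) {
    m <- max(abs(x))
    if (m == 0) 1 else 32000 / m
  }, numeric(1))
  hea <- c(sprintf("%s %d %g %d", recname, length(CHANNELS), rec$fs, n),
           sprintf("%s.dat 16 %.10g(0)/adu 16 0 0 0 0 %s",
                   recname, gains, CHANNELS))
  writeLines(hea, paste0(base, ".hea"))
  dig <- mapply(function(x, g) {
    v <- round(x * g)
    pmin(pmax(v, -32768), 32767)
  }, rec$channels, gains)            # n x 7 matrix
  writeBin(as.integer(t(dig)), paste0(base, ".dat"), size = 2L,
           endian = "little")
}

read_rec_wfdb <- function(path) {
  base <- tools::file_path_sans_ext(path)
  hea_path <- paste0(base, ".hea")
  if (!file.exists(hea_path)) stop("file not found: ", hea_path)
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2]); fs <- as.numeric(top[3]); n <- as.integer(top[4])
  sig <- lines[-1][seq_len(nsig)]
  parts <- strsplit(trimws(sig), "\\s+")
  fmt <- vapply(parts, `[[`, "", 2)
  if (any(sub("x.*|:.*|\\+.*", "", fmt) != "16"))
    stop("only WFDB format 16 is supported")
  gains <- vapply(parts, function(p) as.numeric(sub("\\(.*", "", p[3])), numeric(1))
  gains[is.na(gains) | gains == 0] <- 200  # WFDB default gain
  names_ <- vapply(parts, function(p) p[length(p)], "")
  dat <- readBin(paste0(base, ".dat"), "integer", n = nsig * n, size = 2L,
                 signed = TRUE, endian = "little")
  m <- matrix(dat, nrow = nsig)      # interleaved frames -> signals in rows
  channels <- lapply(seq_len(nsig), function(i) m[i, ] / gains[i])
  names(channels) <- names_
  missing <- setdiff(CHANNELS, names_)
  if (length(missing))
    stop("missing channel(s): ", paste(missing, collapse = ", "))
  list(channels = channels[CHANNELS], fs = fs)
}

## ---- EDF ----
## Plain EDF, int16 little-endian. Data records of 1 s when the length is a
## whole number of seconds, otherwise a single record holding everything.

edf_pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")

## numeric field of at most 8 ascii characters (EDF header constraint)
edf_num8 <- function(x) vapply(x, function(v) {
  for (d in 7:1) {
    s <- formatC(v, digits = d, format = "g")
    if (nchar(s) <= 8) return(s)
  }
  stop("value does not fit an 8-character EDF field: ", v)
}, "")

write_rec_edf <- function(rec, path) {
  n <- length(rec$channels$ecg)
  ns <- length(CHANNELS)
  if (n %% rec$fs == 0 && n > rec$fs) {
    n_rec <- n / rec$fs; spr <- rec$fs; dur <- 1
  } else {
    n_rec <- 1; spr <- n; dur <- n / rec$fs
  }
  pmin_ <- vapply(rec$channels, min, numeric(1))
  pmax_ <- vapply(rec$channels, max, numeric(1))
  flat <- pmax_ == pmin_
  pmax_[flat] <- pmin_[flat] + 1      # avoid zero physical span
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(edf_pad("0", 8), edf_pad(rec$subject_id, 80),
                edf_pad("recording", 80),
                edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
                edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
                edf_pad(n_rec, 8), edf_pad(edf_num8(dur), 8),
                edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, w) writeChar(paste0(edf_pad(vals, w), collapse = ""),
                                       con, eos = NULL)
  field(CHANNELS, 16)                       # label
  field(rep("", ns), 80)                    # transducer
  field(rep("au", ns), 8)                   # physical dimension
  field(edf_num8(pmin_), 8)
  field(edf_num8(pmax_), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)                    # prefiltering
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)                    # reserved
  ## re-read the ascii header fields so digital samples are computed against
  ## the exact (truncated-precision) physical bounds a reader will see
  pmin_r <- as.numeric(edf_num8(pmin_))
  pmax_r <- as.numeric(edf_num8(pmax_))
  scale <- (dmax - dmin) / (pmax_r - pmin_r)
  dig <- mapply(function(x, lo, sc) {
    v <- round((x - lo) * sc) + dmin
    as.integer(pmin(pmax(v, dmin), dmax))
  }, rec$channels, pmin_r, scale, SIMPLIFY = FALSE)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in dig) writeBin(ch[idx], con, size = 2L, endian = "little")
  }
}

read_rec_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8)); dur <- as.numeric(rd(8)); ns <- as.integer(rd(4))
  labs <- trimws(vapply(seq_len(ns), function(i) readChar(con, 16, useBytes = TRUE), ""))
  readChar(con, ns * 80, useBytes = TRUE); readChar(con, ns * 8, useBytes = TRUE)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  readChar(con, ns * 80, useBytes = TRUE)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  readChar(con, ns * 32, useBytes = TRUE)
  chans <- vector("list", ns)
  for (i in seq_len(ns)) chans[[i]] <- numeric(n_rec * spr[i])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      chans[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <-
        pmin_[i] + (d - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
    }
  }
  names(chans) <- labs
  missing <- setdiff(CHANNELS, labs)
  if (length(missing))
    stop("missing channel(s): ", paste(missing, collapse = ", "))
  if (length(unique(spr)) != 1L)
    stop("mixed sampling rates across channels are not supported")
  list(channels = chans[CHANNELS], fs = spr[1] / dur)
}
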