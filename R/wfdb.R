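# Minimal WFDB-compatible record I/O (format 16, multi-frequency records via
# samples-per-frame) and Fourier resampling between analysis frequencies.
#
# Only the subset of the WFDB header grammar needed for two-channel
# driving-protocol records and single-channel session records is supported:
#   record line : <name> <nsig> <frame_fs> <nframes>
#   signal line : <file> <format>[x<spf>] <gain>(<baseline>)/<units> ... <description>
# Samples are 16-bit little-endian integers; -32768 is the invalid-sample
# sentinel and is surfaced as NaN on read.

WFDB_INVALID <- -32768L

#' Write a WFDB-style record
#'
#' Writes a `.hea` header and an interleaved format-16 `.dat` signal file.
#' Channels may have different sampling frequencies provided each is an
#' integer multiple of the slowest (frame) frequency.
#'
#' @param path record path prefix (without extension); directories are created.
#' @param channels list of channels, each a list with `name`, `samples`
#'   (numeric; `NA`/`NaN` written as the invalid-sample sentinel), `fs` (Hz)
#'   and optional `gain` (ADC units per mV, default 1000).
#' @return the header path, invisibly.
#' @export
write_wfdb_record <- function(path, channels) {
  assert_that(length(channels) > 0, "ecgstress_empty_dataset", "no channels to write")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  record <- basename(path)
  frame_fs <- min(vapply(channels, function(ch) ch$fs, numeric(1)))
  spf <- vapply(channels, function(ch) {
    r <- ch$fs / frame_fs
    assert_that(abs(r - round(r)) < 1e-9, "ecgstress_corrupt_record",
                "channel frequencies must be integer multiples of the frame rate")
    as.integer(round(r))
  }, integer(1))
  nframes <- min(vapply(seq_along(channels),
                        function(i) length(channels[[i]]$samples) %/% spf[i], numeric(1)))
  assert_that(nframes > 0, "ecgstress_corrupt_record", "record too short to hold one frame")

  # quantize each channel to ADC integers
  adc <- vector("list", length(channels))
  gains <- numeric(length(channels))
  for (i in seq_along(channels)) {
    g <- channels[[i]]$gain %||% 1000
    x <- channels[[i]]$samples[seq_len(nframes * spf[i])]
    q <- as.integer(round(x * g))
    q[!is.finite(x)] <- WFDB_INVALID
    q[is.finite(x) & q <= WFDB_INVALID] <- WFDB_INVALID + 1L
    q[q > 32767L] <- 32767L
    adc[[i]] <- q
    gains[i] <- g
  }

  hea <- c(sprintf("%s %d %s %d", record, length(channels),
                   format(frame_fs, digits = 12), nframes),
           vapply(seq_along(channels), function(i) {
             fmt <- if (spf[i] > 1L) sprintf("16x%d", spf[i]) else "16"
             sprintf("%s.dat %s %s(0)/mV 16 0 0 0 0 %s",
                     record, fmt, format(gains[i], digits = 12), channels[[i]]$name)
           }, character(1)))
  writeLines(hea, paste0(path, ".hea"))

  # interleave frame by frame: spf[i] consecutive samples per signal i
  total <- sum(spf)
  out <- integer(nframes * total)
  off <- 0L
  for (i in seq_along(channels)) {
    src <- matrix(adc[[i]], nrow = spf[i])           # spf x nframes
    pos <- outer(off + seq_len(spf[i]), (seq_len(nframes) - 1L) * total, `+`)
    out[as.vector(pos)] <- as.vector(src)
    off <- off + spf[i]
  }
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(out, con, size = 2L, endian = "little")
  invisible(paste0(path, ".hea"))
}

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(rec[2])
  frame_fs <- as.numeric(rec[3])
  nframes <- as.integer(rec[4])
  sig <- lapply(lines[1 + seq_len(nsig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    fmt <- f[2]
    spf <- 1L
    if (grepl("x", fmt, fixed = TRUE)) {
      parts <- strsplit(fmt, "x", fixed = TRUE)[[1]]
      fmt <- parts[1]; spf <- as.integer(parts[2])
    }
    gain <- 200; baseline <- 0
    gm <- regmatches(f[3], regexec("^([-0-9.eE+]+)(\\(([-0-9]+)\\))?", f[3]))[[1]]
    if (length(gm) >= 2 && nzchar(gm[2])) gain <- as.numeric(gm[2])
    if (length(gm) >= 4 && nzchar(gm[4])) baseline <- as.numeric(gm[4])
    list(file = f[1], format = fmt, spf = spf, gain = gain, baseline = baseline,
         name = if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else f[length(f)])
  })
  list(record = rec[1], nsig = nsig, frame_fs = frame_fs, nframes = nframes, signals = sig)
}

#' Read a WFDB-style record
#'
#' Reads the named ECG channel (and optionally a marker channel) from a
#' `.hea`/`.dat` pair at their native sampling frequencies.
#'
#' @param path record path prefix, with or without the `.hea` extension.
#' @param ecg_channel name of the ECG channel (default `"ECG"`).
#' @param marker_channel optional name of the marker channel; when `NULL`
#'   no marker is returned.
#' @return a list with elements `ecg` ([ecg_record()]) and `marker`
#'   ([marker_signal()] or `NULL`).
#' @export
read_record <- function(path, ecg_channel = "ECG", marker_channel = NULL) {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  assert_that(file.exists(hea_path), "ecgstress_corrupt_record",
              sprintf("no header found at '%s'", hea_path))
  hdr <- parse_wfdb_header(hea_path)
  names_ <- vapply(hdr$signals, function(s) s$name, character(1))

  dat_path <- file.path(dirname(hea_path), hdr$signals[[1]]$file)
  assert_that(file.exists(dat_path), "ecgstress_corrupt_record",
              sprintf("signal file '%s' missing", dat_path))
  total <- sum(vapply(hdr$signals, function(s) s$spf, integer(1)))
  con <- file(dat_path, "rb")
  raw <- readBin(con, integer(), n = hdr$nframes * total, size = 2L,
                 endian = "little", signed = TRUE)
  close(con)
  assert_that(length(raw) == hdr$nframes * total, "ecgstress_corrupt_record",
              "signal file truncated")

  extract <- function(idx) {
    s <- hdr$signals[[idx]]
    off <- if (idx > 1) sum(vapply(hdr$signals[seq_len(idx - 1)],
                                   function(z) z$spf, integer(1))) else 0L
    pos <- outer(off + seq_len(s$spf), (seq_len(hdr$nframes) - 1L) * total, `+`)
    adc <- raw[as.vector(pos)]
    x <- (adc - s$baseline) / s$gain
    x[adc == WFDB_INVALID] <- NaN
    list(samples = x, fs = hdr$frame_fs * s$spf)
  }

  find_channel <- function(name, what) {
    idx <- match(name, names_)
    if (is.na(idx))
      stop_ecgstress("ecgstress_missing_channel",
                     sprintf("%s channel '%s' not present in record %s (has: %s)",
                             what, name, hdr$record, paste(names_, collapse = ", ")))
    idx
  }

  e <- extract(find_channel(ecg_channel, "ECG"))
  if (any(!is.finite(e$samples)))
    stop_ecgstress("ecgstress_corrupt_record",
                   sprintf("record %s: ECG channel contains invalid signal values", hdr$record))
  ecg <- ecg_record(e$samples, e$fs, subject_id = hdr$record, channel_name = ecg_channel)

  marker <- NULL
  if (!is.null(marker_channel)) {
    m <- extract(find_channel(marker_channel, "marker"))
    if (any(!is.finite(m$samples)))
      stop_ecgstress("ecgstress_corrupt_record",
                     sprintf("record %s: marker channel contains invalid signal values", hdr$record))
    marker <- marker_signal(m$samples, m$fs, subject_id = hdr$record)
  }
  list(ecg = ecg, marker = marker)
}

#' Resample a uniformly sampled signal
#'
#' Fourier-domain resampling: the spectrum is truncated or zero-padded so
#' that the output has exactly `round(n * fs_out / fs_in)` samples.  Content
#' below `min(fs_in, fs_out) / 2` is preserved; a constant signal stays
#' exactly constant.
#'
#' @param x numeric vector (length >= 2).
#' @param fs_in,fs_out input and output sampling frequencies in Hz.
#' @return numeric vector of length `round(length(x) * fs_out / fs_in)`.
#' @export
resample <- function(x, fs_in, fs_out) {
  assert_that(is.numeric(fs_in) && fs_in > 0 && is.numeric(fs_out) && fs_out > 0,
              "ecgstress_degenerate_signal", "sampling frequencies must be positive")
  assert_that(length(x) >= 2, "ecgstress_degenerate_signal",
              "cannot resample a signal with fewer than 2 samples")
  n <- length(x)
  n_out <- as.integer(round(n * fs_out / fs_in))
  assert_that(n_out >= 1, "ecgstress_degenerate_signal", "output length would be empty")
  if (n_out == n) return(x)

  X <- stats::fft(x)
  Y <- complex(n_out)
  m <- min(n, n_out)
  keep_pos <- m %/% 2 + 1L                  # DC .. highest retained positive bin
  Y[seq_len(keep_pos)] <- X[seq_len(keep_pos)]
  neg <- m - keep_pos                       # negative-side bins
  if (neg > 0) Y[(n_out - neg + 1L):n_out] <- X[(n - neg + 1L):n]
  if (m %% 2L == 0L) {
    ny <- keep_pos                          # shared Nyquist bin of the shorter grid
    if (n_out > n) {                        # upsampling: split across the mirror pair
      Y[ny] <- Y[ny] / 2
      Y[n_out - (m %/% 2L) + 1L] <- Conj(Y[ny])
    } else {                                # downsampling: fold the mirror pair in
      Y[ny] <- X[ny] + X[n - (m %/% 2L) + 1L]
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}
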