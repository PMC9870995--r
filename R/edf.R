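# Minimal EDF / BDF reader and writer.
#
# EDF: 256-byte ASCII header + 256 bytes per signal, then data records of
# 16-bit little-endian integers. BDF (BioSemi) is the same layout with a
# 0xFF "BIOSEMI" magic and 24-bit samples. Only the subset needed for this
# pipeline is implemented: identical sample rate on all channels and
# whole-second records.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width)
}

#' Write a recording to EDF or BDF
#'
#' Physical units are microvolts; each channel is scaled to the full
#' digital range (16-bit for EDF, 24-bit for BDF), so round-trip error is
#' bounded by half a quantization step of the channel's amplitude range.
#' The recording must contain a whole number of seconds.
#'
#' @param rec an [recording()].
#' @param path output file path.
#' @param bdf write 24-bit BDF instead of 16-bit EDF.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, bdf = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  srate <- rec$sample_rate
  if (abs(srate - round(srate)) > 1e-9)
    stop("EDF export requires an integer sample rate", call. = FALSE)
  srate <- round(srate)
  ns <- nrow(rec$signals)
  nsamp <- ncol(rec$signals)
  if (nsamp %% srate != 0)
    stop("EDF export requires a whole number of seconds", call. = FALSE)
  nrec <- nsamp %/% srate

  dmin <- if (bdf) -8388608 else -32768
  dmax <- if (bdf) 8388607 else 32767
  # integer physical bounds: exactly representable in the 8-char ASCII
  # header fields, so channel scaling survives the round trip losslessly
  pmin <- floor(apply(rec$signals, 1, min))
  pmax <- ceiling(apply(rec$signals, 1, max))
  flat <- pmax - pmin < 1
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  if (any(pmin < -9999999) || any(pmax > 99999999))
    stop("signal amplitudes exceed the EDF header range", call. = FALSE)

  con <- file(path, "wb")
  on.exit(close(con))
  if (bdf) {
    writeBin(as.raw(255), con)
    writeChar(pad_field("BIOSEMI", 7), con, 7, eos = NULL)
  } else {
    writeChar(pad_field("0", 8), con, 8, eos = NULL)
  }
  writeChar(pad_field("synthetic subject", 80), con, 80, eos = NULL)
  writeChar(pad_field("synthetic recording", 80), con, 80, eos = NULL)
  writeChar(pad_field("01.01.00", 8), con, 8, eos = NULL)
  writeChar(pad_field("00.00.00", 8), con, 8, eos = NULL)
  writeChar(pad_field(256 * (ns + 1), 8), con, 8, eos = NULL)
  writeChar(pad_field(if (bdf) "24BIT" else "", 44), con, 44, eos = NULL)
  writeChar(pad_field(nrec, 8), con, 8, eos = NULL)
  writeChar(pad_field(1, 8), con, 8, eos = NULL)
  writeChar(pad_field(ns, 4), con, 4, eos = NULL)
  wf <- function(vals, width)
    for (v in vals) writeChar(pad_field(v, width), con, width, eos = NULL)
  wf(rec$labels, 16)
  wf(rep("synthetic", ns), 80)
  wf(rep("uV", ns), 8)
  wf(sprintf("%d", as.integer(pmin)), 8)
  wf(sprintf("%d", as.integer(pmax)), 8)
  wf(rep(dmin, ns), 8)
  wf(rep(dmax, ns), 8)
  wf(rep("none", ns), 80)
  wf(rep(srate, ns), 8)
  wf(rep("", ns), 32)

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1) * srate + 1):(r * srate)
    for (ch in seq_len(ns)) {
      d <- round((rec$signals[ch, cols] - pmin[ch]) * scale[ch] + dmin)
      d <- as.integer(clip(d, dmin, dmax))
      if (bdf) {
        u <- ifelse(d < 0, d + 16777216, d)
        b <- rbind(u %% 256L, (u %/% 256L) %% 256L, u %/% 65536L)
        writeBin(as.raw(b), con)
      } else {
        writeBin(d, con, size = 2, endian = "little")
      }
    }
  }
  invisible(path)
}

#' Read an EDF or BDF recording
#'
#' Detects the format from the magic bytes (plain EDF vs 0xFF "BIOSEMI"
#' BDF), reads the signals at full resolution and returns them in physical
#' units (microvolts). Channels whose labels match the 10-10 montage get
#' montage positions attached. All channels must share one sample rate.
#'
#' @param path file path.
#' @return an [recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  bdf <- magic[1] == as.raw(255) &&
    rawToChar(magic[2:8]) == "BIOSEMI"
  if (!bdf && substr(rawToChar(magic), 1, 1) != "0")
    stop("unsupported format: neither EDF nor BDF header", call. = FALSE)
  rstr <- function(k) {
    out <- rawToChar(readBin(con, "raw", k))
    trimws(out)
  }
  rstr(80); rstr(80); rstr(8); rstr(8)
  header_bytes <- as.integer(rstr(8))
  rstr(44)
  nrec <- as.integer(rstr(8))
  rec_dur <- as.numeric(rstr(8))
  ns <- as.integer(rstr(4))
  if (is.na(ns) || ns < 1) stop("corrupt header: bad signal count",
                                call. = FALSE)
  rfields <- function(width) vapply(seq_len(ns), function(i) rstr(width), "")
  labels <- rfields(16)
  rfields(80); rfields(8)
  pmin <- as.numeric(rfields(8))
  pmax <- as.numeric(rfields(8))
  dmin <- as.numeric(rfields(8))
  dmax <- as.numeric(rfields(8))
  rfields(80)
  spr <- as.integer(rfields(8))
  rfields(32)
  if (length(unique(spr)) != 1)
    stop("channels with differing sample rates are not supported",
         call. = FALSE)
  srate <- spr[1] / rec_dur
  bytes_per_sample <- if (bdf) 3L else 2L
  expected <- header_bytes + nrec * sum(spr) * bytes_per_sample
  if (file.size(path) < expected)
    stop(sprintf("truncated file: %d bytes, %d expected", file.size(path),
                 expected), call. = FALSE)

  X <- matrix(0, ns, nrec * spr[1])
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (ch in seq_len(ns)) {
      if (bdf) {
        b <- as.integer(readBin(con, "raw", 3L * spr[ch]))
        u <- b[seq(1, length(b), 3)] + 256 * b[seq(2, length(b), 3)] +
          65536 * b[seq(3, length(b), 3)]
        d <- ifelse(u >= 8388608, u - 16777216, u)
      } else {
        d <- readBin(con, "integer", spr[ch], size = 2, endian = "little")
      }
      X[ch, cols] <- (d - dmin[ch]) * scale[ch] + pmin[ch]
    }
  }
  m <- montage_1010_full()
  positions <- NULL
  if (all(labels %in% m$labels))
    positions <- m$positions[labels, , drop = FALSE]
  recording(X, srate, labels = labels, positions = positions)
}
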