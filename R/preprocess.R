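#' Apply a common average reference
#'
#' Subtracts, at every sample, the instantaneous mean across channels, so
#' that the channel mean of the output is zero everywhere. Idempotent.
#'
#' @param rec an [recording()].
#' @return the re-referenced recording, tagged `reference = "average"`.
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$signals) < 2)
    stop("average reference requires at least 2 channels", call. = FALSE)
  rec$signals <- sweep(rec$signals, 2, colMeans(rec$signals))
  rec$reference <- "average"
  rec
}

#' Downsample a recording by an integer factor
#'
#' Applies a zero-phase anti-alias low-pass (raised-cosine cutoff ending at
#' the new Nyquist frequency, passband flat to 0.85 x Nyquist) before
#' decimation.
#'
#' @param rec an [recording()].
#' @param target_rate new sampling rate in Hz; must divide the current rate
#'   evenly (e.g. 2048 -> 1024).
#' @return the downsampled recording.
#' @export
downsample <- function(rec, target_rate) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_scalar_number(target_rate, "target_rate", positive = TRUE)
  fac <- rec$sample_rate / target_rate
  if (abs(fac - round(fac)) > 1e-9)
    stop(sprintf("target_rate %g does not divide sample_rate %g evenly",
                 target_rate, rec$sample_rate), call. = FALSE)
  fac <- round(fac)
  if (fac == 1L) return(rec)
  nyq <- target_rate / 2
  filt <- fft_filter_rows(rec$signals, rec$sample_rate,
                          low = 0, high = 0.85 * nyq,
                          transition = 0.15 * nyq)
  rec$signals <- filt[, seq(1, ncol(filt), by = fac), drop = FALSE]
  rec$sample_rate <- target_rate
  rec
}

# spherical-spline basis g(cos angle) (order-m spline, nterms Legendre terms)
spline_g <- function(cosang, m = 4, nterms = 20) {
  # Legendre recurrence evaluated for all orders at once
  out <- numeric(length(cosang))
  p_prev <- rep(1, length(cosang))   # P_0
  p_cur <- cosang                    # P_1
  for (n in 1:nterms) {
    out <- out + (2 * n + 1) / (n * (n + 1))^m * p_cur
    p_next <- ((2 * n + 1) * cosang * p_cur - n * p_prev) / (n + 1)
    p_prev <- p_cur
    p_cur <- p_next
  }
  out / (4 * pi)
}

#' Interpolate bad channels by spherical splines
#'
#' Replaces the listed channels with order-4 spherical-spline estimates
#' (Perrin-style regularized spline on the unit sphere) computed from the
#' remaining good channels. At most `max_bad` channels may be interpolated;
#' beyond that the subject must be excluded, which is signalled with a
#' condition of class `macroeeg_exclusion`.
#'
#' @param rec an [recording()] with electrode positions.
#' @param bad character vector of channel labels to replace (may be empty).
#' @param max_bad maximum number of interpolatable channels (default 6,
#'   about 10% of a 64-channel montage).
#' @param lambda ridge regularization added to the spline system.
#' @return the recording with bad channels replaced.
#' @export
interpolate_channels <- function(rec, bad, max_bad = 6, lambda = 1e-8) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(bad) == 0) return(rec)
  bad <- unique(as.character(bad))
  unknown <- setdiff(bad, rec$labels)
  if (length(unknown))
    stop(sprintf("unknown channel(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (length(bad) > max_bad)
    abort_exclusion(
      sprintf("%d bad channels exceed the maximum of %d: subject excluded",
              length(bad), max_bad),
      rule = sprintf("more than %d channels required interpolation", max_bad))
  if (is.null(rec$positions))
    stop("electrode positions are required for interpolation", call. = FALSE)

  good <- setdiff(rec$labels, bad)
  Pg <- rec$positions[good, , drop = FALSE]
  Pb <- rec$positions[bad, , drop = FALSE]
  G <- spline_g(clip(tcrossprod(Pg), -1, 1))
  ng <- length(good)
  # constrained system: [G + lambda I, 1; 1', 0] [c; d] = [v; 0]
  A <- rbind(cbind(G + diag(lambda, ng), 1), c(rep(1, ng), 0))
  V <- rbind(rec$signals[good, , drop = FALSE], 0)
  sol <- solve(A, V)
  Gb <- spline_g(clip(tcrossprod(Pb, Pg), -1, 1))
  est <- Gb %*% sol[seq_len(ng), , drop = FALSE] +
    matrix(sol[ng + 1, ], nrow(Pb), ncol(rec$signals), byrow = TRUE)
  rec$signals[bad, ] <- est
  rec
}

#' Select artifact-free epochs
#'
#' Splits the recording into consecutive non-overlapping windows of
#' `epoch_length` seconds starting at the first sample, marks a window bad
#' when any channel exceeds `amplitude_limit` microvolts in absolute value,
#' and returns the first `n_epochs` clean windows in temporal order. Bad
#' windows are skipped whole, never truncated or shifted.
#'
#' The amplitude criterion is an automatic stand-in for visual artifact
#' rating; 100 uV is a common rejection threshold for eyes-closed recordings.
#'
#' @param rec an [recording()].
#' @param epoch_length window length in seconds (default 4).
#' @param n_epochs number of clean windows required (default 15).
#' @param amplitude_limit per-channel absolute amplitude limit in uV.
#' @return an [epoch_set()] of broadband epochs.
#' @export
select_epochs <- function(rec, epoch_length = 4, n_epochs = 15,
                          amplitude_limit = 100) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- round(epoch_length * rec$sample_rate)
  n_win <- floor(ncol(rec$signals) / ns)
  picked <- list()
  starts <- integer(0)
  for (w in seq_len(n_win)) {
    i0 <- (w - 1L) * ns + 1L
    seg <- rec$signals[, i0:(i0 + ns - 1L), drop = FALSE]
    if (max(abs(seg)) <= amplitude_limit) {
      picked[[length(picked) + 1L]] <- seg
      starts <- c(starts, i0)
      if (length(picked) == n_epochs) break
    }
  }
  if (length(picked) < n_epochs)
    abort_exclusion(
      sprintf("%d clean epochs found, %d required", length(picked), n_epochs),
      rule = sprintf("fewer than %d clean epochs", n_epochs))
  es <- epoch_set(picked, epoch_length, rec$sample_rate, rec$labels)
  attr(es, "starts") <- starts
  es
}

#' Band-pass filter an epoch set
#'
#' Zero-phase FFT filtering with raised-cosine transitions (default width
#' 0.5 Hz) applied outside the band edges, so in-band components keep their
#' amplitude and, critically for phase metrics, their phase. Applying the
#' same filter twice is idempotent in the passband.
#'
#' @param eps an [epoch_set()].
#' @param band a [band_definition()].
#' @param transition transition width in Hz.
#' @return the filtered epoch set, tagged with the band.
#' @export
bandpass <- function(eps, band, transition = 0.5) {
  stopifnot(inherits(eps, "eeg_epochs"))
  if (band$high >= eps$sample_rate / 2)
    stop(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)",
                 band$high, eps$sample_rate / 2), call. = FALSE)
  eps$epochs <- lapply(eps$epochs, fft_filter_rows, srate = eps$sample_rate,
                       low = band$low, high = band$high,
                       transition = transition)
  eps$band <- band
  eps
}
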