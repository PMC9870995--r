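#' Multichannel EEG recording container
#'
#' A light S3 container for a channel-labelled multichannel signal in
#' microvolts, with sample rate, optional unit-sphere electrode positions
#' (needed for spherical-spline interpolation) and a reference tag.
#'
#' @param signals numeric matrix, channels x samples, in microvolts.
#' @param sample_rate sampling rate in Hz.
#' @param labels unique channel labels; defaults to the first rows of the
#'   10-10 montage.
#' @param positions optional channels x 3 matrix of unit-sphere coordinates.
#' @param reference reference tag, `"raw"` or `"average"`.
#' @return an object of class `eeg_recording`.
#' @export
recording <- function(signals, sample_rate, labels = NULL, positions = NULL,
                      reference = c("raw", "average")) {
  reference <- match.arg(reference)
  if (!is.matrix(signals) || !is.numeric(signals))
    stop("'signals' must be a numeric channels x samples matrix", call. = FALSE)
  check_scalar_number(sample_rate, "sample_rate", positive = TRUE)
  nch <- nrow(signals)
  if (is.null(labels)) {
    if (nch > 64)
      stop("default labels only cover up to 64 channels", call. = FALSE)
    m <- montage_1010(nch)
    labels <- m$labels
    if (is.null(positions)) positions <- m$positions
  }
  if (length(labels) != nch) stop("one label per channel required", call. = FALSE)
  if (anyDuplicated(labels)) stop("channel labels must be unique", call. = FALSE)
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != nch || ncol(positions) != 3)
      stop("'positions' must be a channels x 3 matrix", call. = FALSE)
    r <- sqrt(rowSums(positions^2))
    if (any(abs(r - 1) > 1e-6)) positions <- positions / r
    rownames(positions) <- labels
  }
  rownames(signals) <- labels
  structure(list(signals = signals, sample_rate = sample_rate,
                 labels = labels, positions = positions,
                 reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %s reference\n",
              nrow(x$signals), ncol(x$signals), x$sample_rate,
              ncol(x$signals) / x$sample_rate, x$reference))
  invisible(x)
}

#' Canonical frequency bands
#'
#' The four analysis bands: delta 0.5--4, theta 4--8, alpha 8--13 and
#' beta 13--20 Hz. Frequencies above 20 Hz are deliberately excluded
#' (muscle-artifact contamination); there is no gamma band in this pipeline.
#' For band-power accounting, shared edges belong to the lower band via
#' half-open intervals `[low, high)`.
#'
#' @return named list of `c(low, high)` pairs in Hz.
#' @export
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 20))
}

#' Validate a band definition
#'
#' @param name one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`.
#' @param low,high optional edges in Hz; default to the canonical edges.
#' @return list with `name`, `low`, `high`.
#' @export
band_definition <- function(name, low = NULL, high = NULL) {
  canon <- eeg_bands()
  if (!name %in% names(canon))
    stop(sprintf("band '%s' outside supported set (%s)", name,
                 paste(names(canon), collapse = ", ")), call. = FALSE)
  low <- low %||% canon[[name]][1]
  high <- high %||% canon[[name]][2]
  if (low >= high) stop("band low must be < high", call. = FALSE)
  list(name = name, low = low, high = high)
}

#' Fixed-length epoch container
#'
#' @param epochs list of channels x samples matrices, all identically sized.
#' @param epoch_length epoch length in seconds.
#' @param sample_rate sampling rate in Hz.
#' @param labels channel labels.
#' @param band optional band tag (a [band_definition()]).
#' @return an object of class `eeg_epochs`.
#' @export
epoch_set <- function(epochs, epoch_length, sample_rate, labels,
                      band = NULL) {
  if (!length(epochs)) stop("empty epoch list", call. = FALSE)
  ns <- round(epoch_length * sample_rate)
  ok <- vapply(epochs, function(e) is.matrix(e) && ncol(e) == ns &&
                 nrow(e) == length(labels), logical(1))
  if (!all(ok))
    stop("every epoch must be channels x (epoch_length * sample_rate)",
         call. = FALSE)
  structure(list(epochs = epochs, epoch_length = epoch_length,
                 sample_rate = sample_rate, labels = labels, band = band),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  b <- if (is.null(x$band)) "broadband"
       else sprintf("%s (%g-%g Hz)", x$band$name, x$band$low, x$band$high)
  cat(sprintf("<eeg_epochs> %d epochs of %g s, %d channels @ %g Hz, %s\n",
              length(x$epochs), x$epoch_length, length(x$labels),
              x$sample_rate, b))
  invisible(x)
}
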