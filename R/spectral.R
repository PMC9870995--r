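#' Average power spectrum of an epoch set
#'
#' Rectangular-window (no taper) periodogram per epoch and channel, averaged
#' over epochs and channels. 4-s epochs give 0.25 Hz bins; bin `k` covers
#' the half-open interval `[k*df, (k+1)*df)` and holds the power of the FFT
#' component at `k*df`. Scaling satisfies Parseval: the sum of all bins
#' (including the DC bin) equals the time-domain mean square of the epoch.
#' A Hann taper is available behind `window = "hann"` for spectra with
#' strong leakage, at the cost of exact Parseval accounting.
#'
#' @param eps a broadband (unfiltered) [epoch_set()].
#' @param window `"rectangular"` (default) or `"hann"`.
#' @param keep_channels keep the channel-resolved spectrum matrix.
#' @return object of class `eeg_spectrum` with `bin_low`, `bin_high`,
#'   `power` (averaged), and optionally `per_channel` (bins x channels).
#' @export
power_spectrum <- function(eps, window = c("rectangular", "hann"),
                           keep_channels = FALSE) {
  stopifnot(inherits(eps, "eeg_epochs"))
  window <- match.arg(window)
  if (!is.null(eps$band))
    stop("power_spectrum expects broadband (unfiltered) epochs", call. = FALSE)
  if (!length(eps$epochs)) stop("empty epoch set", call. = FALSE)
  n <- ncol(eps$epochs[[1]])
  df <- eps$sample_rate / n
  nb <- floor(n / 2) + 1L
  w <- if (window == "hann") 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n)) else rep(1, n)
  wnorm <- sum(w^2) / n

  acc <- matrix(0, nb, length(eps$labels))
  for (e in eps$epochs) {
    X <- mvfft(t(e) * w)            # samples x channels
    P <- (Mod(X)^2) / n^2 / wnorm   # two-sided
    ps <- P[seq_len(nb), , drop = FALSE]
    # fold negative frequencies onto positive bins (DC and Nyquist unpaired)
    dup <- 2:(nb - if (n %% 2 == 0) 1L else 0L)
    ps[dup, ] <- 2 * ps[dup, , drop = FALSE]
    acc <- acc + ps
  }
  acc <- acc / length(eps$epochs)
  structure(list(bin_low = (seq_len(nb) - 1) * df,
                 bin_high = seq_len(nb) * df,
                 power = rowMeans(acc),
                 per_channel = if (keep_channels) acc else NULL,
                 df = df, n_epochs = length(eps$epochs)),
            class = "eeg_spectrum")
}

#' Relative band power
#'
#' Absolute power per band divided by the total power of the four canonical
#' bands only (not total broadband power), so the four fractions sum to 1.
#' A bin belongs to a band when its lower edge falls in `[low, high)`;
#' shared edges therefore count toward the lower band exactly once.
#'
#' @param spec an `eeg_spectrum` from [power_spectrum()].
#' @param bands band list as from [eeg_bands()].
#' @return named numeric vector of fractions summing to 1.
#' @export
relative_band_power <- function(spec, bands = eeg_bands()) {
  stopifnot(inherits(spec, "eeg_spectrum"))
  absolute <- vapply(bands, function(b)
    sum(spec$power[spec$bin_low >= b[1] - 1e-9 & spec$bin_low < b[2] - 1e-9]),
    numeric(1))
  total <- sum(absolute)
  if (total <= 0) stop("zero total band power", call. = FALSE)
  absolute / total
}
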