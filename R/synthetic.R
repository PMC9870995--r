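#' Specification of a synthetic multichannel EEG-like recording
#'
#' Describes a stationary eyes-closed-like signal: per-band narrowband
#' oscillations (band-limited Gaussian noise) on every channel, a 1/f
#' background, optional pairwise phase coupling (a lagged shared phase
#' time-series blended by a coupling strength), optional pairwise
#' amplitude-envelope coupling (correlated log-envelopes on independent
#' carriers), and an optional instantaneous linear mixing matrix as a
#' volume-conduction surrogate, applied last.
#'
#' Default band amplitudes (alpha-dominant) and the 1/f slope are
#' conventions for a young-adult eyes-closed recording, not estimates from
#' any particular cohort.
#'
#' @param n_channels number of channels (<= 64; labelled from the 10-10
#'   montage).
#' @param sample_rate sampling rate in Hz (default 2048).
#' @param duration recording length in seconds; `duration * sample_rate`
#'   must be a whole number of samples.
#' @param band_amplitudes named amplitudes (uV, SD) of the four band
#'   oscillations.
#' @param noise_amplitude amplitude (uV, SD) of the 1/f background; 0
#'   disables it.
#' @param noise_exponent spectral slope of the background (power ~ 1/f^exp).
#' @param phase_coupling data frame with columns `i`, `j` (channel indices),
#'   `band`, `strength` in `[0, 1]`, `lag` in radians.
#' @param envelope_coupling data frame with columns `i`, `j`, `band`, `rho`
#'   (target envelope correlation in `[-1, 1]`).
#' @param mixing optional n x n finite mixing matrix (identity = no volume
#'   conduction).
#' @param seed integer seed; identical specs give bit-identical recordings.
#' @return a validated list of class `signal_spec`.
#' @export
signal_spec <- function(n_channels = 64, sample_rate = 2048, duration = 64,
                        band_amplitudes = c(delta = 10, theta = 8,
                                            alpha = 20, beta = 6),
                        noise_amplitude = 10, noise_exponent = 1,
                        phase_coupling = NULL, envelope_coupling = NULL,
                        mixing = NULL, seed = 1) {
  check_scalar_number(duration, "duration", positive = TRUE)
  check_scalar_number(sample_rate, "sample_rate", positive = TRUE)
  check_scalar_number(n_channels, "n_channels", positive = TRUE)
  n <- duration * sample_rate
  if (abs(n - round(n)) > 1e-6)
    stop("duration * sample_rate must be an integer sample count",
         call. = FALSE)
  bands <- names(eeg_bands())
  if (!all(bands %in% names(band_amplitudes)))
    stop("'band_amplitudes' must name all four bands", call. = FALSE)
  chk_pairs <- function(df, what, col3, rng) {
    if (is.null(df)) return(NULL)
    df <- as.data.frame(df)
    need <- c("i", "j", "band", col3)
    if (!all(need %in% names(df)))
      stop(sprintf("'%s' needs columns %s", what,
                   paste(need, collapse = ", ")), call. = FALSE)
    if (!all(df$band %in% bands))
      stop(sprintf("'%s' bands must be among %s", what,
                   paste(bands, collapse = ", ")), call. = FALSE)
    if (any(df$i < 1 | df$i > n_channels | df$j < 1 | df$j > n_channels |
              df$i == df$j))
      stop(sprintf("'%s' channel indices out of range", what), call. = FALSE)
    if (any(df[[col3]] < rng[1] | df[[col3]] > rng[2]))
      stop(sprintf("'%s' %s must lie in [%g, %g]", what, col3, rng[1],
                   rng[2]), call. = FALSE)
    df
  }
  phase_coupling <- chk_pairs(phase_coupling, "phase_coupling", "strength",
                              c(0, 1))
  envelope_coupling <- chk_pairs(envelope_coupling, "envelope_coupling",
                                 "rho", c(-1, 1))
  if (!is.null(mixing)) {
    mixing <- as.matrix(mixing)
    if (nrow(mixing) != n_channels || ncol(mixing) != n_channels ||
        any(!is.finite(mixing)))
      stop("'mixing' must be a finite n_channels x n_channels matrix",
           call. = FALSE)
  }
  structure(list(n_channels = n_channels, sample_rate = sample_rate,
                 duration = duration, band_amplitudes = band_amplitudes,
                 noise_amplitude = noise_amplitude,
                 noise_exponent = noise_exponent,
                 phase_coupling = phase_coupling,
                 envelope_coupling = envelope_coupling,
                 mixing = mixing, seed = as.integer(seed)),
            class = "signal_spec")
}

#' Generate a synthetic EEG-like recording
#'
#' Realizes a [signal_spec()]: independent unit-variance narrowband carriers
#' per channel and band; phase coupling replaces a fraction `strength` of
#' the target's carrier with a copy of the seed's carrier shifted by a fixed
#' phase lag (via the analytic signal), so `strength = 1, lag != 0` forces
#' complete non-zero-lag phase locking and `strength = 0` leaves channels
#' independent; envelope coupling multiplies independent carriers by
#' correlated log-normal slow envelopes; the 1/f background is added per
#' channel; instantaneous mixing is applied last.
#'
#' @param spec a [signal_spec()].
#' @return an [recording()] with montage labels and positions.
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "signal_spec"))
  with_seed(spec$seed, {
    nch <- spec$n_channels
    srate <- spec$sample_rate
    n <- round(spec$duration * srate)
    bands <- eeg_bands()
    X <- matrix(0, nch, n)

    for (b in names(bands)) {
      amp <- spec$band_amplitudes[[b]]
      pc <- spec$phase_coupling
      ec <- spec$envelope_coupling
      pc <- if (is.null(pc)) NULL else pc[pc$band == b, , drop = FALSE]
      ec <- if (is.null(ec)) NULL else ec[ec$band == b, , drop = FALSE]
      if (amp <= 0 && (is.null(pc) || !nrow(pc)) &&
            (is.null(ec) || !nrow(ec))) next
      lo <- bands[[b]][1]; hi <- bands[[b]][2]
      S <- t(vapply(seq_len(nch),
                    function(ch) narrowband_noise(n, srate, lo, hi),
                    numeric(n)))
      if (!is.null(pc)) for (k in seq_len(NROW(pc))) {
        ci <- pc$i[k]; cj <- pc$j[k]
        cs <- pc$strength[k]; lag <- pc$lag[k]
        lagged <- Re(analytic_rows(S[ci, , drop = FALSE])[1, ] *
                       exp(-1i * lag))
        S[cj, ] <- (1 - cs) * S[cj, ] + cs * lagged
      }
      if (!is.null(ec)) for (k in seq_len(NROW(ec))) {
        ci <- ec$i[k]; cj <- ec$j[k]; rho <- ec$rho[k]
        a1 <- narrowband_noise(n, srate, 0, 1)
        a2 <- narrowband_noise(n, srate, 0, 1)
        sig_e <- 0.75
        S[ci, ] <- S[ci, ] * exp(sig_e * a1)
        S[cj, ] <- S[cj, ] * exp(sig_e * (rho * a1 + sqrt(1 - rho^2) * a2))
      }
      sds <- apply(S, 1, sd)
      sds[sds == 0] <- 1
      X <- X + (amp * S) / sds
    }

    if (spec$noise_amplitude > 0)
      for (ch in seq_len(nch))
        X[ch, ] <- X[ch, ] +
          spec$noise_amplitude * pink_noise(n, spec$noise_exponent, srate)

    if (!is.null(spec$mixing)) X <- spec$mixing %*% X
    recording(X, srate)
  })
}
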