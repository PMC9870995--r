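# FFT-based signal primitives.
#
# All filtering is done in the frequency domain with raised-cosine
# transition edges, which is zero-phase by construction (a purely real,
# symmetric transfer function) -- essential for phase-based connectivity.
# The cost is circular (wrap-around) edge behaviour on finite segments;
# connectivity routines discard an edge margin of each epoch to compensate.

# |f| for each FFT bin of a length-n transform at rate srate
fft_freqs <- function(n, srate) {
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  if (n == 1) k <- 0
  abs(k[seq_len(n)]) * srate / n
}

# raised-cosine band-pass gain; transition ramps sit *outside* [low, high]
# so in-band amplitudes are passed exactly.
fft_gain <- function(f, low, high, transition) {
  g <- numeric(length(f))
  g[f >= low & f <= high] <- 1
  if (low > 0) {
    lo0 <- max(low - transition, 0)
    i <- f > lo0 & f < low
    g[i] <- 0.5 * (1 + cos(pi * (low - f[i]) / transition))
  }
  i <- f > high & f < high + transition
  g[i] <- 0.5 * (1 + cos(pi * (f[i] - high) / transition))
  g
}

# filter the rows of x (channels x samples)
fft_filter_rows <- function(x, srate, low, high, transition = 0.5) {
  n <- ncol(x)
  g <- fft_gain(fft_freqs(n, srate), low, high, transition)
  X <- mvfft(t(x))
  t(Re(mvfft(X * g, inverse = TRUE))) / n
}

# analytic signal (Hilbert) of each row; returns complex matrix
analytic_rows <- function(x) {
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  X <- mvfft(t(x))
  t(mvfft(X * h, inverse = TRUE)) / n
}

# 1/f^exponent power-shaped Gaussian noise, unit variance
pink_noise <- function(n, exponent, srate = 1) {
  w <- rnorm(n)
  f <- fft_freqs(n, srate)
  shape <- c(0, f[-1]^(-exponent / 2))
  x <- Re(fft(fft(w) * shape, inverse = TRUE)) / n
  s <- sd(x)
  if (s > 0) x / s else x
}

# unit-variance Gaussian noise band-limited to [low, high]
narrowband_noise <- function(n, srate, low, high, transition = 0.5) {
  x <- fft_filter_rows(matrix(rnorm(n), 1), srate, low, high, transition)[1, ]
  s <- sd(x)
  if (s > 0) x / s else x
}
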