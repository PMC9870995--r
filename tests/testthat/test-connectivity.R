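test_that("PLI endpoints: identical signals give 0, quarter-cycle lag gives 1", {
  srate <- 256
  t <- seq(0, 4 - 1 / srate, by = 1 / srate)
  x <- sin(2 * pi * 10 * t) + 0.1 * sin(2 * pi * 9 * t)
  eps <- epoch_set(list(rbind(x, x, sin(2 * pi * 10 * t - pi / 2))),
                   4, srate, c("a", "b", "c"))
  f <- bandpass(eps, band_definition("alpha"))
  cm <- pli(f)
  expect_equal(cm$values[1, 2], 0)
  expect_gt(cm$values[1, 3], 0.999)
  expect_true(all(cm$values[upper.tri(cm$values)] >= 0 &
                    cm$values[upper.tri(cm$values)] <= 1))
  expect_equal(cm$values, t(cm$values))
})

test_that("PLI matches a literal sign-of-sine oracle on independent noise", {
  eps <- quick_epochs(n_channels = 3, n_epochs = 2, seed = 11)
  got <- pli(eps)$values
  want <- naive_pli(eps$epochs)
  diag(want) <- NA_real_
  expect_equal(got, want, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("constant channels are rejected by name", {
  eps <- quick_epochs(n_channels = 3, seed = 2)
  eps$epochs[[1]][2, ] <- 5
  expect_error(pli(eps), "ch2")
  expect_error(aec_c(eps), "ch2")
})

test_that("AEC-c is 0.5 for independent channels and high for shared envelopes", {
  sp <- signal_spec(n_channels = 4, sample_rate = 256, duration = 68,
                    band_amplitudes = c(delta = 0, theta = 0, alpha = 1,
                                        beta = 0),
                    noise_amplitude = 0,
                    envelope_coupling = data.frame(i = 1, j = 2,
                                                   band = "alpha", rho = 1),
                    seed = 3)
  f <- bandpass(select_epochs(generate_recording(sp), 4, 15, Inf),
                band_definition("alpha"))
  ac <- aec_c(f)
  expect_gt(ac$values[1, 2], 0.7)              # coupled: far above null
  expect_lt(abs(ac$values[3, 4] - 0.5), 0.07)  # independent: close to 0.5
  expect_gt(ac$values[1, 2], ac$values[3, 4] + 0.2)
})

test_that("collinear pairs report 0.5 with a warning", {
  eps <- quick_epochs(n_channels = 3, n_epochs = 1, seed = 4)
  eps$epochs[[1]][2, ] <- 2.5 * eps$epochs[[1]][1, ]
  expect_warning(ac <- aec_c(eps), "collinear")
  expect_equal(ac$values[1, 2], 0.5)
})

test_that("both metrics are invariant to channel-wise amplitude scaling", {
  eps <- quick_epochs(n_channels = 3, n_epochs = 2, seed = 5)
  scaled <- eps
  scaled$epochs <- lapply(eps$epochs, function(e) diag(c(2, 0.5, 7)) %*% e)
  expect_equal(pli(scaled)$values, pli(eps)$values, tolerance = 1e-9)
  expect_equal(aec_c(scaled)$values, aec_c(eps)$values, tolerance = 1e-9)
})

test_that("instantaneous mixing leaves PLI low and AEC-c near 0.5, while raw
          envelope correlation inflates", {
  n <- 6
  M <- diag(n); M[M == 0] <- 0.35
  sp <- signal_spec(n_channels = n, sample_rate = 256, duration = 68,
                    band_amplitudes = c(delta = 0, theta = 0, alpha = 1,
                                        beta = 0),
                    noise_amplitude = 0.3, mixing = M, seed = 11)
  f <- bandpass(select_epochs(generate_recording(sp), 4, 15, Inf),
                band_definition("alpha"))
  expect_lt(mean_connectivity(pli(f)), 0.25)
  expect_lt(abs(mean_connectivity(aec_c(f)) - 0.5), 0.05)
  # uncorrected envelope correlation on the same data is clearly inflated
  raw_r <- mean(vapply(f$epochs, function(e) {
    env <- Mod(macroeeg:::analytic_rows(e))
    C <- cor(t(env))
    mean(C[upper.tri(C)])
  }, numeric(1)))
  expect_gt(raw_r, 0.3)
  # genuinely lagged coupling survives the same mixing
  spc <- signal_spec(n_channels = n, sample_rate = 256, duration = 68,
                     band_amplitudes = c(delta = 0, theta = 0, alpha = 1,
                                         beta = 0),
                     noise_amplitude = 0.3,
                     phase_coupling = data.frame(i = 1, j = 2,
                                                 band = "alpha",
                                                 strength = 0.9,
                                                 lag = pi / 2),
                     mixing = M, seed = 12)
  fc <- bandpass(select_epochs(generate_recording(spc), 4, 15, Inf),
                 band_definition("alpha"))
  expect_gt(pli(fc)$values[1, 2], 0.6)
})

test_that("mean connectivity averages the strict upper triangle", {
  v <- matrix(0.3, 5, 5)
  cm <- structure(list(values = v, metric = "PLI",
                       band = band_definition("alpha"),
                       labels = paste0("ch", 1:5)),
                  class = "eeg_connectivity")
  diag(cm$values) <- NA
  expect_equal(mean_connectivity(cm), 0.3)
  v64 <- matrix(0, 64, 64)
  v64[1, 2] <- v64[2, 1] <- 1
  cm64 <- structure(list(values = v64, metric = "PLI",
                         band = band_definition("alpha"),
                         labels = paste0("ch", 1:64)),
                    class = "eeg_connectivity")
  diag(cm64$values) <- NA
  expect_equal(sum(upper.tri(cm64$values)), 2016)
  expect_equal(mean_connectivity(cm64), 1 / 2016)
})
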