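test_that("average reference subtracts the instantaneous channel mean", {
  rec <- recording(rbind(c(1, 1, 1), c(3, 3, 3)), 1,
                   labels = c("a", "b"))
  ar <- average_reference(rec)
  expect_equal(ar$signals, rbind(a = c(-1, -1, -1), b = c(1, 1, 1)))
  expect_equal(ar$reference, "average")
  # idempotence and defining property on arbitrary input
  set.seed(1)
  rec2 <- recording(matrix(rnorm(5 * 100), 5), 100,
                    labels = paste0("ch", 1:5))
  ar2 <- average_reference(rec2)
  expect_lt(max(abs(colMeans(ar2$signals))), 1e-10)
  expect_equal(average_reference(ar2)$signals, ar2$signals)
  expect_error(average_reference(recording(matrix(1, 1, 10), 10,
                                           labels = "z")),
               "at least 2 channels")
})

test_that("downsampling anti-aliases and preserves passband content", {
  srate <- 2048
  t <- seq(0, 8 - 1 / srate, by = 1 / srate)
  rec <- recording(rbind(sin(2 * pi * 10 * t), sin(2 * pi * 900 * t)),
                   srate, labels = c("lo", "hi"))
  d <- downsample(rec, 1024)
  expect_equal(ncol(d$signals), 8192)
  expect_equal(d$sample_rate, 1024)
  # 10 Hz line survives: FFT peak of the output within 0.25 Hz
  ps <- power_spectrum(epoch_set(list(d$signals[, 1:4096, drop = FALSE]),
                                 4, 1024, c("lo", "hi")))
  expect_equal(ps$bin_low[which.max(ps$power)], 10)
  # amplitude preserved
  expect_equal(sd(d$signals[1, ]), sd(rec$signals[1, ]), tolerance = 0.01)
  # 900 Hz component suppressed below 1% of its input amplitude
  expect_lt(sd(d$signals[2, ]), 0.01 * sd(rec$signals[2, ]))
  expect_error(downsample(rec, 1000), "evenly")
})

test_that("spherical-spline interpolation recovers smooth fields", {
  m <- montage_1010(64)
  t <- seq(0, 1 - 1 / 128, by = 1 / 128)
  f1 <- m$positions[, 1] + 0.5 * m$positions[, 2] * m$positions[, 3]
  f2 <- m$positions[, 3]^2 - 0.3 * m$positions[, 1] * m$positions[, 2]
  X <- 40 * (outer(f1, sin(2 * pi * 3 * t)) + outer(f2, cos(2 * pi * 7 * t)))
  rec <- recording(X, 128)
  for (ch in c("Cz", "P3", "F8")) {
    truth <- rec$signals[ch, ]
    damaged <- rec
    damaged$signals[ch, ] <- 999
    fixed <- interpolate_channels(damaged, ch)
    expect_gt(cor(truth, fixed$signals[ch, ]), 0.9)
    # good channels untouched
    others <- setdiff(rec$labels, ch)
    expect_identical(fixed$signals[others, ], damaged$signals[others, ])
  }
  expect_identical(interpolate_channels(rec, character()), rec)
})

test_that("more than six bad channels excludes the subject", {
  rec <- recording(matrix(rnorm(64 * 50), 64), 50)
  cnd <- tryCatch(interpolate_channels(rec, rec$labels[1:7]),
                  condition = function(e) e)
  expect_s3_class(cnd, "macroeeg_exclusion")
  expect_match(conditionMessage(cnd), "excluded")
  # positions are mandatory
  bare <- recording(matrix(rnorm(3 * 50), 3), 50,
                    labels = c("x", "y", "z"))
  expect_error(interpolate_channels(bare, "x"), "positions")
})

test_that("epoch selection takes the first clean windows on a fixed grid", {
  srate <- 1024
  set.seed(2)
  rec <- recording(matrix(rnorm(2 * srate * 120, sd = 10), 2), srate,
                   labels = c("a", "b"))
  es <- select_epochs(rec, 4, 15, 100)
  expect_length(es$epochs, 15)
  expect_equal(attr(es, "starts"), (0:14) * 4096 + 1)   # first minute
  # a 500 uV transient in window 3 skips that window only
  dirty <- rec
  dirty$signals[1, 2 * 4096 + 100] <- 500
  es2 <- select_epochs(dirty, 4, 15, 100)
  expect_equal(attr(es2, "starts"), setdiff((0:15) * 4096 + 1, 2 * 4096 + 1))
  # too short: error reports the count found
  short <- recording(rec$signals[, 1:(40 * srate), drop = FALSE], srate,
                     labels = c("a", "b"))
  expect_error(select_epochs(short, 4, 15, 100), "10 clean epochs found")
})

test_that("epoch selection shifts consistently when windows are prepended", {
  srate <- 256
  set.seed(3)
  rec <- recording(matrix(rnorm(2 * srate * 80, sd = 10), 2), srate,
                   labels = c("a", "b"))
  base <- select_epochs(rec, 4, 10, 100)
  # prepend two whole windows of artifact: selection shifts by exactly 2 windows
  art <- matrix(rnorm(2 * srate * 8, sd = 300), 2)
  shifted <- recording(cbind(art, rec$signals), srate, labels = c("a", "b"))
  es <- select_epochs(shifted, 4, 10, 100)
  expect_equal(attr(es, "starts"), attr(base, "starts") + 2 * 4 * srate)
  expect_equal(es$epochs, base$epochs)
})

test_that("band-pass keeps in-band and rejects out-of-band amplitudes", {
  srate <- 256
  t <- seq(0, 4 - 1 / srate, by = 1 / srate)
  eps <- epoch_set(list(rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t))),
                   4, srate, c("a", "b"))
  inb <- bandpass(eps, band_definition("alpha"))
  keep <- 129:(1024 - 128)   # judge away from the wrap-around edges
  expect_equal(sd(inb$epochs[[1]][1, keep]), sd(eps$epochs[[1]][1, keep]),
               tolerance = 0.05)
  outb <- bandpass(eps, band_definition("beta"))
  expect_lt(sd(outb$epochs[[1]][1, keep]), 0.05 * sd(eps$epochs[[1]][1, keep]))
  # passband idempotence
  twice <- bandpass(inb, band_definition("alpha"))
  expect_equal(twice$epochs[[1]][, keep], inb$epochs[[1]][, keep],
               tolerance = 1e-6)
  expect_equal(inb$band$name, "alpha")
  expect_error(bandpass(eps, list(name = "beta", low = 13, high = 200)),
               "Nyquist")
  expect_error(band_definition("gamma"), "outside supported set")
})
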