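test_that("signal_spec validates its fields with named messages", {
  expect_error(signal_spec(duration = -1), "duration")
  expect_error(signal_spec(sample_rate = 0), "sample_rate")
  expect_error(signal_spec(duration = 1.003, sample_rate = 100),
               "integer sample count")
  expect_error(signal_spec(
    phase_coupling = data.frame(i = 1, j = 2, band = "alpha",
                                strength = 1.2, lag = 0)),
    "strength")
  expect_error(signal_spec(
    phase_coupling = data.frame(i = 1, j = 1, band = "alpha",
                                strength = 0.5, lag = 0)),
    "indices")
  expect_error(signal_spec(
    envelope_coupling = data.frame(i = 1, j = 2, band = "gamma", rho = 0.5)),
    "bands")
  expect_error(signal_spec(n_channels = 4, mixing = matrix(NA, 4, 4)),
               "mixing")
})

test_that("identical spec and seed give bit-identical recordings", {
  sp <- signal_spec(n_channels = 4, sample_rate = 256, duration = 2,
                    seed = 33)
  r1 <- generate_recording(sp)
  r2 <- generate_recording(sp)
  expect_identical(r1$signals, r2$signals)
  r3 <- generate_recording(signal_spec(n_channels = 4, sample_rate = 256,
                                       duration = 2, seed = 34))
  expect_false(identical(r1$signals, r3$signals))
})

test_that("fully phase-coupled pair reaches PLI 1, uncoupled pairs stay low", {
  alpha_only <- c(delta = 0, theta = 0, alpha = 1, beta = 0)
  sp <- signal_spec(n_channels = 4, sample_rate = 256, duration = 68,
                    band_amplitudes = alpha_only, noise_amplitude = 0,
                    phase_coupling = data.frame(i = 1, j = 2, band = "alpha",
                                                strength = 1, lag = pi / 2),
                    seed = 7)
  f <- bandpass(select_epochs(generate_recording(sp), 4, 15, Inf),
                band_definition("alpha"))
  cm <- pli(f)
  expect_gt(cm$values[1, 2], 0.999)

  # zero coupling everywhere: Monte-Carlo mean PLI over seeds is small and
  # shrinks with epoch length (consistent with an asymptotic zero)
  mean_pli_at <- function(epoch_s, seeds) {
    mean(vapply(seeds, function(s) {
      sp0 <- signal_spec(n_channels = 2, sample_rate = 128,
                         duration = 2 * epoch_s,
                         band_amplitudes = alpha_only, noise_amplitude = 0,
                         seed = s)
      f0 <- bandpass(select_epochs(generate_recording(sp0), epoch_s, 2, Inf),
                     band_definition("alpha"))
      pli(f0)$values[1, 2]
    }, numeric(1)))
  }
  short <- mean_pli_at(4, 1:20)
  long <- mean_pli_at(16, 1:20)
  expect_lt(long, short)
  expect_lt(long, 0.15)
})

test_that("planted phase coupling is recovered monotonically by PLI", {
  strengths <- seq(0, 1, by = 0.2)
  mean_pli <- vapply(strengths, function(st) {
    mean(vapply(1:10, function(s) {
      sp <- signal_spec(
        n_channels = 2, sample_rate = 256, duration = 36,
        band_amplitudes = c(delta = 0, theta = 0, alpha = 1, beta = 0),
        noise_amplitude = 0,
        phase_coupling = data.frame(i = 1, j = 2, band = "alpha",
                                    strength = st, lag = pi / 2),
        seed = 100 + s)
      f <- bandpass(select_epochs(generate_recording(sp), 4, 8, Inf),
                    band_definition("alpha"))
      pli(f)$values[1, 2]
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(strengths, mean_pli, method = "spearman"), 0.9)
})

test_that("cohort generator plants the requested group sizes and medians", {
  co <- generate_cohort(cohort_spec(62, 106, seed = 4))
  expect_equal(sum(co$features$group == "patient"), 62)
  expect_equal(sum(co$features$group == "control"), 106)
  expect_equal(nrow(co$clinical), 168)
  expect_setequal(setdiff(names(co$features), c("subject_id", "group")),
                  feature_vocabulary())

  big <- generate_cohort(cohort_spec(
    200, 200,
    effect_map = list(delta_relpower = c(shift = 0.084, control = 0.575)),
    seed = 9))
  mp <- median(big$features$delta_relpower[big$features$group == "patient"])
  mc <- median(big$features$delta_relpower[big$features$group == "control"])
  expect_lt(abs(mp - 0.659), 0.02)
  expect_lt(abs(mc - 0.575), 0.02)
  # relative powers still sum to one per subject
  rp <- as.matrix(big$features[, paste0(names(eeg_bands()), "_relpower")])
  expect_equal(rowSums(rp), rep(1, nrow(rp)), tolerance = 1e-12)
})

test_that("cohort generator rejects unknown feature names, listing the vocabulary", {
  expect_error(cohort_spec(10, 10, effect_map = list(nonsense = c(0.1, 0.5))),
               "alpha_mst_th_aecc")
  expect_error(panss_model(coef = c(bogus_feature = 1)), "valid names")
})

test_that("PANSS values are integers within instrument ranges", {
  co <- generate_cohort(cohort_spec(80, 10, seed = 12))
  cl <- co$clinical[co$clinical$group == "patient", ]
  for (col in c("panss_pos_baseline", "panss_neg_baseline")) {
    expect_true(all(cl[[col]] == round(cl[[col]])))
    expect_true(all(cl[[col]] >= 7 & cl[[col]] <= 49))
  }
  expect_true(all(cl$panss_gen_baseline >= 16 & cl$panss_gen_baseline <= 112))
  expect_equal(cl$panss_total_baseline,
               cl$panss_pos_baseline + cl$panss_neg_baseline +
                 cl$panss_gen_baseline)
  expect_true(all(is.na(
    co$clinical$panss_total_baseline[co$clinical$group == "control"])))
  # follow-up available for roughly the stated fraction
  expect_equal(sum(!is.na(cl$panss_total_followup)),
               round(80 * 45 / 62))
})

test_that("zero-coefficient symptom model yields non-significant forests", {
  ps <- vapply(1:10, function(s) {
    co <- generate_cohort(cohort_spec(
      62, 4, panss = panss_model(coef = numeric(0)), seed = 300 + s))
    dp <- delta_panss(co$clinical)
    ft <- co$features[match(dp$subject_id, co$features$subject_id), ]
    rf_regress_permute(ft, dp$d_pos, n_perm = 99, ntree = 50,
                       seed = s)$perm_p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})
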