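test_that("mtry follows the square-root rule", {
  expect_equal(mtry_rule(40), 6L)
  expect_equal(mtry_rule(60), 8L)
  expect_equal(mtry_rule(36), 6L)
})

test_that("noise screening keeps separating features and never the noise column", {
  kept <- vapply(1:20, function(s) {
    set.seed(s)
    X <- cbind(sep = rep(c(1, 0), each = 20) + rnorm(40, 0, 0.05),
               matrix(rnorm(40 * 9), 40, 9))
    scr <- noise_screen(X, rep(c("patient", "control"), each = 20),
                        ntree = 100, seed = s)
    expect_false(".noise" %in% scr$retained)
    "sep" %in% scr$retained
  }, logical(1))
  expect_true(all(kept))
})

test_that("balanced subsets have twice the minority size; confusion follows the
          patient-positive convention", {
  co <- generate_cohort(cohort_spec(62, 106, seed = 5))
  cl <- classify_balanced(co$features, co$features$group, n_subsets = 2,
                          ntree = 50, seed = 3, screen = FALSE)
  expect_equal(cl$per_subset$n, c(124, 124))

  # exactly separable feature with known mislabelled subjects:
  # 3 patients look like controls (false negatives), 1 control looks like a
  # patient (false positive)
  x <- c(rep(1, 17), rep(0, 3), rep(0, 19), 1)
  X <- cbind(a = x, b = x)
  lab <- rep(c("patient", "control"), each = 20)
  rep2 <- classify_balanced(X, lab, n_subsets = 2, ntree = 100, seed = 1,
                            screen = FALSE)
  expect_equal(rep2$per_subset$sensitivity, rep(17 / 20, 2))
  expect_equal(rep2$per_subset$specificity, rep(19 / 20, 2))
  expect_equal(rep2$per_subset$accuracy, rep(36 / 40, 2))
  expect_error(classify_balanced(X, rep("patient", 40)), "classes")
})

test_that("a strongly separated cohort is classified almost perfectly", {
  co <- generate_cohort(cohort_spec(
    40, 70,
    effect_map = list(alpha_pli = c(shift = -0.2, control = 0.45),
                      delta_relpower = c(shift = 0.15, control = 0.5)),
    seed = 6))
  cl <- classify_balanced(co$features, co$features$group, n_subsets = 5,
                          ntree = 200, seed = 7)
  expect_gt(cl$accuracy, 0.9)
  expect_equal(nrow(cl$per_subset), 5)
  expect_true(all(unlist(cl$per_subset[, c("accuracy", "sensitivity",
                                           "specificity")]) >= 0))
})

test_that("delta PANSS is follow-up minus baseline, dropping missing follow-ups", {
  clin <- data.frame(
    subject_id = c("P1", "P2", "P3"),
    panss_total_baseline = c(71.42, 70, 80),
    panss_pos_baseline = c(17.91, 20, 22),
    panss_neg_baseline = c(20, 20, 28),
    panss_gen_baseline = c(33.51, 30, 30),
    panss_total_followup = c(57.56, 70, NA),
    panss_pos_followup = c(12.73, 20, NA),
    panss_neg_followup = c(18, 20, NA),
    panss_gen_followup = c(26.83, 30, NA))
  dp <- delta_panss(clin)
  expect_equal(nrow(dp), 2)
  expect_equal(dp$d_total[1], -13.86)
  expect_equal(dp$d_pos[1], -5.18)
  expect_equal(dp$d_total[2], 0)
  expect_equal(attr(dp, "n_excluded"), 1)
  expect_error(delta_panss(clin[, -3]), "panss_pos_baseline")
})

test_that("regression forests recover a planted linear outcome and its drivers", {
  top3 <- vapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(45 * 10), 45, 10)
    colnames(X) <- paste0("f", 1:10)
    y <- 2 * X[, 1] - 2 * X[, 2] + 1.5 * X[, 3] + rnorm(45, 0, 0.5)
    r <- rf_regress_permute(X, y, n_perm = 0, ntree = 100, seed = s)
    sum(head(r$vimp$feature, 3) %in% c("f1", "f2", "f3"))
  }, numeric(1))
  expect_gte(mean(top3), 2)

  # permutation p can never be zero and runs are exactly reproducible
  set.seed(1)
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- X[, 1] + rnorm(30, 0, 0.3)
  r1 <- rf_regress_permute(X, y, n_perm = 49, ntree = 50, seed = 11)
  r2 <- rf_regress_permute(X, y, n_perm = 49, ntree = 50, seed = 11)
  expect_gt(r1$perm_p, 0)
  expect_equal(r1$perm_p, 1 / 50, tolerance = 1e-12)
  expect_identical(r1$r2_cv, r2$r2_cv)
  expect_identical(r1$vimp, r2$vimp)
  expect_equal(r1$mtry, 2)
  expect_error(rf_regress_permute(X, rep(1, 30), n_perm = 0), "constant")
  expect_error(rf_regress_permute(X, c(NA, rnorm(29)), n_perm = 0), "NA")
})

test_that("classifier and screening derive everything from the master seed", {
  co <- generate_cohort(cohort_spec(30, 50, seed = 8))
  a <- classify_balanced(co$features, co$features$group, n_subsets = 2,
                         ntree = 50, seed = 99)
  b <- classify_balanced(co$features, co$features$group, n_subsets = 2,
                         ntree = 50, seed = 99)
  expect_identical(a$per_subset, b$per_subset)
  expect_identical(a$retained, b$retained)
  c2 <- classify_balanced(co$features, co$features$group, n_subsets = 2,
                          ntree = 50, seed = 100)
  expect_false(identical(a$per_subset, c2$per_subset))
})
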