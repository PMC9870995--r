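# Random-forest models: balanced patient-control classification with
# noise-feature screening, and permutation-validated regression of symptom
# change. The forest itself is the package's compiled CART implementation
# (see src/forest.cpp); every random element (subset draws, noise column,
# fold assignment, tree randomness, outcome permutations) derives from one
# master seed, so runs are exactly reproducible.

# pull the numeric feature columns out of a feature table
feature_matrix <- function(ft) {
  if (is.matrix(ft)) {
    if (is.null(colnames(ft)))
      colnames(ft) <- paste0("f", seq_len(ncol(ft)))
    return(ft)
  }
  known <- intersect(feature_vocabulary(), names(ft))
  cols <- if (length(known)) known else
    names(ft)[vapply(ft, is.numeric, logical(1))]
  as.matrix(ft[, cols, drop = FALSE])
}

# stratified (optional) fold assignment
rf_folds <- function(n, k, seed, strata = NULL) {
  with_seed(seed, {
    fold <- integer(n)
    if (is.null(strata)) strata <- rep(1L, n)
    for (s in unique(strata)) {
      i <- which(strata == s)
      fold[i] <- sample(rep_len(seq_len(k), length(i)))
    }
    fold
  })
}

# 0/1 encoding with an explicit positive class
encode_labels <- function(labels, positive) {
  labels <- as.character(labels)
  if (length(unique(labels)) != 2)
    stop("exactly two classes required", call. = FALSE)
  if (!positive %in% labels)
    stop(sprintf("positive class '%s' absent from labels", positive),
         call. = FALSE)
  as.numeric(labels == positive)
}

#' mtry rule
#'
#' Square root of the feature count, rounded to the nearest integer
#' (so 40 features give 6 and 60 give 8).
#'
#' @param p number of features.
#' @return integer mtry.
#' @export
mtry_rule <- function(p) as.integer(round(sqrt(p)))

#' Noise-feature screening
#'
#' Appends one uniform-random noise column, fits a forest, and drops every
#' feature whose out-of-bag permutation importance is less than or equal to
#' the noise feature's importance. The noise feature itself is never
#' retained (the rule is `<=`, so it cannot pass its own bar).
#'
#' @param X feature matrix or table.
#' @param y outcome: a two-level factor/character (classification, with
#'   `positive` naming the positive class) or numeric (regression).
#' @param ntree trees per forest.
#' @param seed integer seed (noise column + forest randomness).
#' @param positive positive class for classification.
#' @return list: `retained` (feature names), `vimp` (named importance
#'   vector including `".noise"`), `noise_vimp`.
#' @export
noise_screen <- function(X, y, ntree = 500, seed = 1, positive = "patient") {
  X <- feature_matrix(X)
  if (ncol(X) < 2) stop("need at least 2 features", call. = FALSE)
  classify <- !is.numeric(y)
  yv <- if (classify) encode_labels(y, positive) else as.numeric(y)
  sds <- derive_seeds(seed, 2)
  noise <- with_seed(sds[1], runif(nrow(X)))
  Xn <- cbind(X, .noise = noise)
  fit <- cpp_rf(Xn, yv, matrix(0, 0, ncol(Xn)), ntree,
                mtry_rule(ncol(Xn)), if (classify) 1L else 5L,
                classify, TRUE, as.double(sds[2]))
  v <- setNames(fit$vimp, colnames(Xn))
  retained <- setdiff(names(v)[v > v[".noise"]], ".noise")
  if (!length(retained))
    stop("noise screening dropped all features; inspect the data",
         call. = FALSE)
  list(retained = retained, vimp = v, noise_vimp = unname(v[".noise"]))
}

#' Balanced random-forest classification
#'
#' Handles class imbalance by repeated balanced subsetting: for each of
#' `n_subsets` rounds, all minority-class subjects are paired with an
#' equally sized random draw (without replacement) from the majority class;
#' noise-feature screening is refit within the round; a forest with
#' `mtry = round(sqrt(k))` over the `k` retained features is evaluated by
#' stratified tenfold cross-validation; accuracy, sensitivity and
#' specificity (positive class = patients) are recorded and finally averaged
#' across rounds.
#'
#' @param ft feature table or matrix.
#' @param labels two-class labels, one per row.
#' @param n_subsets number of balanced rounds (default 10).
#' @param ntree trees per forest (default 500).
#' @param seed master seed.
#' @param positive positive class (default `"patient"`).
#' @param screen apply noise screening per round (default TRUE).
#' @param k_folds cross-validation folds (default 10).
#' @return object of class `rf_classifier_report`: `per_subset` data frame,
#'   `accuracy`/`sensitivity`/`specificity` means, `retained` (list per
#'   round), `vimp` (mean importance of ever-retained features), `mtry`
#'   (per round).
#' @export
classify_balanced <- function(ft, labels, n_subsets = 10, ntree = 500,
                              seed = 1, positive = "patient", screen = TRUE,
                              k_folds = 10) {
  X <- feature_matrix(ft)
  labels <- as.character(labels)
  if (length(labels) != nrow(X))
    stop("one label per subject required", call. = FALSE)
  if (length(unique(labels)) != 2)
    stop("both classes must be present", call. = FALSE)
  tab <- table(labels)
  minority <- names(tab)[which.min(tab)]
  majority <- setdiff(names(tab), minority)
  s <- min(tab)
  if (s < 10) stop("minority class must have at least 10 subjects",
                   call. = FALSE)
  sds <- derive_seeds(seed, 4 * n_subsets)
  rows <- list(); retained_all <- list(); vimps <- list()
  for (b in seq_len(n_subsets)) {
    maj_pick <- with_seed(sds[4 * b - 3],
                          sample(which(labels == majority), s))
    idx <- c(which(labels == minority), maj_pick)
    Xs <- X[idx, , drop = FALSE]
    ys <- encode_labels(labels[idx], positive)
    keep <- colnames(Xs)
    vim <- NULL
    if (screen) {
      # if no feature beats the noise column (can happen by chance when no
      # real signal exists) fall back to the full feature set for this round
      scr <- tryCatch(
        noise_screen(Xs, labels[idx], ntree = ntree,
                     seed = sds[4 * b - 2], positive = positive),
        error = function(e) NULL)
      if (!is.null(scr)) {
        keep <- scr$retained
        vim <- scr$vimp[keep]
      }
    }
    Xk <- Xs[, keep, drop = FALSE]
    mtry <- mtry_rule(length(keep))
    fold <- rf_folds(nrow(Xk), k_folds, sds[4 * b - 1], strata = ys)
    pred <- cpp_rf_cv(Xk, ys, fold, ntree, mtry, 1L,
                      as.double(sds[4 * b]))
    cls <- as.numeric(pred >= 0.5)
    tp <- sum(cls == 1 & ys == 1); tn <- sum(cls == 0 & ys == 0)
    fn <- sum(cls == 0 & ys == 1); fp <- sum(cls == 1 & ys == 0)
    rows[[b]] <- data.frame(
      subset = b, n = length(idx), n_retained = length(keep), mtry = mtry,
      accuracy = (tp + tn) / length(idx),
      sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
    retained_all[[b]] <- keep
    if (!is.null(vim)) vimps[[b]] <- vim
  }
  per_subset <- do.call(rbind, rows)
  vimp <- NULL
  if (length(vimps)) {
    all_f <- unique(unlist(lapply(vimps, names)))
    vv <- vapply(all_f, function(f)
      mean(unlist(lapply(vimps, function(v) v[f])), na.rm = TRUE),
      numeric(1))
    vimp <- sort(vv, decreasing = TRUE)
  }
  structure(list(per_subset = per_subset,
                 accuracy = mean(per_subset$accuracy),
                 sensitivity = mean(per_subset$sensitivity),
                 specificity = mean(per_subset$specificity),
                 retained = retained_all, vimp = vimp,
                 positive = positive, ntree = ntree, seed = seed),
            class = "rf_classifier_report")
}

#' @export
print.rf_classifier_report <- function(x, ...) {
  cat(sprintf(paste0("<rf_classifier_report> %d balanced subsets: mean ",
                     "accuracy %.3f, sensitivity %.3f, specificity %.3f ",
                     "(positive = %s)\n"),
              nrow(x$per_subset), x$accuracy, x$sensitivity, x$specificity,
              x$positive))
  invisible(x)
}

#' PANSS change scores
#'
#' Computes follow-up minus baseline for the total score and the three
#' subscales; negative values mean improvement. Subjects without follow-up
#' scores are excluded and their count reported in the `"n_excluded"`
#' attribute.
#'
#' @param clinical clinical table with
#'   `panss_{total,pos,neg,gen}_{baseline,followup}` columns.
#' @return data frame `subject_id`, `d_total`, `d_pos`, `d_neg`, `d_gen`.
#' @export
delta_panss <- function(clinical) {
  need <- as.vector(outer(c("panss_total_", "panss_pos_", "panss_neg_",
                            "panss_gen_"), c("baseline", "followup"),
                          paste0))
  miss <- setdiff(need, names(clinical))
  if (length(miss))
    stop(sprintf("clinical table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  has_fu <- !is.na(clinical$panss_total_followup)
  if (any(has_fu & is.na(clinical$panss_total_baseline)))
    stop("baseline scores required for subjects with follow-up",
         call. = FALSE)
  out <- data.frame(
    subject_id = clinical$subject_id[has_fu],
    d_total = clinical$panss_total_followup[has_fu] -
      clinical$panss_total_baseline[has_fu],
    d_pos = clinical$panss_pos_followup[has_fu] -
      clinical$panss_pos_baseline[has_fu],
    d_neg = clinical$panss_neg_followup[has_fu] -
      clinical$panss_neg_baseline[has_fu],
    d_gen = clinical$panss_gen_followup[has_fu] -
      clinical$panss_gen_baseline[has_fu],
    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!has_fu &
                                   !is.na(clinical$panss_total_baseline))
  out
}

#' Permutation-validated random-forest regression
#'
#' Fits a regression forest (`mtry = round(sqrt(p))` by default) evaluated
#' by tenfold cross-validation. The observed statistic is the CV R-squared,
#' `1 - SSE/SST` over the pooled out-of-fold predictions; RMSE and
#' R-squared are additionally summarized as mean and SD over folds. The
#' outcome is then permuted `n_perm` times (fresh fold assignment each
#' time) and the one-sided permutation p value is
#' `(1 + #\{R2_perm >= R2_obs\}) / (n_perm + 1)` -- it can never be zero.
#' Variable importance is OOB permutation importance from a forest on the
#' full data, rescaled so the top feature scores 100.
#'
#' @param ft feature table or matrix (subjects with an outcome only).
#' @param outcome numeric outcome, one value per row of `ft`.
#' @param n_perm number of permutations (default 1000).
#' @param ntree trees per forest (default 500).
#' @param seed master seed.
#' @param mtry features tried per split; default `round(sqrt(p))`.
#' @param k_folds cross-validation folds (default 10).
#' @param screen apply noise screening first (default FALSE: all features
#'   enter the regression).
#' @param outcome_name label carried into the report.
#' @return object of class `rf_regression_report`.
#' @export
rf_regress_permute <- function(ft, outcome, n_perm = 1000, ntree = 500,
                               seed = 1, mtry = NULL, k_folds = 10,
                               screen = FALSE, outcome_name = "outcome") {
  X <- feature_matrix(ft)
  y <- as.numeric(outcome)
  if (length(y) != nrow(X)) stop("one outcome per row required", call. = FALSE)
  if (anyNA(y)) stop("outcome contains NA; drop those subjects first",
                     call. = FALSE)
  if (nrow(X) < 10) stop("need at least 10 subjects", call. = FALSE)
  if (sd(y) == 0) stop("constant outcome", call. = FALSE)
  sds <- derive_seeds(seed, 4 + 2 * n_perm)
  if (screen) {
    scr <- noise_screen(X, y, ntree = ntree, seed = sds[1])
    X <- X[, scr$retained, drop = FALSE]
  }
  p <- ncol(X)
  if (is.null(mtry)) mtry <- mtry_rule(p)

  cv_r2 <- function(yv, fold_seed, forest_seed) {
    fold <- rf_folds(length(yv), k_folds, fold_seed)
    pred <- cpp_rf_cv(X, yv, fold, ntree, mtry, 5L, as.double(forest_seed))
    sse <- sum((yv - pred)^2)
    sst <- sum((yv - mean(yv))^2)
    list(r2 = 1 - sse / sst, pred = pred, fold = fold)
  }

  obs <- cv_r2(y, sds[2], sds[3])
  fold_stats <- t(vapply(seq_len(max(obs$fold)), function(f) {
    i <- obs$fold == f
    sst_f <- sum((y[i] - mean(y[i]))^2)
    c(rmse = sqrt(mean((y[i] - obs$pred[i])^2)),
      r2 = if (sst_f > 0) 1 - sum((y[i] - obs$pred[i])^2) / sst_f
           else NA_real_)
  }, numeric(2)))

  n_ge <- 0L
  for (b in seq_len(n_perm)) {
    yb <- with_seed(sds[3 + 2 * b], sample(y))
    rb <- cv_r2(yb, sds[4 + 2 * b], sds[4 + 2 * b])$r2
    if (rb >= obs$r2) n_ge <- n_ge + 1L
  }
  perm_p <- (1 + n_ge) / (n_perm + 1)

  fit <- cpp_rf(X, y, matrix(0, 0, p), ntree, mtry, 5L, FALSE, TRUE,
                as.double(sds[4]))
  v <- setNames(fit$vimp, colnames(X))
  scaled <- if (max(v) > 0) 100 * pmax(v, 0) / max(v) else v * 0
  vimp <- data.frame(feature = names(v), vimp = unname(v),
                     scaled = unname(scaled), stringsAsFactors = FALSE)
  vimp <- vimp[order(-vimp$vimp), ]
  rownames(vimp) <- NULL

  structure(list(outcome = outcome_name, n = nrow(X), p = p, mtry = mtry,
                 ntree = ntree, n_perm = n_perm,
                 r2_cv = obs$r2,
                 r2_mean = mean(fold_stats[, "r2"], na.rm = TRUE),
                 r2_sd = sd(fold_stats[, "r2"], na.rm = TRUE),
                 rmse_mean = mean(fold_stats[, "rmse"]),
                 rmse_sd = sd(fold_stats[, "rmse"]),
                 perm_p = perm_p, vimp = vimp, seed = seed),
            class = "rf_regression_report")
}

#' @export
print.rf_regression_report <- function(x, ...) {
  cat(sprintf(paste0("<rf_regression_report> %s: n = %d, mtry = %d, ",
                     "CV R2 = %.3f (fold mean %.2f, SD %.2f), RMSE %.2f ",
                     "(%.2f), permutation p = %.4g [%d permutations]\n"),
              x$outcome, x$n, x$mtry, x$r2_cv, x$r2_mean, x$r2_sd,
              x$rmse_mean, x$rmse_sd, x$perm_p, x$n_perm))
  invisible(x)
}
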