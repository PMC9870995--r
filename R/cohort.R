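#' Symptom-trajectory model for synthetic cohorts
#'
#' Baseline PANSS subscale scores are drawn as rounded, range-clipped
#' normals (defaults from a first-episode psychosis cohort: positive 18.6
#' (4.4), negative 18.5 (7.0), general 37.5 (9.0); the total is their sum).
#' The positive-subscale change at follow-up is generated by a linear link
#' on z-scored features, `delta_pos = mean + Z beta + noise`; negative and
#' general changes are feature-independent normals. PANSS values are
#' integers clipped to the instrument's valid ranges (positive/negative
#' 7--49, general 16--112).
#'
#' @param baseline_mean,baseline_sd named (`positive`, `negative`,
#'   `general`) baseline moments.
#' @param delta_mean named mean change (follow-up minus baseline; negative
#'   means improvement).
#' @param delta_sd named SDs of the feature-independent changes
#'   (`negative`, `general`).
#' @param coef named coefficient vector of the linear link from z-scored
#'   features to the positive-subscale change; names must come from
#'   [feature_vocabulary()]. The default plants a weak link (about 20%
#'   explained variance) on three network features.
#' @param noise_sd residual SD of the positive-subscale change (> 0).
#' @param followup_fraction fraction of patients with follow-up scores.
#' @return list of class `panss_model`.
#' @export
panss_model <- function(baseline_mean = c(positive = 18.57, negative = 18.47,
                                          general = 37.50),
                        baseline_sd = c(positive = 4.38, negative = 6.99,
                                        general = 9.01),
                        delta_mean = c(positive = -5.18, negative = -1.25,
                                       general = -7.44),
                        delta_sd = c(negative = 5, general = 6),
                        coef = c(alpha_mst_th_aecc = -1, beta_pli = -1,
                                 delta_mst_bcmax_pli = -1),
                        noise_sd = 3.5,
                        followup_fraction = 45 / 62) {
  check_scalar_number(noise_sd, "noise_sd", positive = TRUE)
  if (length(coef)) {
    bad <- setdiff(names(coef), feature_vocabulary())
    if (length(bad))
      stop(sprintf("unknown feature name(s) in 'coef': %s\nvalid names:\n%s",
                   paste(bad, collapse = ", "),
                   paste(feature_vocabulary(), collapse = ", ")),
           call. = FALSE)
  }
  structure(list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 delta_mean = delta_mean, delta_sd = delta_sd, coef = coef,
                 noise_sd = noise_sd, followup_fraction = followup_fraction),
            class = "panss_model")
}

#' Specification of a synthetic feature-level cohort
#'
#' Generates subjects directly at the level of the 60-feature vector (all
#' features live in `[0, 1]`) with controllable group effects: each feature
#' is drawn logit-normally around a control median, and `effect_map` shifts
#' the patient median of chosen features. Because the logit-normal median
#' equals the stated median exactly, planted medians are achieved in
#' expectation without calibration.
#'
#' Relative-power features are kept summing to one per subject by anchoring
#' one relative-power feature (the planted one, or delta by default) and
#' scaling the remaining three to the complement; at most one
#' relative-power feature can therefore be planted per cohort.
#'
#' @param n_patients,n_controls group sizes (each >= 2).
#' @param effect_map named list, feature name -> `c(shift, control)`:
#'   control-group median and additive patient shift of that median.
#' @param panss a [panss_model()].
#' @param sigma_logit spread of features on the logit scale (default 0.25).
#' @param seed integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, n_controls, effect_map = list(),
                        panss = panss_model(), sigma_logit = 0.25,
                        seed = 1) {
  if (n_patients < 2 || n_controls < 2)
    stop("n_patients and n_controls must both be >= 2", call. = FALSE)
  if (length(effect_map)) {
    bad <- setdiff(names(effect_map), feature_vocabulary())
    if (length(bad))
      stop(sprintf(
        "unknown feature name(s) in 'effect_map': %s\nvalid names:\n%s",
        paste(bad, collapse = ", "),
        paste(feature_vocabulary(), collapse = ", ")), call. = FALSE)
    rp <- grep("_relpower$", names(effect_map), value = TRUE)
    if (length(rp) > 1)
      stop("at most one relative-power feature may be planted", call. = FALSE)
  }
  stopifnot(inherits(panss, "panss_model"))
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 effect_map = effect_map, panss = panss,
                 sigma_logit = sigma_logit, seed = as.integer(seed)),
            class = "cohort_spec")
}

# control-group feature medians: delta relative power from the reference
# cohort, everything else a documented convention (see methods vignette)
default_feature_medians <- function() {
  med <- numeric(0)
  rp <- c(delta = 0.575, theta = 0.115, alpha = 0.225, beta = 0.085)
  pli_m <- c(delta = 0.20, theta = 0.15, alpha = 0.28, beta = 0.10)
  aec_m <- c(delta = 0.55, theta = 0.54, alpha = 0.60, beta = 0.53)
  mst_m <- c(kmax = 0.15, leaf = 0.62, diameter = 0.28, bcmax = 0.75,
             ecc = 0.155, th = 0.38)
  for (b in names(eeg_bands())) {
    med[paste0(b, "_relpower")] <- rp[[b]]
    med[paste0(b, "_pli")] <- pli_m[[b]]
    med[paste0(b, "_aecc")] <- aec_m[[b]]
    for (basis in c("pli", "aecc"))
      med[paste0(b, "_mst_", names(mst_m), "_", basis)] <- mst_m
  }
  med[feature_vocabulary()]
}

#' Generate a synthetic cohort (feature table + clinical table)
#'
#' @param spec a [cohort_spec()].
#' @return list with `features` (one row per subject: `subject_id`, `group`,
#'   60 feature columns) and `clinical` (`subject_id`, `group`,
#'   `panss_{total,pos,neg,gen}_{baseline,followup}`; follow-up is `NA` for
#'   controls and for patients without follow-up).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    vocab <- feature_vocabulary()
    base_med <- default_feature_medians()
    rp_all <- paste0(names(eeg_bands()), "_relpower")
    planted_rp <- grep("_relpower$", names(spec$effect_map), value = TRUE)
    anchor <- if (length(planted_rp)) planted_rp else "delta_relpower"

    draw_group <- function(n, is_patient) {
      med <- base_med
      for (f in names(spec$effect_map)) {
        eff <- spec$effect_map[[f]]
        pick <- function(nm, pos)
          if (!is.null(names(eff)) && nm %in% names(eff)) eff[[nm]]
          else eff[[pos]]
        med[f] <- pick("control", 2)
        if (is_patient) med[f] <- med[f] + pick("shift", 1)
      }
      if (any(med <= 0 | med >= 1))
        stop("planted medians must stay inside (0, 1)", call. = FALSE)
      X <- matrix(NA_real_, n, length(vocab),
                  dimnames = list(NULL, vocab))
      # anchored relative power: exact median by logit-normal construction
      X[, anchor] <- plogis(qlogis(med[anchor]) +
                              spec$sigma_logit * rnorm(n))
      others <- setdiff(rp_all, anchor)
      W <- sapply(others, function(f)
        med[f] * exp(spec$sigma_logit * rnorm(n)))
      X[, others] <- (1 - X[, anchor]) * W / rowSums(W)
      rest <- setdiff(vocab, rp_all)
      for (f in rest)
        X[, f] <- plogis(qlogis(med[f]) + spec$sigma_logit * rnorm(n))
      X
    }

    Xp <- draw_group(spec$n_patients, TRUE)
    Xc <- draw_group(spec$n_controls, FALSE)
    ids <- c(sprintf("P%03d", seq_len(spec$n_patients)),
             sprintf("C%03d", seq_len(spec$n_controls)))
    group <- rep(c("patient", "control"),
                 c(spec$n_patients, spec$n_controls))
    features <- data.frame(subject_id = ids, group = group,
                           rbind(Xp, Xc), stringsAsFactors = FALSE)

    # clinical trajectories (patients only)
    pm <- spec$panss
    np <- spec$n_patients
    rint <- function(n, m, s, lo, hi) as.integer(round(clip(rnorm(n, m, s),
                                                            lo, hi)))
    pos0 <- rint(np, pm$baseline_mean[["positive"]],
                 pm$baseline_sd[["positive"]], 7, 49)
    neg0 <- rint(np, pm$baseline_mean[["negative"]],
                 pm$baseline_sd[["negative"]], 7, 49)
    gen0 <- rint(np, pm$baseline_mean[["general"]],
                 pm$baseline_sd[["general"]], 16, 112)
    link <- rep(0, np)
    if (length(pm$coef)) {
      Z <- scale(Xp[, names(pm$coef), drop = FALSE])
      Z[is.nan(Z)] <- 0
      link <- as.vector(Z %*% pm$coef)
    }
    dpos <- pm$delta_mean[["positive"]] + link + rnorm(np, 0, pm$noise_sd)
    dneg <- rnorm(np, pm$delta_mean[["negative"]], pm$delta_sd[["negative"]])
    dgen <- rnorm(np, pm$delta_mean[["general"]], pm$delta_sd[["general"]])
    pos1 <- as.integer(round(clip(pos0 + dpos, 7, 49)))
    neg1 <- as.integer(round(clip(neg0 + dneg, 7, 49)))
    gen1 <- as.integer(round(clip(gen0 + dgen, 16, 112)))
    has_fu <- seq_len(np) %in%
      sample(np, round(pm$followup_fraction * np))
    pos1[!has_fu] <- NA_integer_
    neg1[!has_fu] <- NA_integer_
    gen1[!has_fu] <- NA_integer_

    na_int <- rep(NA_integer_, spec$n_controls)
    clinical <- data.frame(
      subject_id = ids, group = group,
      panss_total_baseline = c(pos0 + neg0 + gen0, na_int),
      panss_pos_baseline = c(pos0, na_int),
      panss_neg_baseline = c(neg0, na_int),
      panss_gen_baseline = c(gen0, na_int),
      panss_total_followup = c(pos1 + neg1 + gen1, na_int),
      panss_pos_followup = c(pos1, na_int),
      panss_neg_followup = c(neg1, na_int),
      panss_gen_followup = c(gen1, na_int),
      stringsAsFactors = FALSE)
    list(features = features, clinical = clinical)
  })
}
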