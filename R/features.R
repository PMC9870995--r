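#' The closed 60-feature vocabulary
#'
#' Per band (delta, theta, alpha, beta): relative power, mean PLI, mean
#' AEC-c, and the six MST measures computed on the PLI- and on the
#' AEC-c-based tree -- 15 features per band, 60 in total. Names follow
#' `band_metric[_basis]`, e.g. `alpha_relpower`, `beta_pli`,
#' `alpha_mst_th_aecc`.
#'
#' @param band optionally restrict to one band name.
#' @return character vector of feature names.
#' @export
feature_vocabulary <- function(band = NULL) {
  bands <- band %||% names(eeg_bands())
  mst <- c("kmax", "leaf", "diameter", "bcmax", "ecc", "th")
  unlist(lapply(bands, function(b) {
    c(paste0(b, "_relpower"), paste0(b, "_pli"), paste0(b, "_aecc"),
      paste0(b, "_mst_", mst, "_pli"), paste0(b, "_mst_", mst, "_aecc"))
  }), use.names = FALSE)
}

#' Pipeline configuration for feature extraction
#'
#' @param epoch_length_s epoch length in seconds.
#' @param n_epochs number of clean epochs required.
#' @param target_rate_hz rate to downsample to before epoching (skipped when
#'   the recording is already at or below this rate).
#' @param amplitude_limit_uv artifact rejection threshold in microvolts.
#' @param max_interpolated_channels subject-exclusion cutoff.
#' @param edge_margin per-epoch edge fraction discarded by the connectivity
#'   metrics.
#' @return a named list of class `feature_config`.
#' @export
feature_config <- function(epoch_length_s = 4, n_epochs = 15,
                           target_rate_hz = 1024, amplitude_limit_uv = 100,
                           max_interpolated_channels = 6,
                           edge_margin = 1 / 8) {
  structure(list(epoch_length_s = epoch_length_s, n_epochs = n_epochs,
                 target_rate_hz = target_rate_hz,
                 amplitude_limit_uv = amplitude_limit_uv,
                 max_interpolated_channels = max_interpolated_channels,
                 edge_margin = edge_margin),
            class = "feature_config")
}

#' Extract the 60 macroscale features from one recording
#'
#' Runs the fixed pipeline: average reference, downsampling, optional
#' spherical-spline interpolation of bad channels, selection of the first
#' `n_epochs` clean epochs, then per band: band-pass filtering, PLI and
#' AEC-c matrices with their whole-brain means, and the six MST measures on
#' each matrix; relative band power comes from the broadband epochs.
#'
#' @param rec an [recording()].
#' @param config a [feature_config()].
#' @param bad_channels labels of channels to interpolate before epoching.
#' @return named numeric vector of 60 features, with a `"provenance"`
#'   attribute (data frame: feature, band, metric, basis).
#' @export
extract_features <- function(rec, config = feature_config(),
                             bad_channels = character()) {
  stopifnot(inherits(rec, "eeg_recording"))
  rec <- average_reference(rec)
  if (rec$sample_rate > config$target_rate_hz &&
      abs(rec$sample_rate / config$target_rate_hz -
          round(rec$sample_rate / config$target_rate_hz)) < 1e-9)
    rec <- downsample(rec, config$target_rate_hz)
  rec <- interpolate_channels(rec, bad_channels,
                              max_bad = config$max_interpolated_channels)
  eps <- select_epochs(rec, config$epoch_length_s, config$n_epochs,
                       config$amplitude_limit_uv)

  relp <- relative_band_power(power_spectrum(eps))
  out <- numeric(0)
  for (b in names(eeg_bands())) {
    bd <- band_definition(b)
    f_eps <- bandpass(eps, bd)
    cm_pli <- pli(f_eps, config$edge_margin)
    cm_aec <- aec_c(f_eps, config$edge_margin)
    m_pli <- mst_metrics(build_mst(cm_pli))
    m_aec <- mst_metrics(build_mst(cm_aec))
    v <- c(relp[[b]], mean_connectivity(cm_pli), mean_connectivity(cm_aec),
           unlist(m_pli, use.names = FALSE), unlist(m_aec, use.names = FALSE))
    out <- c(out, v)
  }
  names(out) <- feature_vocabulary()
  attr(out, "provenance") <- feature_provenance()
  out
}

feature_provenance <- function() {
  nm <- feature_vocabulary()
  band <- sub("_.*$", "", nm)
  metric <- ifelse(grepl("_mst_", nm),
                   paste0("mst_", sub("^.*_mst_([a-z]+)_.*$", "\\1", nm)),
                   sub("^[a-z]+_", "", nm))
  basis <- ifelse(grepl("_mst_.*_pli$", nm), "pli",
                  ifelse(grepl("_mst_.*_aecc$", nm), "aecc", NA))
  data.frame(feature = nm, band = band, metric = metric, basis = basis,
             stringsAsFactors = FALSE)
}

#' Build a cohort feature table from recordings
#'
#' One row per subject; subjects whose preprocessing raises an exclusion
#' (too many bad channels, too few clean epochs) are dropped and listed in
#' the `"exclusions"` attribute together with the triggering rule. An
#' optional clinical table is joined by `subject_id`; subjects missing from
#' it keep their EEG row with clinical fields set to `NA`.
#'
#' @param recordings named list of [recording()] objects (names are subject
#'   IDs).
#' @param clinical optional data frame with a `subject_id` column.
#' @param config a [feature_config()].
#' @param bad_channels optional named list: subject ID -> channel labels to
#'   interpolate.
#' @return data frame with `subject_id` plus the 60 features (and clinical
#'   columns when supplied); attribute `"exclusions"` is a data frame
#'   (`subject_id`, `rule`).
#' @export
build_feature_table <- function(recordings, clinical = NULL,
                                config = feature_config(),
                                bad_channels = list()) {
  if (!length(recordings)) stop("empty recording list", call. = FALSE)
  ids <- names(recordings)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("'recordings' must be a named list (subject IDs)", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate subject IDs", call. = FALSE)

  rows <- list()
  excl <- data.frame(subject_id = character(0), rule = character(0))
  for (id in ids) {
    fv <- tryCatch(
      extract_features(recordings[[id]], config,
                       bad_channels[[id]] %||% character()),
      macroeeg_exclusion = function(e) e)
    if (is_exclusion(fv)) {
      excl <- rbind(excl, data.frame(
        subject_id = id,
        rule = fv$rule %||% conditionMessage(fv)))
    } else {
      rows[[id]] <- fv
    }
  }
  if (!length(rows))
    stop("all subjects excluded during preprocessing", call. = FALSE)
  ft <- as.data.frame(do.call(rbind, rows))
  ft <- cbind(subject_id = names(rows), ft, stringsAsFactors = FALSE)
  rownames(ft) <- NULL
  if (!is.null(clinical)) {
    if (!"subject_id" %in% names(clinical))
      stop("clinical table needs a 'subject_id' column", call. = FALSE)
    ft <- merge(ft, clinical, by = "subject_id", all.x = TRUE, sort = FALSE)
  }
  attr(ft, "exclusions") <- excl
  ft
}
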