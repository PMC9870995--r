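#' Pipeline configuration
#'
#' A declarative description of one full analysis run: the data source
#' (either a synthetic [cohort_spec()] or a directory of EDF/BDF recordings
#' with a clinical CSV), the preprocessing parameters, the analysis bands
#' and the model parameters. The configuration is hashed (MD5 of its JSON
#' serialization) and the hash is stamped into every output file.
#'
#' @param out_dir output directory (created if needed).
#' @param cohort optional [cohort_spec()] for a feature-level synthetic run.
#' @param input_dir optional directory of `.edf`/`.bdf` recordings (file
#'   stem = subject ID).
#' @param clinical_csv optional CSV with `subject_id`, `group` and
#'   `panss_{total,pos,neg,gen}_{baseline,followup}` columns.
#' @param bands band names to analyse; must come from the supported set
#'   (delta, theta, alpha, beta) -- there is no gamma band.
#' @param feature a [feature_config()].
#' @param n_subsets,ntree,n_perm model parameters (see
#'   [classify_balanced()], [rf_regress_permute()]).
#' @param seed master seed for every random element of the run.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, cohort = NULL, input_dir = NULL,
                            clinical_csv = NULL,
                            bands = names(eeg_bands()),
                            feature = feature_config(), n_subsets = 10,
                            ntree = 500, n_perm = 1000, seed = 1) {
  bad <- setdiff(bands, names(eeg_bands()))
  if (length(bad))
    stop(sprintf("band(s) outside supported set: %s (supported: %s)",
                 paste(bad, collapse = ", "),
                 paste(names(eeg_bands()), collapse = ", ")), call. = FALSE)
  if (is.null(cohort) && is.null(input_dir))
    stop("either 'cohort' or 'input_dir' must be given", call. = FALSE)
  structure(list(out_dir = out_dir, cohort = cohort, input_dir = input_dir,
                 clinical_csv = clinical_csv, bands = bands,
                 feature = feature, n_subsets = n_subsets, ntree = ntree,
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  # hash the analysis-relevant parameters only: where the outputs land must
  # not change what they contain
  h <- unclass(config)
  h$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(
    lapply(h, function(x)
      if (is.list(x)) lapply(unclass(x), unclass) else x),
    tmp, auto_unbox = TRUE, force = TRUE, null = "null")
  unname(tools::md5sum(tmp))
}

stage <- function(name, expr) {
  tryCatch(expr, macroeeg_exclusion = function(e) stop(e), error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Produces, under `config$out_dir`: the cohort feature table
#' (`features.csv`), the univariate comparison report (`comparison.csv`),
#' the balanced classifier report (`classifier.json`), one regression
#' report per PANSS change outcome (`regression_<outcome>.json`) and a
#' `run_info.json` with the configuration hash and seed. Re-running the
#' same configuration reproduces every number exactly.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory reports and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)

  data <- stage("input", {
    if (!is.null(config$cohort)) {
      generate_cohort(config$cohort)
    } else {
      paths <- list.files(config$input_dir, "\\.(edf|bdf)$",
                          ignore.case = TRUE, full.names = TRUE)
      if (!length(paths))
        stop("no EDF/BDF recordings found (0 subjects)", call. = FALSE)
      recs <- lapply(paths, read_recording)
      names(recs) <- sub("\\.(edf|bdf)$", "", basename(paths),
                         ignore.case = TRUE)
      clinical <- if (!is.null(config$clinical_csv))
        read.csv(config$clinical_csv, stringsAsFactors = FALSE) else NULL
      ft <- build_feature_table(recs, clinical, config$feature)
      if (is.null(ft$group))
        stop("clinical table with a 'group' column is required",
             call. = FALSE)
      list(features = ft, clinical = clinical)
    }
  })
  features <- data$features
  if (!nrow(features)) stop("0 subjects after preprocessing", call. = FALSE)

  comparison <- stage("group comparison", compare_cohort(features))
  classifier <- stage("classification",
                      classify_balanced(features, features$group,
                                        n_subsets = config$n_subsets,
                                        ntree = config$ntree,
                                        seed = config$seed))

  regressions <- stage("regression", {
    dp <- delta_panss(data$clinical)
    keep <- intersect(features$subject_id, dp$subject_id)
    Xr <- features[match(keep, features$subject_id), , drop = FALSE]
    dpr <- dp[match(keep, dp$subject_id), , drop = FALSE]
    outs <- c(total = "d_total", positive = "d_pos", negative = "d_neg",
              general = "d_gen")
    rseeds <- derive_seeds(config$seed, length(outs))
    setNames(lapply(seq_along(outs), function(k)
      rf_regress_permute(Xr, dpr[[outs[k]]], n_perm = config$n_perm,
                         ntree = config$ntree, seed = rseeds[k],
                         outcome_name = names(outs)[k])), names(outs))
  })

  stage("output", {
    stamp <- sprintf("# config_hash=%s seed=%d", hash, config$seed)
    fpath <- file.path(config$out_dir, "features.csv")
    writeLines(stamp, fpath)
    suppressWarnings(write.table(features, fpath, sep = ",", append = TRUE,
                                 row.names = FALSE, col.names = TRUE))
    cpath <- file.path(config$out_dir, "comparison.csv")
    writeLines(stamp, cpath)
    suppressWarnings(write.table(comparison, cpath, sep = ",", append = TRUE,
                                 row.names = FALSE, col.names = TRUE))
    jsonlite::write_json(
      list(config_hash = hash, seed = config$seed,
           accuracy = classifier$accuracy,
           sensitivity = classifier$sensitivity,
           specificity = classifier$specificity,
           per_subset = classifier$per_subset),
      file.path(config$out_dir, "classifier.json"),
      auto_unbox = TRUE, digits = NA)
    for (nm in names(regressions)) {
      r <- regressions[[nm]]
      jsonlite::write_json(
        list(config_hash = hash, seed = config$seed, outcome = nm,
             n = r$n, mtry = r$mtry, ntree = r$ntree, n_perm = r$n_perm,
             r2_cv = r$r2_cv, r2_mean = r$r2_mean, r2_sd = r$r2_sd,
             rmse_mean = r$rmse_mean, rmse_sd = r$rmse_sd,
             perm_p = r$perm_p, vimp = r$vimp),
        file.path(config$out_dir, sprintf("regression_%s.json", nm)),
        auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(list(config_hash = hash, seed = config$seed,
                              n_subjects = nrow(features)),
                         file.path(config$out_dir, "run_info.json"),
                         auto_unbox = TRUE)
  })

  invisible(list(features = features, comparison = comparison,
                 classifier = classifier, regressions = regressions,
                 config_hash = hash, out_dir = config$out_dir))
}
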