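#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. Either `input_dir` points
#' to an existing dataset (per-subject 4D NIfTI files named
#' `<subject_id>_bold.nii.gz`, an `atlas.nii.gz`, a `participants.tsv`)
#' or `simulate` supplies a [cohort_spec()] to generate one in memory.
#'
#' @param input_dir dataset directory, or `NULL` when simulating.
#' @param simulate optional [cohort_spec()].
#' @param tr_seconds repetition time (ignored when simulating: the spec's
#'   value is used).
#' @param band band-pass edges in Hz.
#' @param scales R/S window lengths, or `NULL` for [default_scales()].
#' @param correction Anis-Lloyd correction flag for [fit_hurst()].
#' @param alpha t-test selection level.
#' @param gammas,Cs SVM grid axes.
#' @param kernel `"radial"` or `"linear"`.
#' @param stability_fraction retention-stability fraction.
#' @param seed run seed.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, simulate = NULL,
                            tr_seconds = 2.0, band = c(0.01, 0.10),
                            scales = NULL, correction = FALSE,
                            alpha = 0.05,
                            gammas = grid_values(), Cs = grid_values(),
                            kernel = "radial",
                            stability_fraction = 0.95, seed = 1L) {
  if (is.null(input_dir) && is.null(simulate)) {
    stop_invalid("either input_dir or a simulation spec is required")
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "cohort_spec"))
  structure(list(input_dir = input_dir, simulate = simulate,
                 tr_seconds = tr_seconds, band = band, scales = scales,
                 correction = correction, alpha = alpha,
                 gammas = gammas, Cs = Cs, kernel = kernel,
                 stability_fraction = stability_fraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

read_cohort <- function(dir, tr_seconds) {
  pfile <- file.path(dir, "participants.tsv")
  afile <- file.path(dir, "atlas.nii.gz")
  for (f in c(pfile, afile)) {
    if (!file.exists(f)) stop_invalid("required input missing: ", f)
  }
  participants <- utils::read.delim(pfile, stringsAsFactors = FALSE)
  aimg <- RNifti::readNifti(afile)
  adim <- dim(aimg)
  if (length(adim) < 3L) adim <- c(adim, rep(1L, 3L - length(adim)))
  atlas <- array(as.integer(round(aimg)), dim = adim)
  bold <- lapply(participants$subject_id, function(id) {
    f <- file.path(dir, paste0(id, "_bold.nii.gz"))
    if (!file.exists(f)) stop_invalid("missing BOLD volume for ", id, ": ", f)
    img <- RNifti::readNifti(f)
    array(as.numeric(img), dim = dim(img))
  })
  list(bold = bold, atlas = atlas, participants = participants,
       spec = list(tr_seconds = tr_seconds))
}

#' Run the full analysis pipeline
#'
#' Executes clean -> voxelwise Hurst map -> ROI features -> nested
#' grid-search LOOCV in order, writing each stage's outputs under
#' `out_dir`: the feature matrix (`features.csv` + `groups.json`), the
#' per-point accuracy grid (`grid_accuracy.csv`), fold outcomes
#' (`fold_outcomes.csv`), ROC points (`roc.csv`), stable features
#' (`stable_features.csv`), headline metrics (`cv_result.json`) and a
#' manifest recording the configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created; default a tempdir subdir).
#' @return the [grid_search()] `cv_result`, invisibly, with attribute
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("boldhurst_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- if (!is.null(config$simulate)) {
    simulate_cohort(config$simulate)
  } else {
    read_cohort(config$input_dir, config$tr_seconds)
  }
  tr <- cohort$spec$tr_seconds
  mask <- cohort$atlas > 0L
  maps <- lapply(seq_along(cohort$bold), function(i) {
    cleaned <- clean_volume(cohort$bold[[i]], mask = mask,
                            tr = tr, band = config$band)
    suppressMessages(
      hurst_map(cleaned, mask, scales = config$scales,
                correction = config$correction))
  })
  fm <- build_feature_matrix(maps, cohort$atlas, cohort$participants)
  utils::write.csv(fm$values, file.path(out_dir, "features.csv"))
  jsonlite::write_json(list(subject_ids = fm$subject_ids, groups = fm$groups),
                       file.path(out_dir, "groups.json"))
  cv <- grid_search(fm, gammas = config$gammas, Cs = config$Cs,
                    alpha = config$alpha, kernel = config$kernel,
                    stability_fraction = config$stability_fraction)
  utils::write.csv(cv$per_point_accuracy,
                   file.path(out_dir, "grid_accuracy.csv"))
  utils::write.csv(
    cv$fold_outcomes[, c("held_out_id", "true_label", "predicted_label",
                         "decision_value")],
    file.path(out_dir, "fold_outcomes.csv"), row.names = FALSE)
  utils::write.csv(cv$roc, file.path(out_dir, "roc.csv"), row.names = FALSE)
  stable <- cv$retention$stable
  utils::write.csv(data.frame(
    roi_label = fm$roi_labels[stable],
    retention_count = cv$retention$counts[stable],
    mean_fisher_score = colMeans(cv$selection_fisher_scores)[stable]
  ), file.path(out_dir, "stable_features.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    accuracy = cv$accuracy, sensitivity = cv$sensitivity,
    specificity = cv$specificity, auc = cv$auc,
    best_gamma = cv$best_gamma, best_C = cv$best_C,
    retention_threshold = cv$retention$threshold,
    n_folds = cv$retention$n_folds
  ), file.path(out_dir, "cv_result.json"), auto_unbox = TRUE, digits = NA)
  manifest <- config
  manifest$simulate <- if (is.null(config$simulate)) NULL else unclass(config$simulate)
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  attr(cv, "out_dir") <- out_dir
  invisible(cv)
}
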