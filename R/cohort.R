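#' Specify a synthetic two-group cohort
#'
#' Describes a simulated resting-state cohort of MCI patients and healthy
#' controls (HC). Every voxel carries unit-variance fGn with an ROI-specific
#' Hurst exponent plus additive white measurement noise. HC subjects (and
#' unaffected ROIs of MCI subjects) use `baseline_H`; ROIs listed in
#' `affected_rois` are shifted by `delta_H` in MCI subjects only, so the
#' ground-truth discriminative feature set is known exactly.
#'
#' Defaults mirror a typical resting-state acquisition: 229 retained volumes
#' at TR = 2 s and a 246-parcel atlas. `baseline_H = 0.7` reflects the
#' persistent temporal structure characteristic of BOLD signals, and the
#' default `delta_H = -0.15` encodes a reduction of persistence in the
#' patient group.
#'
#' @param n_mci,n_hc subjects per group (>= 1).
#' @param n_timepoints volumes per subject.
#' @param tr_seconds repetition time, seconds.
#' @param n_rois number of atlas parcels.
#' @param voxels_per_roi voxels in each parcel.
#' @param baseline_H Hurst exponent of unaffected tissue, in (0, 1).
#' @param delta_H shift applied to affected ROIs in MCI subjects;
#'   `baseline_H + delta_H` must stay in (0, 1).
#' @param affected_rois integer ROI labels carrying the group effect.
#' @param noise_sd SD of additive white measurement noise (fGn has SD 1).
#' @param seed master seed; per-subject sub-seeds are derived from it.
#' @return an object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_mci = 64L, n_hc = 60L,
                        n_timepoints = 229L, tr_seconds = 2.0,
                        n_rois = 246L, voxels_per_roi = 8L,
                        baseline_H = 0.7, delta_H = -0.15,
                        affected_rois = 1:15, noise_sd = 0.1,
                        seed = 1L) {
  spec <- list(
    n_mci = as.integer(n_mci), n_hc = as.integer(n_hc),
    n_timepoints = as.integer(n_timepoints), tr_seconds = tr_seconds,
    n_rois = as.integer(n_rois), voxels_per_roi = as.integer(voxels_per_roi),
    baseline_H = baseline_H, delta_H = delta_H,
    affected_rois = as.integer(affected_rois), noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  if (spec$n_mci < 1L || spec$n_hc < 1L) stop_invalid("need >= 1 subject per group")
  check_H(spec$baseline_H)
  shifted <- spec$baseline_H + spec$delta_H
  if (shifted <= 0 || shifted >= 1) {
    stop_invalid("baseline_H + delta_H must lie in (0, 1); got ", format(shifted))
  }
  if (length(spec$affected_rois) &&
      (any(spec$affected_rois < 1L) || any(spec$affected_rois > spec$n_rois))) {
    stop_invalid("affected_rois must be a subset of 1..n_rois")
  }
  if (spec$noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  structure(spec, class = "cohort_spec")
}

#' Build a block-parcel atlas volume
#'
#' Lays out `n_rois` contiguous cuboid parcels in a single 3D grid: the
#' first dimension has length `voxels_per_roi`, so each parcel is a
#' `voxels_per_roi x 1 x 1` block at one (y, z) position. Unused (y, z)
#' positions are background (label 0). No anatomical realism is attempted;
#' ROI averaging only needs label identity.
#'
#' @param n_rois number of parcels (>= 1).
#' @param voxels_per_roi voxels per parcel (>= 1).
#' @return 3D integer array with labels `0` (background) and `1..n_rois`,
#'   each nonzero label appearing exactly `voxels_per_roi` times.
#' @export
build_block_atlas <- function(n_rois, voxels_per_roi) {
  n_rois <- as.integer(n_rois); voxels_per_roi <- as.integer(voxels_per_roi)
  if (n_rois < 1L || voxels_per_roi < 1L) {
    stop_invalid("n_rois and voxels_per_roi must be >= 1")
  }
  ny <- as.integer(ceiling(sqrt(n_rois)))
  nz <- as.integer(ceiling(n_rois / ny))
  atlas <- array(0L, dim = c(voxels_per_roi, ny, nz))
  for (r in seq_len(n_rois)) {
    y <- ((r - 1L) %% ny) + 1L
    z <- ((r - 1L) %/% ny) + 1L
    atlas[, y, z] <- r
  }
  atlas
}

#' Simulate a two-group BOLD cohort
#'
#' Generates one 4D volume per subject on the grid of [build_block_atlas()]:
#' every in-atlas voxel is an independent fGn series with the ROI's
#' ground-truth Hurst exponent plus `Normal(0, noise_sd)` measurement noise;
#' background voxels are pure measurement noise. Each subject draws from its
#' own sub-seed derived from `spec$seed`, so cohorts are bit-reproducible.
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `bold` (list of 4D arrays, one per subject),
#'   `atlas` (3D integer array), and `participants` (data.frame with
#'   `subject_id` and `group` columns).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  atlas <- build_block_atlas(spec$n_rois, spec$voxels_per_roi)
  n_sub <- spec$n_mci + spec$n_hc
  groups <- c(rep("MCI", spec$n_mci), rep("HC", spec$n_hc))
  ids <- sprintf("sub-%03d", seq_len(n_sub))
  seeds <- derive_seeds(spec$seed, n_sub)
  lab <- as.integer(atlas)
  in_atlas <- lab > 0L
  affected_voxel <- in_atlas & lab %in% spec$affected_rois
  Tn <- spec$n_timepoints
  bold <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    bold[[i]] <- with_seed(seeds[i], {
      mat <- matrix(0, Tn, length(lab))
      shift_here <- groups[i] == "MCI" & affected_voxel
      base_vox <- which(in_atlas & !shift_here)
      if (length(base_vox)) {
        mat[, base_vox] <- simulate_fgn(spec$baseline_H, Tn, length(base_vox))
      }
      if (any(shift_here)) {
        mat[, shift_here] <- simulate_fgn(spec$baseline_H + spec$delta_H, Tn,
                                          sum(shift_here))
      }
      if (spec$noise_sd > 0) {
        mat <- mat + matrix(stats::rnorm(length(mat), sd = spec$noise_sd),
                            nrow = Tn)
      }
      arr <- array(t(mat), dim = c(dim(atlas), Tn))
      arr
    })
  }
  participants <- data.frame(
    subject_id = ids,
    group = groups,
    stringsAsFactors = FALSE
  )
  list(bold = bold, atlas = atlas, participants = participants,
       spec = spec)
}

#' Write a simulated cohort to disk
#'
#' Persists the cohort in the layout a real study would use: one 4D NIfTI
#' per subject (TR recorded in the header), a 3D NIfTI atlas, and a
#' `participants.tsv` with `subject_id` and `group` columns.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- cohort$spec$tr_seconds
  for (i in seq_along(cohort$bold)) {
    img <- RNifti::asNifti(cohort$bold[[i]], pixdim = c(3, 3, 3, tr))
    RNifti::writeNifti(img, file.path(dir, paste0(cohort$participants$subject_id[i], "_bold.nii.gz")))
  }
  RNifti::writeNifti(RNifti::asNifti(cohort$atlas),
                     file.path(dir, "atlas.nii.gz"))
  utils::write.table(cohort$participants,
                     file.path(dir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
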