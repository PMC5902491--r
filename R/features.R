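#' Per-ROI mean of a Hurst map
#'
#' Averages defined H values over voxels of each atlas label. Voxels flagged
#' undefined in the map are excluded from the mean; an ROI left with zero
#' defined voxels is an error (a silent gap would corrupt the feature
#' matrix), as is a grid mismatch.
#'
#' @param map a [hurst_map()].
#' @param atlas 3D integer array, labels 0 (background) and 1..K.
#' @return named numeric vector of length K (names are the ROI labels).
#' @export
roi_means <- function(map, atlas) {
  stopifnot(inherits(map, "hurst_map"))
  if (!all(dim(atlas) == dim(map$values))) {
    stop_invalid("atlas grid ", paste(dim(atlas), collapse = "x"),
                 " does not match map grid ",
                 paste(dim(map$values), collapse = "x"))
  }
  lab <- as.integer(atlas)
  if (any(lab < 0L)) stop_invalid("atlas labels must be non-negative")
  K <- max(lab)
  if (K < 1L) stop_invalid("atlas has no nonzero labels")
  vals <- as.vector(map$values)
  use <- lab > 0L & !is.na(vals)
  sums <- rowsum(vals[use], lab[use])
  cnts <- rowsum(rep(1L, sum(use)), lab[use])
  out <- rep(NA_real_, K)
  out[as.integer(rownames(sums))] <- sums / cnts
  missing <- which(is.na(out) & seq_len(K) %in% lab)
  empty <- setdiff(seq_len(K), unique(lab))
  bad <- sort(c(missing, empty))
  if (length(bad)) {
    stop(errorCondition(
      paste0("ROI label(s) with zero defined voxels: ",
             paste(bad, collapse = ", ")),
      class = c("boldhurst_missing_roi", "error")))
  }
  stats::setNames(out, seq_len(K))
}

#' Assemble the subjects x ROIs feature matrix
#'
#' Stacks per-subject ROI-mean Hurst features in participants-table order
#' and attaches group labels. Subjects and maps are reconciled by position
#' against `participants$subject_id`; a count mismatch is an error.
#'
#' @param maps list of [hurst_map()] objects, one per participants row.
#' @param atlas 3D integer atlas array.
#' @param participants data.frame with `subject_id` and `group` (values
#'   `"MCI"` / `"HC"`) columns.
#' @return object of class `feature_matrix`: list with `values`
#'   (subjects x K matrix, rownames = subject ids, colnames = ROI labels),
#'   `subject_ids`, `groups`, `roi_labels`.
#' @export
build_feature_matrix <- function(maps, atlas, participants) {
  if (!nrow(participants)) stop_invalid("participants table is empty")
  if (length(maps) != nrow(participants)) {
    stop(errorCondition(
      paste0("cannot reconcile ", length(maps), " maps with ",
             nrow(participants), " participants (ids: ",
             paste(utils::head(participants$subject_id, 5), collapse = ", "), " ...)"),
      class = c("boldhurst_reconciliation", "error")))
  }
  rows <- lapply(maps, roi_means, atlas = atlas)
  values <- do.call(rbind, rows)
  rownames(values) <- participants$subject_id
  feature_matrix(values, participants$group)
}

#' Construct a feature matrix from raw values
#'
#' Low-level constructor used by [build_feature_matrix()] and by tests;
#' validates group labels and finiteness.
#'
#' @param values subjects x K numeric matrix.
#' @param groups character vector of `"MCI"` / `"HC"`, one per row.
#' @param roi_labels optional integer ROI labels (default from colnames or
#'   1..K).
#' @return a `feature_matrix` object.
#' @export
feature_matrix <- function(values, groups, roi_labels = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stop_invalid("feature matrix contains undefined entries")
  if (length(groups) != nrow(values)) stop_invalid("one group label per row required")
  if (!all(groups %in% c("MCI", "HC"))) stop_invalid('groups must be "MCI" or "HC"')
  if (is.null(roi_labels)) {
    roi_labels <- if (!is.null(colnames(values))) {
      as.integer(colnames(values))
    } else seq_len(ncol(values))
  }
  colnames(values) <- roi_labels
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("sub-%03d", seq_len(nrow(values)))
  }
  structure(list(values = values,
                 subject_ids = rownames(values),
                 groups = as.character(groups),
                 roi_labels = as.integer(roi_labels)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d subjects (%d MCI / %d HC) x %d ROIs\n",
              nrow(x$values), sum(x$groups == "MCI"), sum(x$groups == "HC"),
              ncol(x$values)))
  invisible(x)
}

# Row-subset view of a feature matrix (used for CV folds).
subset_features <- function(fm, idx) {
  feature_matrix(fm$values[idx, , drop = FALSE], fm$groups[idx], fm$roi_labels)
}
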