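# Region-wise SUV feature extraction.
#
# SUV = tissue activity / (injected dose / body weight), with units
# reconciled under the standard unit-density convention (1 g of tissue
# occupies 1 mL), so that kBq/mL activity, MBq dose and kg weight give a
# unitless ratio: SUV = activity * weight / dose (both numerator and
# denominator carry a factor of 1000).

#' Convert tissue activity to standardized uptake values
#'
#' @param activity tissue radioactivity concentration in kBq/mL (scalar,
#'   vector or array); must be non-negative.
#' @param injected_dose injected dose in MBq (> 0).
#' @param body_weight body weight in kg (> 0).
#' @return SUV values, same shape as `activity`.
#' @export
#' @examples
#' compute_suv(5, injected_dose = 370, body_weight = 74)  # 1.0
compute_suv <- function(activity, injected_dose, body_weight) {
  if (!is.numeric(injected_dose) || injected_dose <= 0) {
    stopf("domain error: 'injected_dose' must be > 0 (MBq)")
  }
  if (!is.numeric(body_weight) || body_weight <= 0) {
    stopf("domain error: 'body_weight' must be > 0 (kg)")
  }
  if (any(activity < 0, na.rm = TRUE)) {
    stopf("domain error: 'activity' must be non-negative")
  }
  activity * body_weight / injected_dose
}

#' Mean value per atlas region
#'
#' Arithmetic mean of a 3-D volume over the voxels of every atlas label,
#' background (label 0) excluded. NaN voxels are dropped from the mean with
#' a message reporting how many were dropped.
#'
#' @param volume 3-D numeric array (activity or SUV).
#' @param atlas 3-D integer label array of identical shape.
#' @param labels labels to extract; default all labels present (sorted). A
#'   requested label with no voxels raises an explicit empty-region error.
#' @return named numeric vector of per-region means (names = labels).
#' @export
extract_region_means <- function(volume, atlas, labels = NULL) {
  if (!identical(dim(volume), dim(atlas))) {
    stopf("alignment error: volume %s and atlas %s shapes differ",
          paste(dim(volume), collapse = "x"),
          paste(dim(atlas), collapse = "x"))
  }
  lab <- as.vector(atlas)
  vals <- as.vector(volume)
  present <- sort(unique(lab[lab > 0]))
  if (is.null(labels)) labels <- present
  missing <- setdiff(labels, present)
  if (length(missing)) {
    stopf("empty-region error: label%s %s ha%s no voxels in the atlas",
          if (length(missing) > 1) "s" else "",
          paste(missing, collapse = ", "),
          if (length(missing) > 1) "ve" else "s")
  }
  keep <- lab %in% labels
  v <- vals[keep]; l <- lab[keep]
  n_nan <- sum(is.na(v))
  if (n_nan > 0) {
    message("extract_region_means: dropping ", n_nan, " NaN voxel(s)")
  }
  means <- vapply(split(v, l), mean, 0, na.rm = TRUE)
  means[as.character(labels)]
}

#' Average per-frame region means across frames
#'
#' @param per_frame_means region x frame numeric matrix (no missing cells).
#' @return named vector of per-region means across frames.
#' @export
average_frames <- function(per_frame_means) {
  m <- as.matrix(per_frame_means)
  if (ncol(m) < 1L) stopf("domain error: need at least one frame")
  if (anyNA(m)) stopf("domain error: per-frame means contain missing cells")
  rowMeans(m)
}

#' Build a region-feature table from dynamic PET volumes
#'
#' For each subject: voxelwise SUV conversion, per-frame region means
#' against the atlas, then unweighted frame averaging — yielding one mean
#' SUV per region. Column order follows atlas label order.
#'
#' @param subjects list; each element either a `pet_fixture` or a list with
#'   `volume` (3-D or 4-D activity, kBq/mL), `atlas`, `injected_dose`,
#'   `body_weight` and optionally `subject_id`.
#' @param labels integer labels expected in every atlas; default: all labels
#'   of the first subject's atlas. Absent labels raise an empty-region error.
#' @param region_names optional character names for the label columns, in
#'   label order; default `Region_<label>`.
#' @return data.frame with `subject_id` and one mean-SUV column per region.
#' @export
build_feature_table <- function(subjects, labels = NULL, region_names = NULL) {
  stopifnot(length(subjects) >= 1L)
  first_atlas <- subjects[[1]]$atlas
  if (is.null(labels)) {
    labels <- sort(unique(as.vector(first_atlas[first_atlas > 0])))
  }
  if (is.null(region_names)) region_names <- paste0("Region_", labels)
  stopifnot(length(region_names) == length(labels))
  rows <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    id <- s$subject_id %||% sprintf("subject_%d", i)
    tryCatch({
      vol <- s$volume
      if (length(dim(vol)) == 3L) dim(vol) <- c(dim(vol), 1L)
      suv <- compute_suv(vol, s$injected_dose, s$body_weight)
      per_frame <- vapply(seq_len(dim(suv)[4]), function(t) {
        frame <- array(suv[, , , t], dim = dim(suv)[1:3])
        extract_region_means(frame, s$atlas, labels)
      }, numeric(length(labels)))
      if (is.null(dim(per_frame))) {
        per_frame <- matrix(per_frame, nrow = length(labels))
      }
      c(list(subject_id = id),
        as.list(stats::setNames(average_frames(per_frame), region_names)))
    }, error = function(e) {
      stopf("subject '%s': %s", id, conditionMessage(e))
    })
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}

#' Write a region-feature table as comma-separated text
#'
#' Header is `subject_id,<region names...>`.
#' @param table output of [build_feature_table()].
#' @param path output file.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
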