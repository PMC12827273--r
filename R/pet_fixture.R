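# Synthetic dynamic-PET fixtures: a 4-D activity volume plus an integer
# label atlas with exactly known per-region, per-frame mean activity.
# These stand in for preprocessed dynamic FDG-PET scans when testing the
# SUV extraction path; no image physics is simulated.

#' Generate a synthetic dynamic-PET fixture
#'
#' Partitions a sub-volume (roughly 80% of the voxels, in linear voxel
#' order) into `n_regions` contiguous equal-sized labeled blocks, leaving
#' the remainder as background (label 0). Each region/frame is assigned a
#' true mean activity (kBq/mL) drawn uniformly from `activity_range`;
#' voxel values are that mean plus optional Gaussian noise. The true means
#' are recorded exactly, so extraction can be checked against a stored
#' oracle.
#'
#' @param shape integer vector of 3 spatial extents.
#' @param n_regions number of atlas labels (1..n_regions, all non-empty).
#' @param n_frames number of dynamic frames (default 6).
#' @param seed integer seed; the fixture is a pure function of the inputs.
#' @param noise_sd voxel-level Gaussian noise SD in kBq/mL (default 0).
#' @param injected_dose injected dose in MBq (default 370).
#' @param body_weight subject body weight in kg (default 74).
#' @param activity_range range of true region mean activities (kBq/mL).
#' @return object of class `pet_fixture`: `volume` (4-D x,y,z,frame array,
#'   kBq/mL), `atlas` (3-D integer array), `injected_dose`, `body_weight`,
#'   `true_region_means` (n_regions x n_frames matrix).
#' @export
#' @examples
#' fx <- generate_pet_fixture(c(8, 8, 8), n_regions = 4, n_frames = 3, seed = 1)
#' dim(fx$volume)
generate_pet_fixture <- function(shape, n_regions, n_frames = 6L, seed = 1L,
                                 noise_sd = 0, injected_dose = 370,
                                 body_weight = 74,
                                 activity_range = c(2, 10)) {
  if (length(shape) != 3L || any(shape < 1)) {
    stopf("generate_pet_fixture: 'shape' must be 3 positive extents")
  }
  check_number(n_regions, "n_regions", lower = 1)
  check_number(n_frames, "n_frames", lower = 1)
  if (noise_sd < 0) stopf("generate_pet_fixture: 'noise_sd' must be >= 0")
  n_vox <- prod(shape)
  block <- floor(n_vox * 0.8 / n_regions)
  if (block < 1) {
    stopf("sizing error: %d regions do not fit in a %s volume",
          n_regions, paste(shape, collapse = "x"))
  }
  atlas <- array(0L, dim = shape)
  atlas[seq_len(block * n_regions)] <- rep(seq_len(n_regions), each = block)

  with_seed(seed, {
    tm <- matrix(stats::runif(n_regions * n_frames,
                              activity_range[1], activity_range[2]),
                 n_regions, n_frames)
    rownames(tm) <- as.character(seq_len(n_regions))
    vol <- array(0, dim = c(shape, n_frames))
    lab <- as.vector(atlas)
    inside <- lab > 0
    for (t in seq_len(n_frames)) {
      frame <- numeric(n_vox)
      frame[inside] <- tm[lab[inside], t]
      if (noise_sd > 0) {
        frame[inside] <- pmax(frame[inside] +
                                stats::rnorm(sum(inside), 0, noise_sd), 0)
      }
      vol[, , , t] <- frame
    }
    structure(list(volume = vol, atlas = atlas,
                   injected_dose = injected_dose, body_weight = body_weight,
                   true_region_means = tm),
              class = "pet_fixture")
  })
}

#' Write / read a PET fixture on disk
#'
#' The activity volume and atlas are written as NIfTI (`<prefix>_pet.nii.gz`
#' float32, `<prefix>_atlas.nii.gz` int16); dose, weight and the true
#' region/frame means go to a JSON sidecar (`<prefix>_meta.json`).
#'
#' @param fixture a `pet_fixture`.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return `write_pet_fixture` the prefix path invisibly; `read_pet_fixture`
#'   a `pet_fixture`.
#' @export
write_pet_fixture <- function(fixture, dir, prefix = "fixture") {
  stopifnot(inherits(fixture, "pet_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stub <- file.path(dir, prefix)
  write_nifti(fixture$volume, paste0(stub, "_pet.nii.gz"), "float32")
  write_nifti(fixture$atlas, paste0(stub, "_atlas.nii.gz"), "int16")
  jsonlite::write_json(
    list(injected_dose = fixture$injected_dose,
         body_weight = fixture$body_weight,
         true_region_means = fixture$true_region_means),
    paste0(stub, "_meta.json"), auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(stub)
}

#' @rdname write_pet_fixture
#' @export
read_pet_fixture <- function(dir, prefix = "fixture") {
  stub <- file.path(dir, prefix)
  vol <- read_nifti(paste0(stub, "_pet.nii.gz"))
  atlas <- read_nifti(paste0(stub, "_atlas.nii.gz"))
  meta <- jsonlite::read_json(paste0(stub, "_meta.json"), simplifyVector = TRUE)
  tm <- as.matrix(meta$true_region_means)
  rownames(tm) <- as.character(seq_len(nrow(tm)))
  structure(list(volume = structure(as.vector(vol), dim = dim(vol)),
                 atlas = array(as.integer(atlas), dim = dim(atlas)),
                 injected_dose = meta$injected_dose,
                 body_weight = meta$body_weight,
                 true_region_means = tm),
            class = "pet_fixture")
}
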