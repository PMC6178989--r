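#' Volumetric containers for PET analysis
#'
#' `volume3d()` wraps a 3D scalar grid together with its 4x4 voxel-to-world
#' affine (RAS mm, 0-based voxel indices). `dynamic_pet()` wraps a 4D dynamic
#' PET series (activity in kBq/mL) with per-frame timing in minutes.
#' `label_volume()` wraps a non-negative integer label grid with a label-id to
#' region-name map; label 0 is reserved for background. Decay correction is
#' assumed to have been applied upstream during reconstruction; no decay
#' handling is performed anywhere in the package.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-index (0-based) to world-mm matrix.
#' @param frames 4D numeric array (x, y, z, frame).
#' @param frame_starts,frame_durations numeric vectors, minutes, one per frame.
#' @param labels 3D array of non-negative integers.
#' @param name_map named integer vector mapping region names to label ids.
#' @return An object of class `volume3d`, `dynamic_pet` or `label_volume`.
#' @export
volume3d <- function(data, affine) {
  data <- as.array(data)
  assert_that(length(dim(data)) == 3L, "volume3d requires a 3D array, got %dD",
              length(dim(data)))
  assert_that(all(dim(data) >= 2L), "volume3d requires >= 2 voxels per axis")
  affine <- check_affine(affine)
  structure(list(data = data, affine = affine,
                 voxel_sizes = affine_voxel_sizes(affine)),
            class = "volume3d")
}

#' @rdname volume3d
#' @export
dynamic_pet <- function(frames, affine, frame_starts, frame_durations) {
  frames <- as.array(frames)
  assert_that(length(dim(frames)) == 4L, "dynamic_pet requires a 4D array, got %dD",
              length(dim(frames)))
  nf <- dim(frames)[4]
  assert_that(length(frame_starts) == nf && length(frame_durations) == nf,
              "frame timing mismatch: %d frames but %d starts / %d durations",
              nf, length(frame_starts), length(frame_durations))
  assert_that(all(frame_durations > 0), "frame_durations must be > 0")
  assert_that(!is.unsorted(frame_starts), "frame_starts must be non-decreasing")
  affine <- check_affine(affine)
  structure(list(frames = frames, affine = affine,
                 voxel_sizes = affine_voxel_sizes(affine),
                 frame_starts = as.numeric(frame_starts),
                 frame_durations = as.numeric(frame_durations)),
            class = "dynamic_pet")
}

#' @rdname volume3d
#' @export
label_volume <- function(labels, affine, name_map = NULL) {
  labels <- as.array(labels)
  assert_that(length(dim(labels)) == 3L, "label_volume requires a 3D array")
  assert_that(all(labels >= 0) && all(labels == round(labels)),
              "labels must be non-negative integers")
  affine <- check_affine(affine)
  present <- sort(unique(as.integer(labels)))
  if (is.null(name_map)) {
    ids <- setdiff(present, 0L)
    name_map <- stats::setNames(ids, paste0("region", ids))
  }
  missing <- setdiff(as.integer(name_map), present)
  if (length(missing))
    warn_pq("label ids absent from volume: %s", paste(missing, collapse = ", "))
  structure(list(labels = labels, affine = affine,
                 voxel_sizes = affine_voxel_sizes(affine),
                 name_map = name_map),
            class = "label_volume")
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  assert_that(all(dim(affine) == c(4L, 4L)), "affine must be 4x4")
  assert_that(abs(det(affine[1:3, 1:3])) > 1e-12, "affine must be invertible")
  assert_that(all(affine_voxel_sizes(affine) > 0), "voxel sizes must be > 0")
  affine
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels, %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_sizes, 3), collapse = "x")))
  invisible(x)
}

#' @export
print.dynamic_pet <- function(x, ...) {
  cat(sprintf("<dynamic_pet> %s voxels, %d frames, %.3g-%.3g min\n",
              paste(dim(x$frames)[1:3], collapse = "x"), dim(x$frames)[4],
              x$frame_starts[1], max(x$frame_starts + x$frame_durations)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels, %d regions (%s)\n",
              paste(dim(x$labels), collapse = "x"), length(x$name_map),
              paste(names(x$name_map), collapse = ", ")))
  invisible(x)
}

#' Read and write volumetric images
#'
#' `read_volume()` reads a 3D NIfTI file; `write_volume()` writes one. The
#' write/read round trip preserves data and affine to single-float tolerance
#' (NIfTI stores spatial transforms in 32-bit floats).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param vol a [volume3d] object.
#' @return `read_volume()` returns a [volume3d]; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  assert_that(length(d) == 3L, "expected a 3D volume, got %dD: %s", length(d), path)
  volume3d(array(as.numeric(img), dim = d), nifti_affine(img))
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  write_nifti_array(vol$data, vol$affine, path)
  invisible(path)
}

#' Read a 4D dynamic PET acquisition with its BIDS timing sidecar
#'
#' Frame timing is taken from the BIDS PET JSON sidecar keys `FrameTimesStart`
#' and `FrameDuration` (seconds) and converted to minutes, the time unit used
#' throughout the package (kinetic rate constants are conventionally min^-1).
#'
#' @param pet_path path to a 4D NIfTI file.
#' @param sidecar_path path to the JSON sidecar; defaults to `pet_path` with
#'   the extension replaced by `.json`.
#' @return A [dynamic_pet] object.
#' @export
read_dynamic_pet <- function(pet_path, sidecar_path = NULL) {
  if (is.null(sidecar_path))
    sidecar_path <- paste0(sub("\\.nii(\\.gz)?$", "", pet_path), ".json")
  img <- RNifti::readNifti(pet_path)
  d <- dim(img)
  assert_that(length(d) == 4L, "expected a 4D PET volume, got %dD: %s",
              length(d), pet_path)
  assert_that(file.exists(sidecar_path), "missing PET sidecar: %s", sidecar_path)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (key in c("FrameTimesStart", "FrameDuration")) {
    assert_that(!is.null(side[[key]]), "sidecar missing field %s: %s",
                key, sidecar_path)
    assert_that(length(side[[key]]) == d[4],
                "frame timing mismatch: %d frames but %s has length %d",
                d[4], key, length(side[[key]]))
  }
  dynamic_pet(array(as.numeric(img), dim = d), nifti_affine(img),
              frame_starts = side$FrameTimesStart / 60,
              frame_durations = side$FrameDuration / 60)
}

#' Write a dynamic PET acquisition with its BIDS timing sidecar
#'
#' Timing is written back in seconds per the BIDS PET specification.
#'
#' @param pet a [dynamic_pet] object.
#' @param pet_path output NIfTI path; the sidecar is written alongside with a
#'   `.json` extension.
#' @export
write_dynamic_pet <- function(pet, pet_path) {
  write_nifti_array(pet$frames, pet$affine, pet_path)
  sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", pet_path), ".json")
  jsonlite::write_json(
    list(FrameTimesStart = pet$frame_starts * 60,
         FrameDuration = pet$frame_durations * 60,
         Units = "kBq/mL"),
    sidecar, digits = NA, auto_unbox = FALSE)
  invisible(pet_path)
}

#' Read an integer label volume
#'
#' @param path path to a 3D NIfTI file of non-negative integer labels.
#' @param name_map optional named integer vector (region name -> label id).
#' @return A [label_volume].
#' @export
read_labels <- function(path, name_map = NULL) {
  v <- read_volume(path)
  label_volume(array(as.integer(round(v$data)), dim = dim(v$data)),
               v$affine, name_map)
}

nifti_affine <- function(img) {
  x <- RNifti::xform(img)
  structure(as.matrix(x)[1:4, 1:4], dimnames = NULL)
}

# the spatial transform is carried by the sform alone: assigning the qform as
# well re-normalizes the matrix against the stale pixdim and corrupts scale
write_nifti_array <- function(arr, affine, path) {
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Time-weighted average of a dynamic PET series
#'
#' Collapses a 4D series to a 3D volume with voxelwise
#' sum(frame * duration) / sum(duration); the standard static image used for
#' coregistration and head masking.
#'
#' @param pet a [dynamic_pet].
#' @return A [volume3d].
#' @export
time_weighted_average <- function(pet) {
  d <- dim(pet$frames)
  w <- pet$frame_durations / sum(pet$frame_durations)
  flat <- matrix(pet$frames, ncol = d[4])
  volume3d(array(as.numeric(flat %*% w), dim = d[1:3]), pet$affine)
}
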