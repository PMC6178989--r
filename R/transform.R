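#' Six-parameter rigid transform between world coordinate frames
#'
#' A rigid mapping from the moving image's world coordinates (RAS mm) to the
#' fixed image's world coordinates: rotation (degrees about x, y, z; intrinsic,
#' applied z then y then x) about a world-space center, followed by a
#' translation in mm. In the coregistration module the moving frame is PET
#' world space and the fixed frame is T1 world space.
#'
#' @param rotations numeric length-3, degrees about x, y, z.
#' @param translations numeric length-3, mm along x, y, z.
#' @param center numeric length-3 world-mm rotation center (conventionally the
#'   moving volume's intensity center of mass).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotations = c(0, 0, 0),
                            translations = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  assert_that(length(rotations) == 3 && length(translations) == 3 &&
                length(center) == 3, "rigid_transform needs 3+3 parameters")
  assert_that(all(is.finite(c(rotations, translations, center))),
              "rigid_transform parameters must be finite")
  structure(list(rotations = as.numeric(rotations),
                 translations = as.numeric(translations),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> rot (deg): %s | trans (mm): %s | center: %s\n",
    paste(signif(x$rotations, 4), collapse = ", "),
    paste(signif(x$translations, 4), collapse = ", "),
    paste(signif(x$center, 4), collapse = ", ")))
  invisible(x)
}

# 3x3 rotation matrix, intrinsic z -> y -> x: R = Rx %*% Ry %*% Rz
rotation_matrix <- function(deg) {
  r <- deg * pi / 180
  ca <- cos(r[1]); sa <- sin(r[1])
  cb <- cos(r[2]); sb <- sin(r[2])
  cg <- cos(r[3]); sg <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, ca, -sa), c(0, sa, ca))
  Ry <- rbind(c(cb, 0, sb), c(0, 1, 0), c(-sb, 0, cb))
  Rz <- rbind(c(cg, -sg, 0), c(sg, cg, 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

# Euler angles (deg) for the Rx Ry Rz convention; valid away from gimbal lock
euler_from_matrix <- function(R) {
  b <- asin(max(-1, min(1, R[1, 3])))
  a <- atan2(-R[2, 3], R[3, 3])
  g <- atan2(-R[1, 2], R[1, 1])
  c(a, b, g) * 180 / pi
}

#' Convert a rigid transform to a 4x4 world-to-world matrix
#'
#' @param tf a [rigid_transform].
#' @return 4x4 matrix `A` such that `fixed_world = A %*% c(moving_world, 1)`.
#' @export
transform_matrix <- function(tf) {
  R <- rotation_matrix(tf$rotations)
  A <- diag(4)
  A[1:3, 1:3] <- R
  A[1:3, 4] <- tf$center + tf$translations - R %*% tf$center
  A
}

#' Invert or compose rigid transforms
#'
#' `transform_invert()` returns the transform mapping fixed world coordinates
#' back to moving world coordinates. `transform_compose(a, b)` returns the
#' transform applying `b` first, then `a`.
#'
#' @param tf,a,b [rigid_transform] objects.
#' @return A [rigid_transform].
#' @export
transform_invert <- function(tf) {
  R <- rotation_matrix(tf$rotations)
  Rt <- t(R)
  rigid_transform(euler_from_matrix(Rt),
                  as.numeric(-Rt %*% tf$translations),
                  tf$center)
}

#' @rdname transform_invert
#' @export
transform_compose <- function(a, b) {
  M <- transform_matrix(a) %*% transform_matrix(b)
  matrix_to_rigid(M, center = b$center)
}

# recover the 6-parameter form of a rigid 4x4 matrix about a given center
matrix_to_rigid <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  trans <- M[1:3, 4] - center + as.numeric(R %*% center)
  rigid_transform(euler_from_matrix(R), trans, center)
}

#' Apply a rigid transform to world-coordinate points
#'
#' @param tf a [rigid_transform].
#' @param pts N x 3 matrix of world coordinates (mm).
#' @return N x 3 matrix of mapped coordinates.
#' @export
transform_points <- function(tf, pts) {
  apply_affine(transform_matrix(tf), as.matrix(pts))
}

#' Read and write rigid transforms as text
#'
#' Serialized as a 9-line text file: the 6 parameters (one per line), the
#' rotation center, the angle convention string and the direction label.
#'
#' @param tf a [rigid_transform].
#' @param path output/input path.
#' @param direction free-text direction label stored in the file.
#' @export
write_transform <- function(tf, path, direction = "moving_to_fixed") {
  lines <- c(sprintf("rotation_x_deg: %.12g", tf$rotations[1]),
             sprintf("rotation_y_deg: %.12g", tf$rotations[2]),
             sprintf("rotation_z_deg: %.12g", tf$rotations[3]),
             sprintf("translation_x_mm: %.12g", tf$translations[1]),
             sprintf("translation_y_mm: %.12g", tf$translations[2]),
             sprintf("translation_z_mm: %.12g", tf$translations[3]),
             sprintf("center_mm: %.12g %.12g %.12g", tf$center[1],
                     tf$center[2], tf$center[3]),
             "convention: intrinsic z-y-x, degrees",
             sprintf("direction: %s", direction))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  lines <- readLines(path)
  val <- function(key) {
    line <- grep(paste0("^", key, ":"), lines, value = TRUE)
    assert_that(length(line) == 1, "transform file missing field %s", key)
    as.numeric(strsplit(trimws(sub("^[^:]+:", "", line)), "\\s+")[[1]])
  }
  rigid_transform(
    c(val("rotation_x_deg"), val("rotation_y_deg"), val("rotation_z_deg")),
    c(val("translation_x_mm"), val("translation_y_mm"), val("translation_z_mm")),
    val("center_mm"))
}
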