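#' Resample a volume onto a target grid through a rigid transform
#'
#' Pull-resampling: each target-grid voxel's world coordinate is mapped
#' through the inverse of `transform` (which maps source world coordinates to
#' target world coordinates) into source voxel space and interpolated there.
#' Voxels falling outside the source field of view are set to 0. Label volumes
#' require nearest-neighbour interpolation.
#'
#' @param source a [volume3d] or [label_volume].
#' @param transform a [rigid_transform] mapping source world to target world;
#'   identity by default.
#' @param target_grid a list with `dims` (length-3 integer) and `affine`
#'   (4x4), or any volume object whose grid should be matched; defaults to the
#'   source grid.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return A volume of the same class as `source` on the target grid.
#' @export
resample <- function(source, transform = rigid_transform(),
                     target_grid = NULL,
                     interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  is_labels <- inherits(source, "label_volume")
  if (is_labels && interpolation == "trilinear")
    stop_pq("label volumes must be resampled with nearest interpolation")
  src_data <- if (is_labels) source$labels else source$data
  tg <- as_target_grid(target_grid %||% source)
  # target voxel index -> target world -> source world -> source voxel index
  M <- solve(source$affine) %*% solve(transform_matrix(transform)) %*% tg$affine
  out <- resample_array(src_data, M, tg$dims, interpolation)
  if (is_labels) {
    label_volume(array(as.integer(out), dim = tg$dims), tg$affine,
                 source$name_map)
  } else {
    volume3d(out, tg$affine)
  }
}

as_target_grid <- function(x) {
  if (is.list(x) && !is.null(x$dims) && !is.null(x$affine))
    return(list(dims = as.integer(x$dims), affine = as.matrix(x$affine)))
  if (inherits(x, "volume3d")) return(list(dims = dim(x$data), affine = x$affine))
  if (inherits(x, "label_volume")) return(list(dims = dim(x$labels), affine = x$affine))
  if (inherits(x, "dynamic_pet")) return(list(dims = dim(x$frames)[1:3], affine = x$affine))
  stop_pq("cannot interpret target_grid")
}

grid_index_matrix <- function(dims) {
  cbind(
    rep.int(seq_len(dims[1]) - 1, times = dims[2] * dims[3]),
    rep.int(rep(seq_len(dims[2]) - 1, each = dims[1]), times = dims[3]),
    rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2]))
}

# core gather: map all target voxel indices through M (target idx -> source idx)
resample_array <- function(src, M, dims, interpolation, idx = NULL) {
  n <- prod(dims)
  if (is.null(idx)) idx <- grid_index_matrix(dims)
  sidx <- apply_affine(M, idx)
  sd <- dim(src)
  if (interpolation == "nearest") {
    i <- round(sidx[, 1]); j <- round(sidx[, 2]); k <- round(sidx[, 3])
    ok <- i >= 0 & i <= sd[1] - 1 & j >= 0 & j <= sd[2] - 1 &
      k >= 0 & k <= sd[3] - 1
    out <- numeric(n)
    out[ok] <- src[1 + i[ok] + sd[1] * (j[ok] + sd[2] * k[ok])]
    array(out, dim = dims)
  } else {
    array(trilinear_gather(list(src), sidx, sd)[[1]], dim = dims)
  }
}

# zero-pad a 3D array by one voxel on every side; lets the fast gather clamp
# out-of-field coordinates into the zero border instead of branch-masking
pad_zero <- function(arr) {
  d <- dim(arr)
  out <- array(0, d + 2L)
  out[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  out
}

# fast trilinear gather on pre-padded arrays (see pad_zero); sd is the
# ORIGINAL (unpadded) dimension
trilinear_gather_padded <- function(srcs_padded, sidx, sd) {
  pd1 <- sd[1] + 2L
  pd12 <- pd1 * (sd[2] + 2L)
  i0 <- floor(sidx[, 1]); j0 <- floor(sidx[, 2]); k0 <- floor(sidx[, 3])
  fx <- sidx[, 1] - i0; fy <- sidx[, 2] - j0; fz <- sidx[, 3] - k0
  cl <- function(v, n) pmin.int(pmax.int(v, -1), n)
  i1 <- cl(i0 + 1, sd[1]); j1 <- cl(j0 + 1, sd[2]); k1 <- cl(k0 + 1, sd[3])
  i0 <- cl(i0, sd[1]); j0 <- cl(j0, sd[2]); k0 <- cl(k0, sd[3])
  # 1-based linear index into the padded array (offset +1 per axis)
  base <- function(i, j, k) 2 + i + pd1 * (j + 1) + pd12 * (k + 1)
  wx0 <- 1 - fx; wy0 <- 1 - fy; wz0 <- 1 - fz
  lapply(srcs_padded, function(s) {
    (s[base(i0, j0, k0)] * wx0 + s[base(i1, j0, k0)] * fx) * wy0 * wz0 +
      (s[base(i0, j1, k0)] * wx0 + s[base(i1, j1, k0)] * fx) * fy * wz0 +
      (s[base(i0, j0, k1)] * wx0 + s[base(i1, j0, k1)] * fx) * wy0 * fz +
      (s[base(i0, j1, k1)] * wx0 + s[base(i1, j1, k1)] * fx) * fy * fz
  })
}

# trilinear interpolation of one or more arrays sharing a source grid at the
# same continuous voxel coordinates; out-of-field contributions are 0
trilinear_gather <- function(srcs, sidx, sd) {
  n <- nrow(sidx)
  i0 <- floor(sidx[, 1]); j0 <- floor(sidx[, 2]); k0 <- floor(sidx[, 3])
  fx <- sidx[, 1] - i0; fy <- sidx[, 2] - j0; fz <- sidx[, 3] - k0
  outs <- lapply(srcs, function(s) numeric(n))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) fx else 1 - fx) * (if (dj) fy else 1 - fy) *
      (if (dk) fz else 1 - fz)
    ii <- i0 + di; jj <- j0 + dj; kk <- k0 + dk
    ok <- w > 0 & ii >= 0 & ii <= sd[1] - 1 & jj >= 0 & jj <= sd[2] - 1 &
      kk >= 0 & kk <= sd[3] - 1
    if (any(ok)) {
      lin <- 1 + ii[ok] + sd[1] * (jj[ok] + sd[2] * kk[ok])
      wok <- w[ok]
      for (s in seq_along(srcs))
        outs[[s]][ok] <- outs[[s]][ok] + wok * srcs[[s]][lin]
    }
  }
  outs
}

#' Resample every frame of a dynamic PET series
#'
#' Used to apply a known misregistration to a synthetic acquisition and to
#' move acquisitions between grids.
#'
#' @param pet a [dynamic_pet].
#' @param transform a [rigid_transform] mapping the series' world coordinates
#'   to the target world coordinates.
#' @param target_grid grid to sample on; defaults to the input grid.
#' @return A [dynamic_pet] on the target grid.
#' @export
resample_dynamic <- function(pet, transform = rigid_transform(),
                             target_grid = NULL) {
  tg <- as_target_grid(target_grid %||% pet)
  M <- solve(pet$affine) %*% solve(transform_matrix(transform)) %*% tg$affine
  nf <- dim(pet$frames)[4]
  out <- array(0, dim = c(tg$dims, nf))
  for (f in seq_len(nf))
    out[, , , f] <- resample_array(pet$frames[, , , f], M, tg$dims, "trilinear")
  dynamic_pet(out, tg$affine, pet$frame_starts, pet$frame_durations)
}

# blur-then-stride downsampling used by the registration pyramid
downsample_volume <- function(vol, factor) {
  if (factor <= 1) return(vol)
  dims <- dim(vol$data)
  nd <- pmax(2L, as.integer(ceiling(dims / factor)))
  S <- diag(c(factor, factor, factor, 1))
  # center the coarse grid on the fine grid
  S[1:3, 4] <- (dims - 1 - factor * (nd - 1)) / 2
  new_affine <- vol$affine %*% S
  M <- S  # target idx -> source idx directly
  volume3d(resample_array(vol$data, M, nd, "trilinear"), new_affine)
}
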