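# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pq <- function(...) stop(sprintf(...), call. = FALSE)

warn_pq <- function(...) warning(sprintf(...), call. = FALSE)

#' @noRd
assert_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop_pq(msg, ...)
  invisible(TRUE)
}

# voxel-index (0-based) -> world mm for all voxels of a grid, as an N x 3 matrix
grid_world_coords <- function(dims, affine) {
  idx <- as.matrix(expand.grid(
    i = seq_len(dims[1]) - 1,
    j = seq_len(dims[2]) - 1,
    k = seq_len(dims[3]) - 1
  ))
  apply_affine(affine, idx)
}

# apply a 4x4 affine to an N x 3 matrix of points
apply_affine <- function(affine, pts) {
  pts <- cbind(pts, 1)
  out <- pts %*% t(affine)
  out[, 1:3, drop = FALSE]
}

# voxel edge lengths (mm) from an affine
affine_voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# run an expression with a locally seeded RNG, restoring global state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic formatting for numeric CSV output
format_num <- function(x) {
  ifelse(is.na(x), "", formatC(x, digits = 10, format = "g"))
}
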