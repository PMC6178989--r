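#' Registration configuration
#'
#' Controls the hierarchical NMI registration. The pyramid smooths both
#' images at progressively finer Gaussian levels with matched downsampling;
#' the mask stage uses only the coarse levels.
#'
#' @param pyramid_fwhm smoothing levels in mm, coarse to fine.
#' @param mask_pyramid_fwhm levels used for the initial binary-mask stage.
#' @param bins joint-histogram size (>= 8).
#' @param max_eval maximum objective evaluations per pyramid level.
#' @param tol parameter tolerance (mm / degrees) at which the coordinate
#'   search stops.
#' @param min_overlap minimum fraction of the fixed mask that the moving mask
#'   must cover for a step to be accepted.
#' @return A list of class `registration_config`.
#' @export
registration_config <- function(pyramid_fwhm = c(8, 4, 2),
                                mask_pyramid_fwhm = c(8, 4),
                                bins = 64, max_eval = 200, tol = 1e-3,
                                min_overlap = 0.1) {
  assert_that(bins >= 8, "bins must be >= 8")
  assert_that(!is.unsorted(rev(pyramid_fwhm)), "pyramid must be coarse to fine")
  structure(list(pyramid_fwhm = pyramid_fwhm,
                 mask_pyramid_fwhm = mask_pyramid_fwhm,
                 bins = bins, max_eval = max_eval, tol = tol,
                 min_overlap = min_overlap),
            class = "registration_config")
}

#' Automatic PET head mask
#'
#' Otsu threshold on the (time-weighted average) volume, followed by largest
#' 6-connected component and a morphological closing (implemented as a 4 mm
#' Gaussian blur of the binary mask thresholded at 0.5).
#'
#' @param vol a [volume3d].
#' @return A logical array on the grid of `vol`.
#' @export
auto_mask <- function(vol) {
  thr <- otsu_threshold(vol$data)
  m <- vol$data > thr
  m <- largest_component(m)
  closed <- blur_array(m + 0, psf(4)$sigma / vol$voxel_sizes) > 0.5
  m | closed
}

otsu_threshold <- function(x, nbins = 256) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(nbins, 1 + floor((x - rng[1]) / diff(rng) * nbins)), nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

largest_component <- function(mask) {
  dims <- dim(mask)
  vox <- which(mask)
  if (length(vox) == 0) return(mask)
  lin <- array(0L, dims)
  lin[vox] <- seq_along(vox)
  edges <- NULL
  for (ax in 1:3) {
    stride <- c(1L, dims[1], dims[1] * dims[2])[ax]
    coord <- arrayInd(vox, dims)[, ax]
    ok <- coord < dims[ax] & mask[pmin(vox + stride, prod(dims))]
    if (any(ok))
      edges <- rbind(edges, cbind(lin[vox[ok]], lin[vox[ok] + stride]))
  }
  if (is.null(edges)) return(mask)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(vox) - igraph::vcount(g)))
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  out <- array(FALSE, dims)
  out[vox[keep]] <- TRUE
  out
}

# intensity-weighted center of mass in world mm
center_of_mass <- function(vol, mask = NULL) {
  w <- as.numeric(vol$data)
  if (!is.null(mask)) w <- w * as.numeric(mask)
  w <- pmax(w, 0)
  assert_that(sum(w) > 0, "cannot compute center of mass of empty volume")
  pts <- grid_world_coords(dim(vol$data), vol$affine)
  as.numeric(colSums(pts * w) / sum(w))
}

#' Rigid PET-to-T1 registration by normalized mutual information
#'
#' Three-phase, hierarchical six-parameter registration. Phase 0 translates
#' the moving (PET) image so the intensity centers of mass coincide. Stage 1
#' registers the two binary head masks (treated as 0/1 intensity images)
#' through the coarse pyramid levels. Stage 2 refines from the stage-1
#' parameters on the intensity images, with the joint histogram restricted to
#' the union of the two masks, through all pyramid levels. NMI is maximized
#' with a derivative-free coordinate (pattern) search per level; candidate
#' steps whose mask overlap falls below `min_overlap` are rejected.
#'
#' @param pet_static a [volume3d], typically [time_weighted_average()] of the
#'   dynamic series; the moving image.
#' @param t1 a [volume3d]; the fixed image.
#' @param pet_mask,t1_mask logical arrays on the respective grids; computed
#'   with [auto_mask()] when `NULL` (a supplied brain mask is preferable for
#'   the T1, where Otsu is only a fallback).
#' @param config a [registration_config].
#' @return An object of class `rigid_registration`: fields `transform` (a
#'   [rigid_transform] mapping PET world to T1 world), `similarity` (final
#'   NMI), `stage_similarity` (per-stage NMI), `config`.
#' @export
rigid_register <- function(pet_static, t1, pet_mask = NULL, t1_mask = NULL,
                           config = registration_config()) {
  if (is.null(pet_mask)) pet_mask <- auto_mask(pet_static)
  if (is.null(t1_mask)) t1_mask <- auto_mask(t1)
  assert_that(any(pet_mask), "empty PET mask")
  assert_that(any(t1_mask), "empty T1 mask")

  center <- center_of_mass(pet_static, pet_mask)
  t0 <- center_of_mass(t1, t1_mask) - center
  par <- c(0, 0, 0, t0)

  pet_mask_vol <- volume3d(pet_mask + 0, pet_static$affine)
  t1_mask_vol <- volume3d(t1_mask + 0, t1$affine)

  if (overlap_fraction(par, center, pet_mask_vol, t1_mask_vol) <
      config$min_overlap)
    stop_pq("insufficient overlap between masks after center-of-mass alignment")

  # stage 1: binary masks through the coarse levels
  s1 <- run_pyramid(par, center, pet_mask_vol, t1_mask_vol,
                    pet_mask_vol, t1_mask_vol,
                    config$mask_pyramid_fwhm, config)
  # stage 2: intensities, histogram restricted to the mask union
  s2 <- run_pyramid(s1$par, center, pet_static, t1,
                    pet_mask_vol, t1_mask_vol,
                    config$pyramid_fwhm, config)

  tf <- rigid_transform(s2$par[1:3], s2$par[4:6], center)
  structure(list(transform = tf, similarity = s2$value,
                 stage_similarity = c(mask_stage = s1$value,
                                      intensity_stage = s2$value),
                 config = config),
            class = "rigid_registration")
}

#' @export
print.rigid_registration <- function(x, ...) {
  cat("Rigid NMI registration\n")
  print(x$transform)
  cat(sprintf("  NMI: mask stage %.4f, intensity stage %.4f\n",
              x$stage_similarity[1], x$stage_similarity[2]))
  invisible(x)
}

run_pyramid <- function(par, center, moving, fixed, moving_mask, fixed_mask,
                        fwhm_levels, config) {
  value <- -Inf
  for (fw in fwhm_levels) {
    factor <- max(1, floor(fw / (2 * min(fixed$voxel_sizes))))
    mv <- downsample_volume(gaussian_blur(moving, fw), factor)
    fx <- downsample_volume(gaussian_blur(fixed, fw), factor)
    mm <- downsample_volume(moving_mask, factor)
    fm <- downsample_volume(fixed_mask, factor) # soft masks after downsampling
    obj <- make_nmi_objective(center, mv, fx, mm, fm, config)
    init_step <- c(rep(max(fw / 2, 1), 3), rep(max(fw / 2, 1), 3))
    res <- pattern_search(obj, par, init_step, config$max_eval, config$tol)
    par <- res$par
    value <- res$value
  }
  list(par = par, value = value)
}

make_nmi_objective <- function(center, moving, fixed, moving_mask, fixed_mask,
                               config) {
  fdims <- dim(fixed$data)
  Afix <- fixed$affine
  inv_mov <- solve(moving$affine)
  # moving image and moving mask are resampled on the same grid, so the
  # interpolation coordinates and weights are shared between them
  assert_that(all(abs(moving$affine - moving_mask$affine) < 1e-9) &&
                all(dim(moving_mask$data) == dim(moving$data)),
              "moving image and mask must share a grid")
  fmask_full <- fixed_mask$data > 0.5
  # the histogram support is bounded to a generous neighbourhood of the
  # fixed head mask (the practical field of view of the alignment)
  support <- blur_array(fmask_full + 0,
                        rep(16, 3) / (2.3548 * affine_voxel_sizes(Afix))) > 0.01
  keep <- which(support)
  fmask_arr <- fmask_full[keep]
  n_fmask <- max(1, sum(fmask_arr))
  bins <- config$bins
  fbin <- bin_index(as.numeric(fixed$data)[keep], bins, c(0.01, 0.99))$idx
  # robust moving-intensity range fixed once per level (resampling does not
  # change the intensity distribution materially)
  mrng <- stats::quantile(as.numeric(moving$data)[moving_mask$data > 0.5],
                          c(0.01, 0.99), names = FALSE)
  if (diff(mrng) <= 0) mrng <- range(moving$data) + c(0, 1e-12)
  idx <- grid_index_matrix(fdims)[keep, , drop = FALSE]
  sd <- dim(moving$data)
  padded <- list(pad_zero(moving$data), pad_zero(moving_mask$data))
  function(par) {
    tf <- rigid_transform(par[1:3], par[4:6], center)
    M <- inv_mov %*% solve(transform_matrix(tf)) %*% Afix
    sidx <- apply_affine(M, idx)
    g <- trilinear_gather_padded(padded, sidx, sd)
    mm <- g[[2]] > 0.5
    ov <- sum(mm & fmask_arr) / n_fmask
    if (ov < config$min_overlap) return(-Inf)
    un <- mm | fmask_arr
    mbin <- floor((g[[1]][un] - mrng[1]) / (mrng[2] - mrng[1]) * bins) + 1
    mbin <- pmin.int(pmax.int(mbin, 1L), bins)
    counts <- tabulate(mbin + bins * (fbin[un] - 1L), nbins = bins * bins)
    nmi_from_counts(counts, bins)
  }
}

nmi_from_counts <- function(counts, bins) {
  n <- sum(counts)
  if (n == 0) return(-Inf)
  p <- counts / n
  pm <- matrix(p, bins, bins)
  ha <- entropy_nats(rowSums(pm))
  hb <- entropy_nats(colSums(pm))
  hab <- entropy_nats(p)
  if (hab <= 0) return(-Inf)
  (ha + hb) / hab
}

# greedy coordinate/pattern search maximizing f; steps halve after a sweep
# with no improvement; ties broken toward the smaller-magnitude parameter
pattern_search <- function(f, par, step, max_eval, tol) {
  best <- f(par)
  if (!is.finite(best))
    stop_pq("registration objective not finite at the starting point")
  evals <- 1
  while (evals < max_eval && any(step > tol)) {
    improved <- FALSE
    for (i in seq_along(par)) {
      if (step[i] <= tol) next
      for (sgn in c(1, -1)) {
        cand <- par
        cand[i] <- par[i] + sgn * step[i]
        v <- f(cand)
        evals <- evals + 1
        accept <- v > best ||
          (v == best && is.finite(v) && sum(cand^2) < sum(par^2))
        if (accept) {
          par <- cand
          best <- v
          improved <- TRUE
          break
        }
        if (evals >= max_eval) break
      }
      if (evals >= max_eval) break
    }
    if (!improved) step <- step / 2
  }
  list(par = par, value = best)
}

overlap_fraction <- function(par, center, moving_mask, fixed_mask) {
  tf <- rigid_transform(par[1:3], par[4:6], center)
  mm <- resample(moving_mask, tf, fixed_mask, "trilinear")$data > 0.5
  fm <- fixed_mask$data > 0.5
  sum(mm & fm) / max(1, sum(fm))
}
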