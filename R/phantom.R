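#' Synthetic dynamic-PET phantom specification
#'
#' Describes a label phantom (shape primitives on a regular grid), a dynamic
#' frame schedule, per-region tracer kinetics for one of three tracer
#' archetypes, a scanner PSF, and a noise level. The defaults emulate a
#' validation experiment in which empirically shaped tracer curves are
#' painted into anatomical regions, blurred with a 6.5 mm FWHM Gaussian PSF,
#' and degraded with frame-dependent noise: a cortical shell, a deep
#' (white-matter-like) filler, a putamen-like ellipsoid (~4 cm^3), a smaller
#' caudate-like ellipsoid, and a cerebellum-like reference region.
#'
#' Tracer archetypes: `"fdg"` assigns ratio (SUVR-style) kinetics with the
#' cortical shell as validation region; `"fdopa"` assigns irreversible
#' (Patlak-style) kinetics with the putamen-like region as validation region;
#' `"raclopride"` assigns reversible (SRTM) kinetics with the caudate-like
#' region as validation region. The cerebellum-like region always carries the
#' gamma-variate reference curve `A t^b exp(-t / tau)`.
#'
#' The default frame schedule is 6 x 0.5, 4 x 3, 12 x 4 min (63 min total).
#' The default `noise_scale` (8.5) was set analytically so the putamen-like
#' region's last-frame regional-mean SNR is ~20 under the fdopa archetype.
#'
#' @param tracer `"fdopa"`, `"fdg"` or `"raclopride"`.
#' @param grid_shape voxels per axis.
#' @param voxel_size mm (isotropic).
#' @param psf_fwhm scanner PSF FWHM in mm.
#' @param noise_scale scale of the frame-dependent Gaussian noise (voxel sd
#'   is `noise_scale * sqrt(activity / frame_duration)`).
#' @param seed RNG seed for the noise.
#' @param frame_starts,frame_durations minutes.
#' @param regions list of region primitives (name, type, center, semi-axes or
#'   size in mm, label, optional `within` host); `NULL` for the default brain
#'   phantom.
#' @param kinetics named list (region -> archetype spec); `NULL` for the
#'   tracer's defaults.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(tracer = c("fdopa", "fdg", "raclopride"),
                         grid_shape = c(49, 57, 49), voxel_size = 2,
                         psf_fwhm = 6.5, noise_scale = 8.5, seed = 1,
                         frame_starts = NULL, frame_durations = NULL,
                         regions = NULL, kinetics = NULL) {
  tracer <- match.arg(tracer)
  if (is.null(frame_durations))
    frame_durations <- c(rep(0.5, 6), rep(3, 4), rep(4, 12))
  if (is.null(frame_starts))
    frame_starts <- cumsum(c(0, frame_durations[-length(frame_durations)]))
  if (is.null(regions)) regions <- default_phantom_regions()
  if (is.null(kinetics)) kinetics <- default_phantom_kinetics(tracer)
  structure(list(tracer = tracer, grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size, psf_fwhm = psf_fwhm,
                 noise_scale = noise_scale, seed = seed,
                 frame_starts = frame_starts,
                 frame_durations = frame_durations,
                 regions = regions, kinetics = kinetics),
            class = "phantom_spec")
}

default_phantom_regions <- function() {
  list(
    list(name = "cortex", type = "ellipsoid_shell", center = c(0, 0, 0),
         semi_axes = c(34, 42, 34), inner_scale = 0.8, label = 1L),
    list(name = "deep", type = "ellipsoid", center = c(0, 0, 0),
         semi_axes = c(34, 42, 34) * 0.8, label = 2L),
    list(name = "putamen", type = "ellipsoid", center = c(14, 4, 0),
         semi_axes = c(12, 9, 9), label = 3L, within = "deep"),
    list(name = "caudate", type = "ellipsoid", center = c(-14, 8, 4),
         semi_axes = c(9, 7, 6), label = 4L, within = "deep"),
    list(name = "cerebellum", type = "ellipsoid", center = c(0, -20, -8),
         semi_axes = c(16, 10, 10), label = 5L, within = "deep"))
}

# gamma-variate reference curve shared by all archetypes
default_reference_params <- function() list(A = 4, b = 1, tau = 15)

default_phantom_kinetics <- function(tracer) {
  ref <- list(archetype = "reference", params = default_reference_params())
  switch(tracer,
    fdg = list(
      cortex = list(archetype = "ratio", params = list(scale = 2.0)),
      deep = list(archetype = "ratio", params = list(scale = 0.8)),
      putamen = list(archetype = "ratio", params = list(scale = 2.2)),
      caudate = list(archetype = "ratio", params = list(scale = 2.1)),
      cerebellum = ref),
    fdopa = list(
      cortex = list(archetype = "ratio", params = list(scale = 0.9)),
      deep = list(archetype = "ratio", params = list(scale = 0.55)),
      putamen = list(archetype = "irreversible",
                     params = list(Ki = 0.012, V = 1.0)),
      caudate = list(archetype = "irreversible",
                     params = list(Ki = 0.008, V = 0.9)),
      cerebellum = ref),
    raclopride = list(
      cortex = list(archetype = "reversible",
                    params = list(R1 = 1.0, k2 = 0.25, BPnd = 0.3)),
      deep = list(archetype = "ratio", params = list(scale = 0.5)),
      putamen = list(archetype = "reversible",
                     params = list(R1 = 1.0, k2 = 0.3, BPnd = 2.5)),
      caudate = list(archetype = "reversible",
                     params = list(R1 = 1.0, k2 = 0.3, BPnd = 2.0)),
      cerebellum = ref))
}

#' Region validated for each tracer archetype
#'
#' @param tracer tracer archetype name.
#' @return Region name (`"cortex"`, `"putamen"` or `"caudate"`).
#' @export
validation_region <- function(tracer) {
  switch(tracer, fdg = "cortex", fdopa = "putamen", raclopride = "caudate",
         stop_pq("unknown tracer '%s'", tracer))
}

#' Rasterize the label phantom of a specification
#'
#' Primitives are rasterized at the spec's voxel size on a grid whose world
#' origin is the grid center. Primitives carrying a `within` host are carved
#' out of that host; any other overlap between primitives is an error.
#'
#' @param spec a [phantom_spec].
#' @return A [label_volume].
#' @export
make_label_phantom <- function(spec) {
  dims <- spec$grid_shape
  vs <- spec$voxel_size
  affine <- diag(c(vs, vs, vs, 1))
  affine[1:3, 4] <- -(dims - 1) / 2 * vs
  pts <- grid_world_coords(dims, affine)
  labels <- array(0L, dims)
  name_map <- integer(0)
  host_label <- function(nm) {
    h <- Filter(function(r) r$name == nm, spec$regions)
    assert_that(length(h) == 1, "unknown host region '%s'", nm)
    h[[1]]$label
  }
  for (r in spec$regions) {
    m <- rasterize_primitive(r, pts, dims)
    assert_that(any(m), "region '%s' is empty at this grid resolution", r$name)
    if (is.null(r$within)) {
      if (any(labels[m] != 0))
        stop_pq("overlapping primitives: '%s' intersects an earlier region",
                r$name)
    } else {
      hl <- host_label(r$within)
      if (any(labels[m] != hl))
        stop_pq("overlapping primitives: '%s' extends outside its host '%s'",
                r$name, r$within)
    }
    labels[m] <- r$label
    name_map[r$name] <- r$label
  }
  label_volume(labels, affine, name_map)
}

rasterize_primitive <- function(r, pts, dims) {
  d <- sweep(pts, 2, r$center)
  inside <- switch(r$type,
    ellipsoid = rowSums(sweep(d, 2, r$semi_axes, "/")^2) <= 1,
    cuboid = apply(abs(d) <= matrix(r$size / 2, nrow(d), 3, byrow = TRUE),
                   1, all),
    ellipsoid_shell = {
      outer_in <- rowSums(sweep(d, 2, r$semi_axes, "/")^2) <= 1
      inner_in <- rowSums(sweep(d, 2, r$semi_axes * r$inner_scale, "/")^2) <= 1
      outer_in & !inner_in
    },
    stop_pq("unknown primitive type '%s'", r$type))
  array(inside, dims)
}

# analytic running integral of the gamma-variate A t^b exp(-t/tau)
gamma_variate <- function(t, p) p$A * t^p$b * exp(-t / p$tau)

gamma_variate_integral <- function(t, p) {
  p$A * p$tau^(p$b + 1) * gamma(p$b + 1) * stats::pgamma(t / p$tau, p$b + 1)
}

#' Simulate a regional time-activity curve for a tracer archetype
#'
#' Archetypes: `"reference"` evaluates the gamma-variate
#' `A t^b exp(-t / tau)` at frame mid-times; `"ratio"` scales the reference
#' curve (SUVR-style kinetics); `"irreversible"` builds
#' `Ki * int_0^t C_ref + V * C_ref` with the running integral evaluated
#' analytically (so a Patlak plot of the pair is exactly linear with slope
#' `Ki`); `"reversible"` integrates the simplified-reference-tissue-model ODE
#' `dC_t/dt = (k2 - R1 k2a) C_ref - k2a (C_t - R1 C_ref) ...` on a fine grid
#' (0.01 min, lsoda) and averages within each frame. All archetypes start at
#' activity 0.
#'
#' @param archetype one of `"reference"`, `"ratio"`, `"irreversible"`,
#'   `"reversible"`.
#' @param params archetype parameters (see above); reversible/irreversible/
#'   ratio accept a `ref` element overriding the default reference-curve
#'   parameters.
#' @param frame_starts,frame_durations frame schedule (minutes).
#' @param source region name recorded in the TAC.
#' @return A list: `tac` (a [tac]) and `truth` (archetype, parameters, and
#'   derived quantities such as `DVR`).
#' @export
simulate_tacs <- function(archetype, params, frame_starts, frame_durations,
                          source = NA_character_) {
  mids <- frame_starts + frame_durations / 2
  ref <- params$ref %||% default_reference_params()
  truth <- list(archetype = archetype, params = params)
  if (archetype == "reference") {
    p <- params[c("A", "b", "tau")]
    assert_that(p$tau > 0 && p$A >= 0 && p$b >= 0,
                "reference parameters must be non-negative (tau > 0)")
    act <- gamma_variate(mids, p)
  } else if (archetype == "ratio") {
    assert_that(params$scale >= 0, "ratio scale must be >= 0")
    act <- params$scale * gamma_variate(mids, ref)
    truth$SUVR <- params$scale
  } else if (archetype == "irreversible") {
    assert_that(params$Ki >= 0 && params$V >= 0,
                "rate constants must be non-negative")
    act <- params$Ki * gamma_variate_integral(mids, ref) +
      params$V * gamma_variate(mids, ref)
    truth$Ki <- params$Ki
    truth$V <- params$V
  } else if (archetype == "reversible") {
    assert_that(params$R1 >= 0 && params$k2 >= 0 && params$BPnd >= 0,
                "rate constants must be non-negative")
    k2a <- params$k2 / (1 + params$BPnd)
    end <- max(frame_starts + frame_durations)
    fine <- seq(0, end, by = 0.01)
    # y = C_t - R1 C_ref;  dy/dt = (k2 - R1 k2a) C_ref - k2a y
    sol <- deSolve::ode(
      y = c(y = 0), times = fine,
      func = function(t, y, parms)
        list((params$k2 - params$R1 * k2a) * gamma_variate(t, ref) -
               k2a * y[1]),
      parms = NULL, method = "lsoda")
    ct_fine <- sol[, 2] + params$R1 * gamma_variate(fine, ref)
    act <- vapply(seq_along(mids), function(i) {
      inwin <- fine >= frame_starts[i] &
        fine <= frame_starts[i] + frame_durations[i]
      mean(ct_fine[inwin])
    }, numeric(1))
    truth$k2a <- k2a
    truth$DVR <- 1 + params$BPnd
    truth$BPnd <- params$BPnd
  } else {
    stop_pq("unknown archetype '%s'", archetype)
  }
  list(tac = tac(mids, act, frame_durations, source = source), truth = truth)
}

#' Render a dynamic PET acquisition from a label phantom
#'
#' Per frame: paint each region's true activity into its voxels, blur with
#' the PSF, then add zero-mean Gaussian noise with voxel standard deviation
#' `noise_scale * sqrt(activity / frame_duration)` (the blurred noiseless
#' activity; air stays noiseless). Fully reproducible given the seed.
#'
#' @param labels a [label_volume].
#' @param tacs named list (region name -> [tac]) covering every non-zero
#'   label.
#' @param psf_ a [psf] or scalar fwhm (mm).
#' @param noise_scale noise level; 0 disables noise.
#' @param seed RNG seed.
#' @return A list: `pet` (a [dynamic_pet]) and `truth` (the inputs: `tacs`,
#'   `psf`, `noise_scale`, `seed`).
#' @export
render_dynamic_pet <- function(labels, tacs, psf_, noise_scale = 0, seed = 1) {
  if (!inherits(psf_, "psf")) psf_ <- psf(psf_)
  ids <- sort(setdiff(unique(as.integer(labels$labels)), 0L))
  nms <- region_names_for(labels, ids)
  missing <- setdiff(nms, names(tacs))
  assert_that(length(missing) == 0, "missing TAC for region(s): %s",
              paste(missing, collapse = ", "))
  t0 <- tacs[[nms[1]]]
  nf <- length(t0$frame_mid_times)
  dims <- dim(labels$labels)
  act_lut <- matrix(0, max(ids) + 1, nf)
  for (i in seq_along(ids))
    act_lut[ids[i] + 1, ] <- tacs[[nms[i]]]$activity
  sig <- psf_$sigma / labels$voxel_sizes
  lab1 <- as.integer(labels$labels) + 1L
  frames <- array(0, c(dims, nf))
  durations <- t0$frame_durations
  with_seed(seed, {
    for (f in seq_len(nf)) {
      painted <- array(act_lut[lab1, f], dims)
      blurred <- blur_array(painted, sig)
      if (noise_scale > 0) {
        sd <- noise_scale * sqrt(pmax(blurred, 0) / durations[f])
        blurred <- blurred + stats::rnorm(length(blurred), 0, sd)
      }
      frames[, , , f] <- blurred
    }
  })
  starts <- t0$frame_mid_times - durations / 2
  pet <- dynamic_pet(frames, labels$affine, starts, durations)
  list(pet = pet, truth = list(tacs = tacs, psf = psf_,
                               noise_scale = noise_scale, seed = seed))
}

#' Build the full synthetic phantom bundle for a specification
#'
#' Rasterizes the label phantom, simulates every region's true TAC, renders
#' the noisy blurred dynamic acquisition, and builds a T1-weighted proxy
#' image (distinct tissue intensities, lightly blurred) for coregistration.
#'
#' @param spec a [phantom_spec].
#' @return A list of class `phantom_bundle`: `labels`, `t1`, `pet`, `truth`
#'   (per-region TACs and kinetic parameters, PSF, noise, seed, tracer).
#' @export
render_phantom <- function(spec) {
  labels <- make_label_phantom(spec)
  sims <- lapply(names(spec$kinetics), function(nm) {
    k <- spec$kinetics[[nm]]
    simulate_tacs(k$archetype, k$params, spec$frame_starts,
                  spec$frame_durations, source = nm)
  })
  names(sims) <- names(spec$kinetics)
  tacs <- lapply(sims, `[[`, "tac")
  rendered <- render_dynamic_pet(labels, tacs, psf(spec$psf_fwhm),
                                 spec$noise_scale, spec$seed)
  structure(list(labels = labels, t1 = t1_proxy(labels), pet = rendered$pet,
                 truth = list(tacs = tacs,
                              kinetics = lapply(sims, `[[`, "truth"),
                              psf = psf(spec$psf_fwhm),
                              noise_scale = spec$noise_scale,
                              seed = spec$seed, tracer = spec$tracer,
                              validation_region = validation_region(spec$tracer))),
            class = "phantom_bundle")
}

# T1-weighted proxy: distinct tissue intensities, 2 mm blur
t1_proxy <- function(labels) {
  lut <- c(0, 80, 100, 95, 92, 85)
  ids <- sort(unique(as.integer(labels$labels)))
  full_lut <- numeric(max(ids) + 1)
  full_lut[seq_along(lut)] <- lut
  painted <- array(full_lut[as.integer(labels$labels) + 1L],
                   dim(labels$labels))
  volume3d(blur_array(painted, psf(2)$sigma / labels$voxel_sizes),
           labels$affine)
}

#' Apply a known misregistration to a dynamic series
#'
#' All frames are resampled through the rigid transform; the applied
#' transform is recorded in the `"applied_transform"` attribute so that
#' registration and QC experiments retain their ground truth.
#'
#' @param pet a [dynamic_pet].
#' @param transform a [rigid_transform].
#' @return A [dynamic_pet].
#' @export
apply_misregistration <- function(pet, transform) {
  out <- resample_dynamic(pet, transform)
  attr(out, "applied_transform") <- transform
  out
}

#' Write a ready-to-run BIDS tree of phantom subjects
#'
#' Emits `sub-XX/anat/*_T1w.nii`, `sub-XX/anat/*_dseg.nii`,
#' `sub-XX/pet/*_task-rest_pet.nii` (+ JSON timing sidecar) for each subject
#' (uncompressed NIfTI, so repeated runs are byte-identical), plus a
#' `ground_truth.json` at the root. Subjects share the anatomy and differ by
#' noise seed (`seed + subject index`).
#'
#' @param root output directory.
#' @param n_subjects number of subjects.
#' @param tracer tracer archetype.
#' @param seed base seed.
#' @param noise_scale noise level passed to the spec.
#' @param spec optionally a full [phantom_spec] overriding the above.
#' @return `root`, invisibly.
#' @export
phantom_bids_tree <- function(root, n_subjects = 5,
                              tracer = "fdopa", seed = 1, noise_scale = 8.5,
                              spec = NULL) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  truth_out <- list()
  for (s in seq_len(n_subjects)) {
    sp <- spec %||% phantom_spec(tracer, noise_scale = noise_scale)
    sp$seed <- seed + s
    bundle <- render_phantom(sp)
    sub <- sprintf("sub-%02d", s)
    anat <- file.path(root, sub, "anat")
    petd <- file.path(root, sub, "pet")
    dir.create(anat, recursive = TRUE, showWarnings = FALSE)
    dir.create(petd, recursive = TRUE, showWarnings = FALSE)
    write_volume(bundle$t1, file.path(anat, paste0(sub, "_T1w.nii")))
    write_volume(
      volume3d(bundle$labels$labels + 0, bundle$labels$affine),
      file.path(anat, paste0(sub, "_dseg.nii")))
    write_dynamic_pet(bundle$pet,
                      file.path(petd, paste0(sub, "_task-rest_pet.nii")))
    truth_out[[sub]] <- list(
      tracer = sp$tracer, seed = sp$seed,
      psf_fwhm = sp$psf_fwhm, noise_scale = sp$noise_scale,
      validation_region = validation_region(sp$tracer),
      kinetics = bundle$truth$kinetics,
      tacs = lapply(bundle$truth$tacs, function(t)
        list(frame_mid_times = t$frame_mid_times, activity = t$activity)))
  }
  jsonlite::write_json(truth_out, file.path(root, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(root)
}
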