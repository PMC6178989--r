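test_that("rasterized ellipsoids match their analytic volume", {
  sp <- phantom_spec("fdopa", grid_shape = c(25, 25, 25), voxel_size = 2,
                     regions = list(
                       list(name = "blob", type = "ellipsoid",
                            center = c(0, 0, 0), semi_axes = c(10, 7, 7),
                            label = 1L)),
                     kinetics = list(blob = list(
                       archetype = "ratio", params = list(scale = 1))))
  lab <- make_label_phantom(sp)
  vol <- sum(lab$labels == 1L) * prod(lab$voxel_sizes)
  expect_lt(abs(vol - 4 * pi * 10 * 7 * 7 / 3) / (4 * pi * 10 * 7 * 7 / 3),
            0.1)
})

test_that("default phantom regions are disjoint, named, and sized sensibly", {
  b <- default_bundle_noiseless()
  lab <- b$labels
  expect_setequal(names(lab$name_map),
                  c("cortex", "deep", "putamen", "caudate", "cerebellum"))
  # every voxel carries exactly one label by construction of the array
  expect_true(all(lab$labels %in% 0:5))
  putamen_cm3 <- sum(lab$labels == lab$name_map[["putamen"]]) *
    prod(lab$voxel_sizes) / 1000
  expect_gt(putamen_cm3, 3.5)
})

test_that("overlapping primitives are rejected", {
  sp <- phantom_spec("fdopa", regions = list(
    list(name = "a", type = "ellipsoid", center = c(0, 0, 0),
         semi_axes = c(10, 10, 10), label = 1L),
    list(name = "b", type = "ellipsoid", center = c(5, 0, 0),
         semi_axes = c(10, 10, 10), label = 2L)))
  expect_error(make_label_phantom(sp), "overlapping")
})

test_that("label phantom generation is deterministic", {
  sp <- phantom_spec("fdg", seed = 9)
  expect_identical(make_label_phantom(sp)$labels,
                   make_label_phantom(sp)$labels)
})

test_that("tracer archetypes start at zero and satisfy their kinetics", {
  fr <- default_frames()
  ref <- simulate_tacs("reference", list(A = 4, b = 1, tau = 15),
                       fr$starts, fr$durations)
  expect_equal(petquant:::gamma_variate(0, list(A = 4, b = 1, tau = 15)), 0)
  expect_true(all(ref$tac$activity > 0))

  # reversible: late-time target/reference ratio approaches DVR once the
  # input decays slowly enough for quasi-equilibrium (tau = 40 min here)
  slow_ref <- list(A = 4, b = 1, tau = 40)
  rv <- simulate_tacs("reversible",
                      list(R1 = 1, k2 = 0.1, BPnd = 1.5, ref = slow_ref),
                      fr$starts, fr$durations)
  ref_slow <- simulate_tacs("reference", slow_ref, fr$starts, fr$durations)
  late <- length(fr$mids)
  expect_lt(abs(rv$tac$activity[late] / ref_slow$tac$activity[late] -
                  rv$truth$DVR) / rv$truth$DVR, 0.1)

  # irreversible: Patlak plot of the generated pair is linear with slope Ki
  ir <- simulate_tacs("irreversible", list(Ki = 0.012, V = 1),
                      fr$starts, fr$durations)
  f <- patlak(ir$tac, ref$tac, 20)
  expect_gt(f$goodness, 0.999)
  expect_lt(abs(f$parameters$Ki - 0.012) / 0.012, 0.02)

  expect_error(simulate_tacs("reversible",
                             list(R1 = 1, k2 = -0.1, BPnd = 1),
                             fr$starts, fr$durations), "non-negative")
})

test_that("rendering without blur or noise reproduces regional TACs exactly", {
  sp <- small_phantom_spec("fdopa")
  lab <- make_label_phantom(sp)
  sims <- lapply(names(sp$kinetics), function(nm)
    simulate_tacs(sp$kinetics[[nm]]$archetype, sp$kinetics[[nm]]$params,
                  sp$frame_starts, sp$frame_durations, source = nm)$tac)
  names(sims) <- names(sp$kinetics)
  out <- render_dynamic_pet(lab, sims, psf(0), noise_scale = 0)
  for (nm in c("putamen", "cerebellum")) {
    got <- extract_tac(out$pet, lab, nm)
    expect_equal(got$activity, sims[[nm]]$activity, tolerance = 1e-12)
  }
  expect_error(render_dynamic_pet(lab, sims[-1], psf(0)), "missing TAC")
})

test_that("blur induces spill-out in small bright regions and is seeded", {
  b <- small_bundle_noiseless()  # psf 6.5, noise 0
  obs <- extract_tac(b$pet, b$labels, "putamen")
  r <- tac_integral(obs, 60) / tac_integral(b$truth$tacs$putamen, 60)
  expect_lt(r, 1)

  sp <- small_phantom_spec("fdopa", noise_scale = 8.5, seed = 77)
  p1 <- render_phantom(sp)$pet
  p2 <- render_phantom(sp)$pet
  expect_identical(p1$frames, p2$frames)
  sp2 <- small_phantom_spec("fdopa", noise_scale = 8.5, seed = 78)
  expect_false(identical(render_phantom(sp2)$pet$frames, p1$frames))
})

test_that("rendering noise is unbiased across seeds", {
  sp <- small_phantom_spec("fdopa", noise_scale = 8.5)
  lab <- make_label_phantom(sp)
  noiseless <- small_bundle_noiseless()
  truth <- extract_tac(noiseless$pet, lab, "putamen")$activity
  n_seeds <- 20
  acts <- vapply(seq_len(n_seeds), function(s) {
    sp$seed <- 1000 + s
    extract_tac(render_phantom(sp)$pet, lab, "putamen")$activity
  }, numeric(length(truth)))
  mc_mean <- rowMeans(acts)
  mc_se <- apply(acts, 1, sd) / sqrt(n_seeds)
  expect_true(all(abs(mc_mean - truth) <= 3 * mc_se + 1e-9))
})

test_that("misregistration moves the center of mass as requested", {
  b <- small_bundle_noiseless()
  same <- apply_misregistration(b$pet, rigid_transform())
  expect_lt(max(abs(same$frames - b$pet$frames)), 1e-9)

  tf <- rigid_transform(translations = c(7, 0, 0))
  moved <- apply_misregistration(b$pet, tf)
  com <- function(p) {
    v <- time_weighted_average(p)
    petquant:::center_of_mass(v)
  }
  delta <- com(moved) - com(b$pet)
  expect_equal(delta[1], 7, tolerance = 0.5)
  expect_lt(max(abs(delta[2:3])), 0.5)
  expect_identical(attr(moved, "applied_transform"), tf)

  # near-involution: applying the inverse brings the series back
  back <- apply_misregistration(moved, transform_invert(tf))
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(back$frames - b$pet$frames), 0.1 * rms(b$pet$frames))
})

test_that("the phantom BIDS tree is complete and discoverable", {
  root <- withr::local_tempdir()
  phantom_bids_tree(root, n_subjects = 2, tracer = "fdg", seed = 5,
                    spec = small_phantom_spec("fdg", noise_scale = 8.5))
  recs <- discover_bids(root)
  expect_equal(nrow(recs), 2)
  expect_true(all(!is.na(recs$t1_path)))
  expect_true(all(!is.na(recs$label_path)))
  expect_true(file.exists(file.path(root, "ground_truth.json")))
  gt <- jsonlite::read_json(file.path(root, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$`sub-01`$validation_region, "cortex")
})
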