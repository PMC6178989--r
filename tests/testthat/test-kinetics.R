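ref_tac <- function() {
  fr <- default_frames()
  simulate_tacs("reference", list(A = 4, b = 1, tau = 15),
                fr$starts, fr$durations, source = "ref")$tac
}

test_that("extract_tac averages region voxels per frame", {
  dims <- c(4, 2, 2)
  lab_arr <- array(0L, dims)
  lab_arr[1:8] <- 1L
  lab_arr[9:10] <- 2L
  lab <- label_volume(lab_arr, grid_affine(2))
  fr <- array(5, c(dims, 3))
  pet <- dynamic_pet(fr, lab$affine, 0:2, rep(1, 3))
  expect_equal(extract_tac(pet, lab, 1)$activity, rep(5, 3))

  # 2-voxel region with values 1 and 3 averages to 2
  fr2 <- fr
  for (f in 1:3) fr2[c(9, 10) + (f - 1) * prod(dims)] <- c(1, 3)
  pet2 <- dynamic_pet(fr2, lab$affine, 0:2, rep(1, 3))
  expect_equal(extract_tac(pet2, lab, 2)$activity, rep(2, 3))

  # brute-force oracle on a random phantom
  set.seed(20)
  frr <- array(rnorm(prod(dims) * 3, 10), c(dims, 3))
  pet3 <- dynamic_pet(frr, lab$affine, 0:2, rep(1, 3))
  manual <- sapply(1:3, function(f) {
    v <- frr[, , , f]
    mean(v[lab$labels == 1L])
  })
  expect_equal(extract_tac(pet3, lab, 1)$activity, manual)
  expect_error(extract_tac(pet3, lab, 9), "empty")
})

test_that("tac_integral is the 0-anchored trapezoid", {
  mids <- c(0.5, 1.5, 3, 5, 7, 10)
  t1 <- tac(mids, rep(1, 6), source = "c")
  # leading segment rises from the (0, 0) anchor: area 0.25 instead of 0.5
  expect_equal(tac_integral(t1, 10), 9.75, tolerance = 1e-12)
  dense <- seq(0.05, 10, by = 0.05)
  t2 <- tac(dense, dense, source = "lin")
  expect_equal(tac_integral(t2, 10), 50, tolerance = 1e-3)
  expect_equal(tac_integral(t1, 0.5), 0.5 * 1 / 2, tolerance = 1e-12)
  expect_error(tac_integral(t1, 0.2), "precedes")
  expect_error(tac_integral(t1, 11), "beyond")
})

test_that("Logan slope is exact on proportional TACs", {
  ref <- ref_tac()
  target <- tac(ref$frame_mid_times, 2 * ref$activity, ref$frame_durations)
  f <- logan(target, ref, 20)
  expect_equal(f$parameters$DVR, 2, tolerance = 1e-10)
  expect_equal(f$parameters$BPnd, 1, tolerance = 1e-10)
  expect_equal(f$goodness, 1, tolerance = 1e-10)
})

test_that("Logan recovers BPnd from SRTM-simulated data and flags bad input", {
  fr <- default_frames()
  ref <- ref_tac()
  s <- simulate_tacs("reversible", list(R1 = 1, k2 = 0.3, BPnd = 1.5),
                     fr$starts, fr$durations)
  f <- logan(s$tac, ref, 20)
  expect_lt(abs(f$parameters$BPnd - 1.5) / 1.5, 0.05)
  expect_error(logan(s$tac, ref, 70), "beyond the last frame")
  bad <- tac(ref$frame_mid_times, ref$activity - max(ref$activity),
             ref$frame_durations)
  expect_error(logan(bad, ref, 20), "nonpositive")
})

test_that("Logan DVR increases with simulated BPnd", {
  fr <- default_frames()
  ref <- ref_tac()
  dvr <- vapply(c(0.5, 1, 2), function(bp) {
    s <- simulate_tacs("reversible", list(R1 = 1, k2 = 0.3, BPnd = bp),
                       fr$starts, fr$durations)
    logan(s$tac, ref, 20)$parameters$DVR
  }, numeric(1))
  expect_true(all(diff(dvr) > 0))
})

test_that("Patlak recovers a constructed Ki and V exactly", {
  ref <- ref_tac()
  mids <- ref$frame_mid_times
  ct <- 0.01 * petquant:::cumtrapz0(mids, ref$activity) + 1.0 * ref$activity
  target <- tac(mids, ct, ref$frame_durations)
  f <- patlak(target, ref, 20)
  expect_equal(f$parameters$Ki, 0.01, tolerance = 1e-10)
  expect_equal(f$parameters$V, 1.0, tolerance = 1e-8)
  expect_equal(f$goodness, 1, tolerance = 1e-10)

  zero_ref <- tac(mids, c(rep(1, 10), rep(0, 12)), ref$frame_durations)
  expect_error(patlak(target, zero_ref, 20), "nonpositive input")
})

test_that("Patlak on simulated irreversible kinetics is t_star-insensitive", {
  fr <- default_frames()
  ref <- ref_tac()
  s <- simulate_tacs("irreversible", list(Ki = 0.012, V = 1),
                     fr$starts, fr$durations)
  k20 <- patlak(s$tac, ref, 20)$parameters$Ki
  k30 <- patlak(s$tac, ref, 30)$parameters$Ki
  expect_lt(abs(k20 - 0.012) / 0.012, 0.05)
  expect_lt(abs(k20 - k30) / k20, 0.02)
})

test_that("SRTM recovers its own forward simulation within 3%", {
  fr <- default_frames()
  ref <- ref_tac()
  s <- simulate_tacs("reversible", list(R1 = 1.0, k2 = 0.1, BPnd = 1.5),
                     fr$starts, fr$durations)
  f <- srtm(s$tac, ref)
  expect_lt(abs(f$parameters$R1 - 1.0), 0.03)
  expect_lt(abs(f$parameters$k2 - 0.1) / 0.1, 0.03)
  expect_lt(abs(f$parameters$BPnd - 1.5) / 1.5, 0.03)

  s0 <- simulate_tacs("reversible", list(R1 = 0.9, k2 = 0.15, BPnd = 0),
                      fr$starts, fr$durations)
  f0 <- srtm(s0$tac, ref)
  expect_lt(abs(f0$parameters$BPnd), 0.05)

  expect_error(srtm(s$tac, ref, k2a_grid = 0.05), "degenerate")
  expect_warning(srtm(s$tac, ref, k2a_grid = c(0.5, 0.75, 1)), "bracket")
})

test_that("SUVR is the duration-weighted ratio and is scale invariant", {
  mids <- c(1, 3, 5, 7)
  durs <- c(2, 2, 2, 2)
  expect_equal(suvr(tac(mids, rep(2, 4), durs), tac(mids, rep(1, 4), durs),
                    c(0, 8))$parameters$SUVR, 2)
  t1 <- tac(mids, c(1, 2, 3, 4), durs)
  t2 <- tac(mids, c(2, 2, 1, 1), durs)
  f <- suvr(t1, t2, c(2, 8))
  f7 <- suvr(tac(mids, 7 * t1$activity, durs),
             tac(mids, 7 * t2$activity, durs), c(2, 8))
  expect_equal(f$parameters$SUVR, f7$parameters$SUVR, tolerance = 1e-12)
  # window covering exactly two frames, hand-computed weighted means
  fw <- suvr(t1, t2, c(2.5, 5.5))
  expect_equal(fw$parameters$SUVR, mean(c(2, 3)) / mean(c(2, 1)),
               tolerance = 1e-12)
  expect_equal(fw$n_points_used, 2)
  expect_error(suvr(t1, t2, c(8.5, 9)), "empty")
})

test_that("graphical slopes are invariant to joint rescaling", {
  fr <- default_frames()
  ref <- ref_tac()
  s <- simulate_tacs("irreversible", list(Ki = 0.01, V = 0.9),
                     fr$starts, fr$durations)
  scale_tac <- function(t, k) tac(t$frame_mid_times, k * t$activity,
                                  t$frame_durations)
  f1 <- patlak(s$tac, ref, 20)
  f2 <- patlak(scale_tac(s$tac, 7), scale_tac(ref, 7), 20)
  expect_equal(f1$parameters$Ki, f2$parameters$Ki, tolerance = 1e-12)
  l1 <- logan(s$tac, ref, 20)
  l2 <- logan(scale_tac(s$tac, 7), scale_tac(ref, 7), 20)
  expect_equal(l1$parameters$DVR, l2$parameters$DVR, tolerance = 1e-12)
})

test_that("arterial input curves drop the BPnd report in Logan", {
  ref <- ref_tac()
  art <- input_curve(ref$frame_mid_times, ref$activity, "arterial_plasma")
  target <- tac(ref$frame_mid_times, 2 * ref$activity, ref$frame_durations)
  f <- logan(target, art, 20)
  expect_true("Vt" %in% names(f$parameters))
  expect_false("BPnd" %in% names(f$parameters))
})

test_that("voxelwise maps agree with ROI fits on piecewise-constant data", {
  fr <- default_frames()
  ref <- ref_tac()
  s <- simulate_tacs("irreversible", list(Ki = 0.012, V = 1),
                     fr$starts, fr$durations)
  dims <- c(6, 5, 4)
  lab <- array(0L, dims)
  lab[2:5, 2:4, 2:3] <- 1L
  frames <- array(0, c(dims, length(fr$mids)))
  for (f in seq_along(fr$mids)) {
    v <- array(0, dims)
    v[lab == 1L] <- s$tac$activity[f]
    frames[, , , f] <- v
  }
  pet <- dynamic_pet(frames, grid_affine(2), fr$starts, fr$durations)

  pm <- voxelwise_map(pet, ref, "patlak", t_star = 20)
  roi <- patlak(s$tac, ref, 20)$parameters$Ki
  expect_lt(max(abs(pm$map$data[lab == 1L] - roi)), 1e-6)
  # all-zero voxels are masked out at 0
  expect_true(all(pm$failed[lab == 0L]))
  expect_true(all(pm$map$data[lab == 0L] == 0))
  expect_false(any(pm$failed[lab == 1L]))

  sm <- voxelwise_map(pet, ref, "suvr", window = c(40, 60))
  roi_s <- suvr(s$tac, ref, c(40, 60))$parameters$SUVR
  expect_lt(max(abs(sm$map$data[lab == 1L] - roi_s)), 1e-6)

  rv <- simulate_tacs("reversible", list(R1 = 1, k2 = 0.3, BPnd = 1.5),
                      fr$starts, fr$durations)
  frames2 <- frames
  for (f in seq_along(fr$mids)) {
    v <- array(0, dims)
    v[lab == 1L] <- rv$tac$activity[f]
    frames2[, , , f] <- v
  }
  pet2 <- dynamic_pet(frames2, grid_affine(2), fr$starts, fr$durations)
  bm <- voxelwise_map(pet2, ref, "srtm")
  roi_b <- srtm(rv$tac, ref, refine = FALSE)$parameters$BPnd
  expect_lt(max(abs(bm$map$data[lab == 1L] - roi_b)), 1e-6)
})
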