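test_that("volume write/read round-trips data and affine", {
  v <- random_volume(c(8, 8, 8))
  f <- withr::local_tempfile(fileext = ".nii")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_lt(max(abs(v2$data - v$data)), 1e-6)
  expect_lt(max(abs(v2$affine - v$affine)), 1e-5)
  expect_equal(v2$voxel_sizes, v$voxel_sizes, tolerance = 1e-5)
})

test_that("read_volume rejects 4D files", {
  f <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 3))), f)
  expect_error(read_volume(f), "3D")
})

test_that("dynamic PET reading converts sidecar seconds to minutes", {
  dims <- c(5, 5, 5, 3)
  pet <- dynamic_pet(array(rnorm(prod(dims)), dims), grid_affine(),
                     frame_starts = c(0, 1, 3), frame_durations = c(1, 2, 2))
  f <- withr::local_tempfile(fileext = ".nii")
  write_dynamic_pet(pet, f)
  p2 <- read_dynamic_pet(f)
  expect_equal(p2$frame_starts, c(0, 1, 3))
  expect_equal(p2$frame_durations, c(1, 2, 2))
  expect_lt(max(abs(p2$frames - pet$frames)), 1e-6)
  # sidecar itself must be in seconds
  side <- jsonlite::read_json(sub("\\.nii$", ".json", f),
                              simplifyVector = TRUE)
  expect_equal(side$FrameTimesStart, c(0, 60, 180))
})

test_that("frame-timing mismatches and missing sidecar fields are format errors", {
  dims <- c(4, 4, 4, 3)
  f <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(0, dims)), f)
  side <- sub("\\.nii$", ".json", f)
  jsonlite::write_json(list(FrameTimesStart = c(0, 60, 120),
                            FrameDuration = c(60, 60)), side)
  expect_error(read_dynamic_pet(f), "frame timing mismatch")
  jsonlite::write_json(list(FrameTimesStart = c(0, 60, 120)), side)
  expect_error(read_dynamic_pet(f), "FrameDuration")
})

test_that(".dft parsing takes frame midpoints and records units", {
  f <- withr::local_tempfile(fileext = ".dft")
  writeLines(c("# unit := kBq/cc", "# kind := plasma",
               "0 1 10", "1 2 20", "2 4 15"), f)
  cur <- parse_dft(f)
  expect_equal(cur$times, c(0.5, 1.5, 3.0))
  expect_equal(cur$activity, c(10, 20, 15))
  expect_equal(cur$kind, "arterial_plasma")
  expect_equal(cur$unit, "kBq/cc")

  # two-column time/activity dialect
  writeLines(c("# kind := reference", "1 5", "2 6", "3 7"), f)
  cur2 <- parse_dft(f)
  expect_equal(cur2$times, 1:3)
  expect_equal(cur2$kind, "reference_region")
})

test_that(".dft parse errors are informative", {
  f <- withr::local_tempfile(fileext = ".dft")
  writeLines(c("0 1 10", "1 2 20"), f)
  expect_error(parse_dft(f), ">= 3")
  writeLines(c("0 1 10", "1 2 xx", "2 4 15"), f)
  expect_error(parse_dft(f), "line 2")
  writeLines(c("0 1 10", "5 6 20", "2 4 15"), f)
  expect_error(parse_dft(f), "strictly increasing")
})

test_that("BIDS discovery parses entities and tolerates missing T1", {
  root <- withr::local_tempdir()
  mk <- function(...) {
    p <- file.path(root, ...)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    file.create(p)
    p
  }
  mk("sub-01", "pet", "sub-01_task-rest_pet.nii.gz")
  mk("sub-01", "anat", "sub-01_T1w.nii.gz")
  mk("sub-02", "pet", "sub-02_task-rest_pet.nii.gz")
  mk("sub-02", "anat", "sub-02_T1w.nii.gz")
  recs <- discover_bids(root)
  expect_equal(nrow(recs), 2)
  expect_equal(recs$task_id, c("rest", "rest"))
  expect_equal(recs$subject_id, c("01", "02"))

  mk("sub-03", "pet", "sub-03_task-rest_pet.nii.gz")
  expect_warning(recs <- discover_bids(root), "T1w")
  expect_true(is.na(recs$t1_path[recs$subject_id == "03"]))

  # full entity set parsed exactly from the filename
  ent <- petquant:::parse_bids_entities(
    "sub-01_ses-02_task-baseline_run-1_pet.nii.gz")
  expect_equal(unname(ent[c("sub", "ses", "task", "run")]),
               c("01", "02", "baseline", "1"))

  empty <- withr::local_tempdir()
  expect_error(discover_bids(empty), "no sub-")
})

test_that("BIDS discovery is deterministic and order-stable", {
  root <- withr::local_tempdir()
  for (s in c("sub-03", "sub-01", "sub-02")) {
    p <- file.path(root, s, "pet", paste0(s, "_task-rest_pet.nii.gz"))
    dir.create(dirname(p), recursive = TRUE)
    file.create(p)
    a <- file.path(root, s, "anat", paste0(s, "_T1w.nii.gz"))
    dir.create(dirname(a), recursive = TRUE)
    file.create(a)
  }
  r1 <- discover_bids(root)
  r2 <- discover_bids(root)
  expect_identical(r1, r2)
  expect_equal(r1$subject_id, c("01", "02", "03"))
})

test_that("resampling is exact for identity and integer-voxel shifts", {
  v <- random_volume(c(9, 8, 7))
  out <- resample(v, rigid_transform(), v)
  expect_lt(max(abs(out$data - v$data)), 1e-6)

  # single-hot voxel moved exactly 2 voxels along x
  hot <- array(0, c(11, 11, 11))
  hot[6, 6, 6] <- 1
  hv <- volume3d(hot, grid_affine(2))
  shifted <- resample(hv, rigid_transform(translations = c(4, 0, 0)), hv)
  peak <- which(shifted$data == max(shifted$data), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(8, 6, 6))
  expect_equal(max(shifted$data), 1, tolerance = 1e-6)
})

test_that("label resampling uses nearest neighbour and preserves the label set", {
  lab <- label_volume(array(sample(0:3, 8^3, TRUE), c(8, 8, 8)), grid_affine())
  out <- resample(lab, rigid_transform(translations = c(1.2, -0.7, 0.4)), lab,
                  "nearest")
  expect_true(all(unique(as.integer(out$labels)) %in%
                    unique(as.integer(lab$labels))))
  expect_error(resample(lab, interpolation = "trilinear"), "nearest")
})

test_that("time-weighted average weights frames by duration", {
  mk <- function(vals, durs) {
    fr <- array(rep(vals, each = 8), c(2, 2, 2, length(vals)))
    dynamic_pet(fr, grid_affine(), cumsum(c(0, durs[-length(durs)])), durs)
  }
  expect_equal(unique(as.numeric(time_weighted_average(
    mk(c(1, 3), c(1, 1)))$data)), 2)
  expect_equal(unique(as.numeric(time_weighted_average(
    mk(c(1, 3), c(3, 1)))$data)), 1.5)
  expect_equal(unique(as.numeric(time_weighted_average(
    mk(5, 2))$data)), 5)
  # invariant to splitting a frame into two contiguous halves
  expect_equal(time_weighted_average(mk(c(1, 3, 3), c(3, 0.5, 0.5)))$data,
               time_weighted_average(mk(c(1, 3), c(3, 1)))$data)
})
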