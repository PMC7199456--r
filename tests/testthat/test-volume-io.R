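make_vol <- function(arr4, spacing = c(1, 1, 1))
  multimodal_volume(arr4, spacing = spacing, patient_id = "t")

test_that("read_volume assembles four modalities in fixed channel order", {
  dir <- withr::local_tempdir()
  arr <- array(0, c(20, 20, 20, 4))
  for (ch in 1:4) arr[, , , ch] <- ch * 100 + seq_len(20)  # integer-valued
  paths <- write_volume(make_vol(arr), dir)
  expect_named(paths, modality_names())
  vol <- read_volume(unlist(paths), patient_id = "t")
  expect_equal(dim(vol$intensities), c(20, 20, 20, 4))
  expect_identical(vol$intensities, arr)     # float-exact round trip
  # named paths in scrambled order are re-ordered by modality
  vol2 <- read_volume(unlist(paths)[c(3, 1, 4, 2)][c("T1", "FLAIR", "T1ce", "T2")])
  expect_identical(vol2$intensities, arr)
})

test_that("read_volume reports missing modalities and shape mismatches", {
  dir <- withr::local_tempdir()
  arr <- array(1.0, c(18, 18, 18, 4))
  paths <- unlist(write_volume(make_vol(arr), dir))
  expect_error(read_volume(paths[c("FLAIR", "T2", "T1")]), "T1ce")
  bad <- file.path(dir, "bad.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1.0, c(10, 18, 18))), bad)
  p2 <- paths; p2["FLAIR"] <- bad
  expect_error(read_volume(p2), "shapes")
})

test_that("normalization z-scores brain voxels with the population sd", {
  arr <- array(0, c(16, 16, 16, 1))
  arr[1, 1, 1:3, 1] <- c(1, 2, 3)
  out <- normalize_volume(make_vol(arr))
  got <- out$intensities[1, 1, 1:3, 1]
  expect_equal(got, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_true(all(out$intensities[, , 5:16, ] == 0))   # background untouched
})

test_that("normalization is idempotent and rejects degenerate channels", {
  set.seed(1)
  arr <- array(0, c(16, 16, 16, 1))
  arr[4:12, 4:12, 4:12, 1] <- rnorm(9^3, mean = 5)
  once <- normalize_volume(make_vol(arr))
  twice <- normalize_volume(once)
  expect_equal(twice$intensities, once$intensities, tolerance = 1e-10)
  const <- array(0, c(16, 16, 16, 1)); const[1:5, 1, 1, 1] <- 7
  expect_error(normalize_volume(make_vol(const)), "constant")
  empty <- array(0, c(16, 16, 16, 1)); empty[1, 1, 1, 1] <- 1
  expect_error(normalize_volume(make_vol(empty)), "fewer than 2")
})

test_that("box_from_mask returns the tight half-open box", {
  m <- array(FALSE, c(12, 12, 12))
  m[6, 6, 6] <- TRUE                       # 0-based voxel (5,5,5)
  b <- box_from_mask(m)
  expect_equal(b$low, c(5L, 5L, 5L))
  expect_equal(b$high, c(6L, 6L, 6L))
  m[2, 2, 2] <- TRUE; m[5, 3, 4] <- TRUE   # 0-based (1,1,1) and (4,2,3)
  b2 <- box_from_mask(m)
  expect_equal(b2$low, c(1L, 1L, 1L))
  expect_equal(b2$high, c(6L, 6L, 6L))
  m2 <- array(FALSE, c(12, 12, 12)); m2[2, 2, 2] <- TRUE; m2[5, 3, 4] <- TRUE
  b3 <- box_from_mask(m2)
  expect_equal(b3$low, c(1L, 1L, 1L))
  expect_equal(b3$high, c(5L, 3L, 4L))
  # every positive voxel lies inside the returned box
  idx <- which(m2, arr.ind = TRUE) - 1
  expect_true(all(in_box_pts(idx, b3)))
  expect_error(box_from_mask(array(FALSE, c(4, 4, 4))), "no positive")
})

test_that("box_from_mask margin expands symmetrically but clamps at bounds", {
  m <- array(FALSE, c(10, 10, 10)); m[2:3, 5:6, 9:10] <- TRUE
  b <- box_from_mask(m, margin = 2)
  expect_equal(b$low, c(0L, 2L, 6L))
  expect_equal(b$high, c(5L, 8L, 10L))
})

test_that("box round-trips through JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  b <- box_annotation(c(1, 2, 3), c(4, 5, 6), patient_id = "p7")
  write_box(b, f)
  b2 <- read_box(f)
  expect_equal(b2$low, b$low)
  expect_equal(b2$high, b$high)
  expect_equal(b2$patient_id, "p7")
})

test_that("class prior equals brute-force voxel counting", {
  b <- box_annotation(c(1, 1, 1), c(3, 3, 3))
  expect_equal(class_prior(b, c(4, 4, 4))$pi_p, 56 / 64)
  half <- box_annotation(c(0, 0, 0), c(2, 4, 4))
  expect_equal(class_prior(half, c(4, 4, 4))$pi_p, 0.5)
  expect_error(class_prior(box_annotation(c(0, 0, 0), c(4, 4, 4)), c(4, 4, 4)),
               "whole volume")
  set.seed(42)
  for (k in 1:100) {
    shape <- sample(4:12, 3, replace = TRUE)
    lo <- vapply(shape, function(s) sample.int(s, 1) - 1L, 1L)
    hi <- vapply(seq_len(3), function(a)
      lo[a] + sample.int(shape[a] - lo[a], 1), 1L)
    if (all(hi - lo == shape)) hi[1] <- hi[1] - 1L
    if (any(hi <= lo)) next
    b <- box_annotation(lo, hi)
    grid <- as.matrix(expand.grid(0:(shape[1] - 1), 0:(shape[2] - 1),
                                  0:(shape[3] - 1)))
    inside <- sum(in_box_pts(grid, b))
    expect_equal(class_prior(b, shape)$pi_p, (prod(shape) - inside) / prod(shape))
  }
})

test_that("boxes derived from box-shaped masks are fixed points", {
  m <- array(FALSE, c(10, 12, 14)); m[3:6, 2:9, 5:5] <- TRUE
  b <- box_from_mask(m)
  m2 <- array(FALSE, dim(m))
  m2[(b$low[1] + 1):b$high[1], (b$low[2] + 1):b$high[2],
     (b$low[3] + 1):b$high[3]] <- TRUE
  expect_identical(m, m2)
  b2 <- box_from_mask(m2)
  expect_equal(b2$low, b$low); expect_equal(b2$high, b$high)
})
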