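test_that("dice handles identity, disjoint, counted and empty cases", {
  a <- array(FALSE, c(6, 6, 6)); a[2:3, 2:3, 2] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- array(FALSE, c(6, 6, 6)); b[5, 5, 5] <- TRUE
  expect_equal(dice(a, b), 0)
  # |A| = 4, |B| = 6, |A n B| = 3 -> 2*3/10
  A <- array(FALSE, c(6, 6, 6)); A[1:4, 1, 1] <- TRUE
  B <- array(FALSE, c(6, 6, 6)); B[2:4, 1, 1] <- TRUE; B[1:3, 2, 1] <- TRUE
  expect_equal(dice(A, B), 0.6)
  empty <- array(FALSE, c(6, 6, 6))
  expect_equal(dice(empty, empty), 1)
  expect_equal(dice(empty, a), 0)
  expect_equal(dice(a, b), dice(b, a))
  expect_error(dice(a, array(FALSE, c(5, 5, 5))), "shapes")
})

test_that("hausdorff distances match hand geometry", {
  A <- matrix(c(0, 0, 0), 1)
  B <- matrix(c(3, 0, 0), 1)
  expect_equal(directed_hausdorff(A, B), 3)
  expect_equal(hausdorff(A, B), 3)
  # A subset of B whose extra point sits at distance 5
  A2 <- rbind(c(0, 0, 0), c(1, 0, 0))
  B2 <- rbind(A2, c(1, 5, 0))
  expect_equal(directed_hausdorff(A2, B2), 0)
  expect_equal(directed_hausdorff(B2, A2), 5)
  expect_equal(hausdorff(A2, B2), 5)
  expect_equal(hausdorff(B2, A2), hausdorff(A2, B2))
  # spacing scales physical distance
  expect_equal(hausdorff(A, B, spacing = c(2, 1, 1)), 6)
  m <- array(TRUE, c(3, 3, 3))
  expect_equal(hausdorff(m, m), 0)
  expect_equal(hausdorff95(m, m), 0)
})

test_that("hausdorff95 of a uniformly shifted point set is the shift", {
  # 100 collinear points spaced 3 apart vs the same set shifted by 1:
  # every nearest-neighbour distance equals 1 in both directions
  A <- cbind(3 * (0:99), 0, 0)
  B <- cbind(3 * (0:99) + 1, 0, 0)
  expect_equal(hausdorff95(A, B), 1)
})

test_that("empty masks yield missing distances, never zero", {
  empty <- array(FALSE, c(4, 4, 4))
  full <- array(TRUE, c(4, 4, 4))
  expect_true(is.na(directed_hausdorff(empty, full)))
  expect_true(is.na(hausdorff(full, empty)))
  expect_true(is.na(hausdorff95(empty, empty)))
})

test_that("distance metrics agree with exhaustive oracles on random masks", {
  set.seed(21)
  for (k in 1:100) {
    side <- sample(4:16, 1)
    A <- random_mask(side); B <- random_mask(side)
    pa <- which(A, arr.ind = TRUE) * 1.0
    pb <- which(B, arr.ind = TRUE) * 1.0
    sp <- runif(3, 0.5, 2)
    expect_equal(directed_hausdorff(A, B, sp), directed_hd_oracle(pa, pb, sp),
                 tolerance = 1e-12)
    h <- hausdorff(A, B, sp)
    expect_equal(h, hd_oracle(pa, pb, sp), tolerance = 1e-12)
    h95 <- hausdorff95(A, B, sp)
    expect_equal(h95, hd95_oracle(pa, pb, sp), tolerance = 1e-9)
    expect_lte(h95, h + 1e-12)
    # surface-only variant equals the full computation for solid small masks
    expect_equal(dice(A, B), dice(B, A))
  }
})

test_that("fill_holes closes cavities, is idempotent and monotone", {
  cube <- array(FALSE, c(9, 9, 9)); cube[3:7, 3:7, 3:7] <- TRUE
  holed <- cube; holed[5, 5, 5] <- FALSE
  expect_identical(fill_holes(holed), cube)
  expect_identical(fill_holes(cube), cube)          # no cavities: unchanged
  shell <- array(FALSE, c(9, 9, 9)); shell[3:7, 3:7, 3:7] <- TRUE
  shell[4:6, 4:6, 4:6] <- FALSE                     # hollow 5^3 shell
  filled <- fill_holes(shell)
  expect_equal(sum(filled), 125)
  expect_identical(fill_holes(filled), filled)      # idempotent
  expect_true(all(filled[shell]))                   # monotone: output contains input
  # an open notch touching the border is not a cavity
  notch <- cube; notch[5, 5, 1:5] <- FALSE
  expect_identical(fill_holes(notch), notch)
})

test_that("region growing recovers a noise-free tumor exactly", {
  ph <- generate_phantom(tiny_spec(seed = 31, noise_sd = 0))
  vol <- normalize_volume(ph$volume)
  box <- box_from_mask(ph$mask)
  seedpt <- (box$low + box$high) %/% 2L
  grown <- region_grow_baseline(vol, seedpt, threshold = 0.5)
  expect_identical(as.logical(grown), as.logical(ph$mask))
  expect_equal(n_components_oracle(grown), 1)
  # threshold 0 admits nothing beyond the seed voxel
  single <- region_grow_baseline(vol, seedpt, threshold = 0)
  expect_equal(sum(single), 1)
  expect_true(single[seedpt[1] + 1, seedpt[2] + 1, seedpt[3] + 1])
  expect_error(region_grow_baseline(vol, c(0, 0, 0)), "zero background")
})

test_that("cohort evaluation aggregates seeded folds", {
  set.seed(8)
  gts <- lapply(1:6, function(i) {
    m <- array(FALSE, c(12, 12, 12)); m[3:8, 3:8, 3:8] <- TRUE; m
  })
  report <- evaluate_cohort(gts, gts, n_folds = 5, seed = 2)
  expect_equal(nrow(report$per_fold), 5)
  expect_equal(report$summary$mean[report$summary$metric == "dice"], 1)
  expect_equal(report$summary$sd[report$summary$metric == "dice"], 0)
  # fold means recompute from the per-patient table and the fold membership
  preds <- gts
  preds[[2]][3, 3, 3] <- FALSE    # perturb one patient
  rep2 <- evaluate_cohort(preds, gts, n_folds = 3, seed = 4)
  for (f in seq_along(rep2$folds)) {
    idx <- rep2$folds[[f]]
    expect_equal(rep2$per_fold$dice[rep2$per_fold$fold == f],
                 mean(rep2$per_patient$dice[idx]))
  }
  expect_error(evaluate_cohort(gts[1:3], gts[1:3]), "at least 5")
})

test_that("metrics reports serialize to JSON and CSV", {
  gts <- lapply(1:5, function(i) {
    m <- array(FALSE, c(10, 10, 10)); m[2:5, 2:5, 2:5] <- TRUE; m
  })
  report <- evaluate_cohort(gts, gts, n_folds = 2, seed = 1)
  jf <- withr::local_tempfile(fileext = ".json")
  cf <- withr::local_tempfile(fileext = ".csv")
  write_metrics_report(report, jf, cf)
  parsed <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(nrow(parsed$per_fold), 2)
  expect_equal(nrow(utils::read.csv(cf)), 5)
})
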